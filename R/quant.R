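# quant: combined reference, per-version counting, RPKM, expression calls.

#' Build the combined A+C reference
#'
#' Concatenates the two cured references into one reference carrying, for
#' every unigene, its A-genome version (id suffixed `_A`) and its C-genome
#' version (id suffixed `_C`). Polyploid reads aligned against this
#' reference are apportioned between the versions by the aligner's best-hit
#' rule: a read spanning an IHP matches one version strictly better, while a
#' read in identical tract ties and is assigned at random, distributing such
#' reads evenly.
#'
#' @param pair a `cured_pair` from [build_cured_pair()].
#' @return a `combined_reference` (a [unigene_reference] with a
#'   `base_ids` attribute).
#' @export
build_combined_reference <- function(pair) {
  ids <- names(pair$a_ref)
  seqs <- character(2L * length(ids))
  nm <- character(2L * length(ids))
  if (length(ids) > 0) {
    seqs[seq(1L, by = 2L, length.out = length(ids))] <- unclass(pair$a_ref)
    seqs[seq(2L, by = 2L, length.out = length(ids))] <- unclass(pair$c_ref)
    nm[seq(1L, by = 2L, length.out = length(ids))] <- paste0(ids, "_A")
    nm[seq(2L, by = 2L, length.out = length(ids))] <- paste0(ids, "_C")
  }
  names(seqs) <- nm
  out <- unigene_reference(seqs)
  attr(out, "base_ids") <- ids
  class(out) <- c("combined_reference", class(out))
  out
}

#' Split combined-reference identifiers into unigene and genome version
#'
#' @param ids character vector of `<unigene>_A` / `<unigene>_C` identifiers.
#' @return a data frame with columns `unigene` and `version`.
#' @export
split_version_id <- function(ids) {
  version <- sub("^.*_([AC])$", "\\1", ids)
  bad <- !grepl("_[AC]$", ids)
  if (any(bad)) {
    stop(sprintf("not a combined-reference identifier: '%s'", ids[bad][1]),
         call. = FALSE)
  }
  data.frame(unigene = sub("_[AC]$", "", ids), version = version,
             stringsAsFactors = FALSE)
}

#' Count mapped reads separately for the A and C version of each unigene
#'
#' Each mapped read increments exactly one version's count, so for every
#' unigene `count_A + count_C` equals the total reads mapped to that pair.
#'
#' @param alns an `alignment_set` produced against the combined reference.
#' @param combined the `combined_reference` aligned against.
#' @return a data frame: `unigene`, `count_A`, `count_C` (one row per base
#'   unigene, zeros included).
#' @export
count_by_version <- function(alns, combined) {
  base_ids <- attr(combined, "base_ids")
  r <- alns$records
  unknown <- setdiff(unique(r$unigene), names(combined))
  if (length(unknown) > 0) {
    stop(sprintf("alignment to id absent from combined reference: '%s'",
                 unknown[1]), call. = FALSE)
  }
  tab <- table(factor(r$unigene, levels = names(combined)))
  data.frame(unigene = base_ids,
             count_A = as.integer(tab[paste0(base_ids, "_A")]),
             count_C = as.integer(tab[paste0(base_ids, "_C")]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reads per kilobase per million aligned reads
#'
#' `RPKM = count * 1e9 / (length_bases * total_mapped)`. A zero count gives
#' RPKM 0 by convention even when `total_mapped` is zero; a positive count
#' with zero total mapped reads is an invalid state.
#'
#' @param count non-negative read count (vectorised).
#' @param length_bases sequence length in bases (> 0).
#' @param total_mapped total mapped reads in the sample.
#' @return numeric RPKM values.
#' @export
rpkm <- function(count, length_bases, total_mapped) {
  stopifnot(all(count >= 0), all(length_bases > 0), all(total_mapped >= 0))
  if (any(total_mapped == 0 & count > 0)) {
    stop("positive count with zero total mapped reads", call. = FALSE)
  }
  out <- ifelse(count == 0, 0,
                count * 1e9 / (as.double(length_bases) * as.double(total_mapped)))
  as.numeric(out)
}

#' Align one polyploid sample and quantify both genome versions
#'
#' Aligns the reads against the combined reference and returns per-unigene
#' per-version counts and RPKM values. The RPKM denominator is the sample's
#' total mapped reads across the whole combined reference.
#'
#' @param reads a polyploid [read_set].
#' @param combined a `combined_reference`.
#' @param max_mismatches aligner substitution cap (default 3).
#' @param seed tie-break seed (ties between identical A and C tracts are
#'   resolved uniformly at random, apportioning such reads evenly).
#' @return a data frame `unigene`, `count_A`, `count_C`, `rpkm_A`,
#'   `rpkm_C`, with attributes `n_mapped` and `n_input`.
#' @export
quantify_sample <- function(reads, combined, max_mismatches = 3L, seed = 1L) {
  aln <- align_readset(reads, combined, max_mismatches, seed)
  counts <- count_by_version(aln, combined)
  len <- nchar(unclass(combined))
  counts$rpkm_A <- rpkm(counts$count_A, len[paste0(counts$unigene, "_A")],
                        aln$n_mapped_reads)
  counts$rpkm_C <- rpkm(counts$count_C, len[paste0(counts$unigene, "_C")],
                        aln$n_mapped_reads)
  attr(counts, "n_mapped") <- aln$n_mapped_reads
  attr(counts, "n_input") <- aln$n_input_reads
  counts
}

#' Qualitative expression call from replicate counts
#'
#' A unigene is called `expressed` when every replicate has at least one
#' mapped read, `non_expressed` when every replicate has zero, and
#' `inconsistent` otherwise.
#'
#' @param counts_per_replicate integer vector of per-replicate read counts
#'   (at least one replicate).
#' @return `"expressed"`, `"non_expressed"` or `"inconsistent"`.
#' @export
call_expression <- function(counts_per_replicate) {
  stopifnot(length(counts_per_replicate) >= 1, all(counts_per_replicate >= 0))
  if (min(counts_per_replicate) > 0) "expressed"
  else if (max(counts_per_replicate) == 0) "non_expressed"
  else "inconsistent"
}

#' Expression calls for a counts matrix
#'
#' @param counts matrix of counts, unigenes in rows, replicates in columns.
#' @return character vector of calls, one per row.
#' @export
call_expression_matrix <- function(counts) {
  apply(counts, 1L, call_expression)
}

#' Write a per-version count/RPKM table as TSV
#'
#' @param counts a data frame from [quantify_sample()] (or several merged).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
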
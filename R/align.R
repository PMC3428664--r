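# align: ungapped best-hit read alignment, pileups, consensus calls.
#
# The aligner is the pipeline's internal stand-in for a classic short-read
# mapper: ungapped, fully contained placements on either strand, at most
# `max_mismatches` substitutions, single best hit per read with a uniform
# random tie-break among equally good placements. Its contract is exact —
# it must agree with an exhaustive Hamming-distance scan over every offset
# and both strands — while the implementation uses pigeonhole k-mer seeding
# for speed.

#' Align a read set against a reference
#'
#' Each read is placed at the fully contained, ungapped position (on either
#' strand; reverse-strand placements match the reverse complement) with the
#' fewest mismatches, provided that number does not exceed `max_mismatches`.
#' `N` in read or reference always counts as a mismatch. When several
#' placements are equally good one is chosen uniformly at random and the
#' record is flagged `tie_broken`; reads whose best placement exceeds the
#' cap are unmapped. Results are deterministic given `seed`.
#'
#' @param reads a [read_set].
#' @param ref a [unigene_reference].
#' @param max_mismatches substitution cap (default 3, the cap under which
#'   reads are accepted throughout the curing walk-through).
#' @param seed integer seed for the tie-break RNG.
#' @return an `alignment_set`: a list with `records` (data frame of
#'   `read_id`, `unigene`, `start` (0-based), `strand`, `mismatches`,
#'   `tie_broken`), `n_input_reads`, `n_mapped_reads` and `seed`.
#' @export
align_readset <- function(reads, ref, max_mismatches = 3L, seed = 1L) {
  stopifnot(inherits(reads, "read_set"), inherits(ref, "unigene_reference"),
            max_mismatches >= 0L)
  res <- with_seed(seed,
    cpp_align_reads(reads$seq, as.character(ref), as.integer(max_mismatches)))
  mapped <- !is.na(res$unigene_idx)
  records <- data.frame(
    read_id = reads$id[mapped],
    unigene = names(ref)[res$unigene_idx[mapped]],
    start = res$start[mapped],
    strand = res$strand[mapped],
    mismatches = res$mismatches[mapped],
    tie_broken = res$tie_broken[mapped],
    stringsAsFactors = FALSE)
  structure(
    list(records = records, n_input_reads = length(reads$id),
         n_mapped_reads = sum(mapped), seed = seed,
         max_mismatches = as.integer(max_mismatches)),
    class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d / %d reads mapped (cap %d mismatches)\n",
              x$n_mapped_reads, x$n_input_reads, x$max_mismatches))
  invisible(x)
}

#' Align a single read
#'
#' Convenience wrapper around [align_readset()] for one read.
#'
#' @param bases the read sequence.
#' @param ref a [unigene_reference].
#' @param max_mismatches substitution cap.
#' @param seed tie-break seed.
#' @return a one-row data frame as in `alignment_set$records`, or `NULL`
#'   when the read is unmapped.
#' @export
align_read <- function(bases, ref, max_mismatches = 3L, seed = 1L) {
  rs <- read_set(id = "read", seq = bases,
                 qual = strrep("I", nchar(bases)))
  aln <- align_readset(rs, ref, max_mismatches, seed)
  if (aln$n_mapped_reads == 0) NULL else aln$records
}

#' Build a pileup from an alignment set
#'
#' Tallies, for every covered reference position, the aligned read bases and
#' their Phred qualities. Reverse-strand reads contribute complemented bases
#' (and their qualities) at the correct reference positions.
#'
#' @param alns an `alignment_set` (or a bare `records` data frame).
#' @param reads the [read_set] that was aligned.
#' @param ref the [unigene_reference] that was aligned against.
#' @return a data frame with one row per covered position: `unigene`, `pos`
#'   (0-based), `ref`, `depth`, per-base counts `A,C,G,T,N` and per-base
#'   summed qualities `qA,qC,qG,qT,qN`.
#' @export
build_pileup <- function(alns, reads, ref) {
  records <- if (inherits(alns, "alignment_set")) alns$records else alns
  idx <- match(records$read_id, reads$id)
  if (anyNA(idx)) {
    stop(sprintf("alignment refers to unknown read '%s'",
                 records$read_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  uni <- match(records$unigene, names(ref))
  if (anyNA(uni)) {
    stop(sprintf("alignment refers to unknown unigene '%s'",
                 records$unigene[which(is.na(uni))[1]]), call. = FALSE)
  }
  p <- cpp_build_pileup(uni, as.integer(records$start), records$strand,
                        reads$seq[idx], reads$qual[idx],
                        as.character(ref), 33L)
  out <- data.frame(unigene = names(ref)[p$unigene_idx], pos = p$pos,
                    ref = p$ref, depth = p$depth, stringsAsFactors = FALSE)
  cn <- c("A", "C", "G", "T", "N")
  counts <- p$counts; colnames(counts) <- cn
  quals <- p$quals; colnames(quals) <- paste0("q", cn)
  cbind(out, counts, quals)
}

#' Call a quality-aware consensus over pileup columns
#'
#' For each column the candidate base is the one of `{A,C,G,T}` with the
#' highest summed Phred quality (a tie yields `N`). The consensus quality is
#' that base's summed quality minus the summed quality of all other non-`N`
#' bases, floored at 0 and capped at 93. The base is called only when its
#' read count strictly exceeds `min_depth_exclusive` and the consensus
#' quality strictly exceeds `min_consensus_quality`; otherwise the call is
#' `N`. The default thresholds (depth > 3, quality > 40) are the curing
#' pipeline's high-confidence criteria.
#'
#' @param pileup a pileup data frame from [build_pileup()].
#' @param min_depth_exclusive call only when the supporting read count is
#'   strictly greater than this (default 3).
#' @param min_consensus_quality call only when the consensus quality is
#'   strictly greater than this (default 40).
#' @return a data frame: `unigene`, `pos`, `ref`, `called`,
#'   `supporting_depth`, `consensus_quality`.
#' @export
call_consensus <- function(pileup, min_depth_exclusive = 3L,
                           min_consensus_quality = 40L) {
  if (nrow(pileup) == 0) {
    return(data.frame(unigene = character(0), pos = integer(0),
                      ref = character(0), called = character(0),
                      supporting_depth = integer(0),
                      consensus_quality = integer(0),
                      stringsAsFactors = FALSE))
  }
  qm <- as.matrix(pileup[, c("qA", "qC", "qG", "qT")])
  cm <- as.matrix(pileup[, c("A", "C", "G", "T")])
  top <- do.call(pmax, as.data.frame(qm))
  n_at_top <- rowSums(qm == top)
  which_top <- max.col(qm, ties.method = "first")
  base <- c("A", "C", "G", "T")[which_top]
  support <- cm[cbind(seq_len(nrow(cm)), which_top)]
  cq <- pmin(pmax(2L * top - rowSums(qm), 0L), 93L)
  called <- ifelse(
    n_at_top == 1L & support > min_depth_exclusive & cq > min_consensus_quality,
    base, "N")
  data.frame(unigene = pileup$unigene, pos = pileup$pos, ref = pileup$ref,
             called = called, supporting_depth = support,
             consensus_quality = as.integer(cq), stringsAsFactors = FALSE)
}

#' Export an alignment set as SAM
#'
#' Minimal single-end SAM: header `@SQ` lines from the reference, one
#' alignment line per mapped read with an ungapped CIGAR and an `NM` tag for
#' the mismatch count. Reverse-strand reads are written reverse-complemented
#' with reversed qualities, as the format requires.
#'
#' @param alns an `alignment_set`.
#' @param reads the aligned [read_set].
#' @param ref the [unigene_reference] aligned against.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(alns, reads, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)), con)
  r <- alns$records
  if (nrow(r) > 0) {
    idx <- match(r$read_id, reads$id)
    rev <- r$strand == "-"
    seq <- ifelse(rev, reverse_complement(reads$seq[idx]), reads$seq[idx])
    qual <- ifelse(rev,
                   vapply(reads$qual[idx], function(q)
                     intToUtf8(rev(utf8ToInt(q))), character(1),
                     USE.NAMES = FALSE),
                   reads$qual[idx])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       r$read_id, ifelse(rev, 16L, 0L), r$unigene,
                       r$start + 1L, nchar(seq), seq, qual, r$mismatches),
               con)
  }
  invisible(path)
}

#' Export a pileup as TSV
#'
#' Positions are written 1-based, as in all file-facing coordinates.
#'
#' @param pileup a pileup data frame from [build_pileup()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pileup_tsv <- function(pileup, path) {
  out <- pileup
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
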
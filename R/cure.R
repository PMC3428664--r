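# cure: iterative correction of the naive reference towards a progenitor
# genome.
#
# Each cycle aligns the two 40-base halves of every progenitor read against
# the current reference, merges the placements into one pileup, calls a
# high-confidence consensus per covered position, and substitutes every
# reference base that differs from a called (non-N) consensus base. Fixing
# a divergent base lets reads spanning it align on the next cycle, so the
# set of reachable positions grows until the process converges; six cycles
# is the default.

#' Curing configuration
#'
#' @param n_cycles number of curing iterations (default 6).
#' @param max_mismatches aligner substitution cap (default 3).
#' @param min_depth_exclusive consensus depth threshold, exclusive
#'   (default 3: a base is called only with depth > 3).
#' @param min_consensus_quality consensus quality threshold, exclusive
#'   (default 40).
#' @param split_length length of each read half (default 40; 80-base reads
#'   are split into their first and last 40 bases).
#' @param rng_seed seed from which all per-cycle tie-break seeds derive.
#' @param early_stop stop when a cycle changes no bases (default `FALSE`:
#'   run the fixed number of cycles).
#' @return a `curing_config` list.
#' @export
curing_config <- function(n_cycles = 6L, max_mismatches = 3L,
                          min_depth_exclusive = 3L,
                          min_consensus_quality = 40L,
                          split_length = 40L, rng_seed = 1L,
                          early_stop = FALSE) {
  for (v in list(n_cycles, max_mismatches, min_depth_exclusive,
                 min_consensus_quality, split_length, rng_seed)) {
    if (length(v) != 1L || !is.numeric(v) || is.na(v)) {
      stop("curing_config: every parameter must be a single number",
           call. = FALSE)
    }
  }
  stopifnot(n_cycles >= 0L, max_mismatches >= 0L, min_depth_exclusive >= 0L,
            min_consensus_quality >= 0L, split_length >= 1L)
  structure(list(n_cycles = as.integer(n_cycles),
                 max_mismatches = as.integer(max_mismatches),
                 min_depth_exclusive = as.integer(min_depth_exclusive),
                 min_consensus_quality = as.integer(min_consensus_quality),
                 split_length = as.integer(split_length),
                 rng_seed = as.integer(rng_seed),
                 early_stop = isTRUE(early_stop)),
            class = "curing_config")
}

#' Split fixed-length reads into two halves
#'
#' Splitting 80-base reads into two 40-base reads lets reads map into
#' regions of higher divergence: each half tolerates the full mismatch cap
#' on its own. The first output holds bases `[1, split_length]`, the second
#' bases `[split_length + 1, 2 * split_length]`, each with its qualities.
#' Reads shorter than `2 * split_length` are dropped and counted.
#'
#' @param reads a [read_set].
#' @param split_length half length (default 40).
#' @return a list with `first` and `second` ([read_set]s, ids suffixed
#'   `:1` / `:2`) and `n_dropped`.
#' @export
split_reads <- function(reads, split_length = 40L) {
  split_length <- as.integer(split_length)
  stopifnot(split_length >= 1L)
  keep <- nchar(reads$seq) >= 2L * split_length
  mk <- function(from, to, tag) {
    ids <- reads$id[keep]
    read_set(id = if (length(ids)) paste0(ids, ":", tag) else character(0),
             seq = substr(reads$seq[keep], from, to),
             qual = substr(reads$qual[keep], from, to),
             sample = reads$sample, genome_tag = reads$genome_tag)
  }
  list(first = mk(1L, split_length, "1"),
       second = mk(split_length + 1L, 2L * split_length, "2"),
       n_dropped = sum(!keep))
}

#' Run one curing cycle
#'
#' Aligns both half-read sets against the current reference, merges the two
#' alignment sets into a single pileup (qualities accumulate across both),
#' calls the consensus, and substitutes every reference base whose called
#' consensus is a non-N base different from the current reference base.
#'
#' @param ref current [unigene_reference].
#' @param half1,half2 the two half-[read_set]s from [split_reads()].
#' @param cfg a [curing_config].
#' @param seed tie-break seed for this cycle.
#' @return a list: `ref` (updated reference), `n_reads_mapped` (merged
#'   mapped count over both halves), `changes` (data frame `unigene`,
#'   `pos`, `old_base`, `new_base`).
#' @export
cure_cycle <- function(ref, half1, half2, cfg = curing_config(), seed = 1L) {
  aln1 <- align_readset(half1, ref, cfg$max_mismatches, seed)
  aln2 <- align_readset(half2, ref, cfg$max_mismatches, derive_seed(seed, 1L))
  merged_reads <- combine_read_sets(half1, half2)
  merged_records <- rbind(aln1$records, aln2$records)
  pile <- build_pileup(merged_records, merged_reads, ref)
  cons <- call_consensus(pile, cfg$min_depth_exclusive,
                         cfg$min_consensus_quality)
  chg <- cons[cons$called != "N" & cons$called != cons$ref, , drop = FALSE]
  changes <- data.frame(unigene = chg$unigene, pos = chg$pos,
                        old_base = chg$ref, new_base = chg$called,
                        stringsAsFactors = FALSE)
  new_ref <- apply_substitutions(ref, changes)
  list(ref = new_ref,
       n_reads_mapped = aln1$n_mapped_reads + aln2$n_mapped_reads,
       changes = changes)
}

apply_substitutions <- function(ref, changes) {
  if (nrow(changes) == 0) return(ref)
  seqs <- unclass(ref)
  for (u in unique(changes$unigene)) {
    rows <- changes$unigene == u
    s <- strsplit(seqs[[u]], "", fixed = TRUE)[[1]]
    s[changes$pos[rows] + 1L] <- changes$new_base[rows]
    seqs[[u]] <- paste(s, collapse = "")
  }
  unigene_reference(seqs)
}

#' Cure a reference towards one progenitor genome
#'
#' Splits the progenitor reads once, then iterates [cure_cycle()]
#' `cfg$n_cycles` times, threading the evolving reference. Per-cycle
#' tie-break seeds are derived deterministically from `cfg$rng_seed` and the
#' cycle index, so the whole run is reproducible.
#'
#' @param naive the naive [unigene_reference].
#' @param progenitor_reads progenitor [read_set] (nominally 80-base reads).
#' @param cfg a [curing_config].
#' @return a list: `ref` (cured reference), `stats` (data frame
#'   `cycle_index`, `n_reads_mapped`, `n_bases_changed`,
#'   `cumulative_bases_changed`), `changes` (full change log with a `cycle`
#'   column), `n_reads_dropped` (too short to split).
#' @export
cure_reference <- function(naive, progenitor_reads, cfg = curing_config()) {
  halves <- split_reads(progenitor_reads, cfg$split_length)
  ref <- naive
  stats <- data.frame(cycle_index = integer(0), n_reads_mapped = integer(0),
                      n_bases_changed = integer(0),
                      cumulative_bases_changed = integer(0))
  logs <- list()
  cum <- 0L
  for (cyc in seq_len(cfg$n_cycles)) {
    res <- cure_cycle(ref, halves$first, halves$second, cfg,
                      seed = derive_seed(cfg$rng_seed, cyc))
    ref <- res$ref
    n_chg <- nrow(res$changes)
    cum <- cum + n_chg
    stats <- rbind(stats, data.frame(
      cycle_index = cyc, n_reads_mapped = res$n_reads_mapped,
      n_bases_changed = n_chg, cumulative_bases_changed = cum))
    if (n_chg > 0) {
      logs[[length(logs) + 1L]] <- cbind(res$changes, cycle = cyc)
    }
    if (cfg$early_stop && n_chg == 0L) break
  }
  changes <- if (length(logs)) do.call(rbind, logs) else
    data.frame(unigene = character(0), pos = integer(0),
               old_base = character(0), new_base = character(0),
               cycle = integer(0), stringsAsFactors = FALSE)
  list(ref = ref, stats = stats, changes = changes,
       n_reads_dropped = halves$n_dropped)
}

#' Cure the naive reference to an A-genome and a C-genome version
#'
#' Runs [cure_reference()] independently for each progenitor read set from
#' the same naive reference.
#'
#' @param naive the naive [unigene_reference].
#' @param a_reads,c_reads progenitor [read_set]s for the A and C genomes.
#' @param cfg a [curing_config]; the C-genome run derives its seed from
#'   `cfg$rng_seed` so the two runs are independent but reproducible.
#' @return a `cured_pair`: `a_ref`, `c_ref`, `a_stats`, `c_stats`,
#'   `a_changes`, `c_changes`.
#' @export
build_cured_pair <- function(naive, a_reads, c_reads, cfg = curing_config()) {
  a <- cure_reference(naive, a_reads, cfg)
  cfg_c <- cfg
  cfg_c$rng_seed <- derive_seed(cfg$rng_seed, 9901L)
  c_ <- cure_reference(naive, c_reads, cfg_c)
  structure(list(a_ref = a$ref, c_ref = c_$ref,
                 a_stats = a$stats, c_stats = c_$stats,
                 a_changes = a$changes, c_changes = c_$changes),
            class = "cured_pair")
}

#' @export
print.cured_pair <- function(x, ...) {
  cat(sprintf(paste0("cured_pair: %d unigenes; %d bases cured towards A, ",
                     "%d towards C (%d concerted)\n"),
              length(x$a_ref), nrow(x$a_changes), nrow(x$c_changes),
              count_concerted_changes(x)))
  invisible(x)
}

#' Count concerted base changes between the two curing runs
#'
#' A change is concerted when both the A and the C run substituted the same
#' position of the same unigene with the same new base — typically a
#' correction of an assembly error in the naive reference rather than a
#' genome-specific difference.
#'
#' @param pair a `cured_pair` from [build_cured_pair()].
#' @return integer count of concerted changes.
#' @export
count_concerted_changes <- function(pair) {
  key <- function(chg) paste(chg$unigene, chg$pos, chg$new_base, sep = "\r")
  length(intersect(key(pair$a_changes), key(pair$c_changes)))
}

#' Write the per-cycle curing statistics as TSV
#'
#' @param stats a stats data frame from [cure_reference()] (optionally with
#'   a genome column prepended by the caller).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cycle_stats_tsv <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a curing change log as TSV (positions 1-based)
#'
#' @param changes a change-log data frame from [cure_reference()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_changes_tsv <- function(changes, path) {
  out <- changes
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
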
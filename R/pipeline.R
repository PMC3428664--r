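# pipeline: end-to-end orchestration (cure -> ihp -> quantify -> test),
# run configuration, and mapping-gain reporting. A thin command-line
# front-end over these functions ships in inst/cli/homeocure.R.

#' Percentage gain in mapped reads on the cured versus the naive reference
#'
#' @param naive_alns,cured_alns `alignment_set`s of the same read set
#'   aligned to the naive and to the cured (combined) reference.
#' @return percentage gain `100 * (mapped_cured - mapped_naive) /
#'   mapped_naive`; `NA` with a warning when nothing mapped to the naive
#'   reference.
#' @export
report_mapping_gain <- function(naive_alns, cured_alns) {
  n0 <- naive_alns$n_mapped_reads
  n1 <- cured_alns$n_mapped_reads
  if (n0 == 0) {
    warning("no reads mapped to the naive reference; gain undefined")
    return(NA_real_)
  }
  100 * (n1 - n0) / n0
}

#' Read a flat key=value run configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Values for the replicate
#' FASTQ list are comma-separated.
#'
#' @param path configuration file path.
#' @return a named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("malformed config line: '%s'", lines[bad][1]), call. = FALSE)
  }
  out <- lapply(kv, function(m) trimws(m[3]))
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}

#' Run the full apportioning pipeline
#'
#' Executes curing, IHP calling, per-replicate quantification and the
#' paired quasi-Poisson test in order, writing all result tables plus a
#' machine-readable JSON manifest (seeds, parameters, per-stage read and
#' base counters, mapping gain versus the naive reference) into `out_dir`.
#'
#' @param naive_fasta path to the naive reference FASTA.
#' @param reads_a_fastq,reads_c_fastq progenitor FASTQ paths.
#' @param poly_fastqs character vector of polyploid replicate FASTQ paths
#'   (one per biological replicate).
#' @param out_dir output directory (created if missing).
#' @param cfg a [curing_config]; its seed also drives quantification
#'   tie-breaks deterministically.
#' @param alpha significance level for the homoeologue test.
#' @param encoding FASTQ quality encoding of all inputs.
#' @param verbose print stage progress.
#' @return invisibly, a list with the cured pair, IHP table, count tables,
#'   test results and the manifest.
#' @export
run_pipeline <- function(naive_fasta, reads_a_fastq, reads_c_fastq,
                         poly_fastqs, out_dir, cfg = curing_config(),
                         alpha = 0.05, encoding = "sanger",
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  for (p in c(naive_fasta, reads_a_fastq, reads_c_fastq, poly_fastqs)) {
    if (!file.exists(p)) stop(sprintf("input not found: '%s'", p), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[cure] loading inputs")
  naive <- read_fasta(naive_fasta)
  reads_a <- read_fastq(reads_a_fastq, encoding, sample = "progenitor_A",
                        genome_tag = "A")
  reads_c <- read_fastq(reads_c_fastq, encoding, sample = "progenitor_C",
                        genome_tag = "C")
  say("[cure] curing naive reference (%d cycles, %d + %d reads)",
      cfg$n_cycles, length(reads_a), length(reads_c))
  pair <- build_cured_pair(naive, reads_a, reads_c, cfg)
  write_fasta(pair$a_ref, file.path(out_dir, "cured.A.fa"))
  write_fasta(pair$c_ref, file.path(out_dir, "cured.C.fa"))
  write_cycle_stats_tsv(
    rbind(cbind(genome = "A", pair$a_stats), cbind(genome = "C", pair$c_stats)),
    file.path(out_dir, "cure_cycles.tsv"))
  write_changes_tsv(
    rbind(cbind(genome = "A", pair$a_changes), cbind(genome = "C", pair$c_changes)),
    file.path(out_dir, "cure_changes.tsv"))

  say("[ihp] comparing cured references")
  ihp <- compare_references(pair$a_ref, pair$c_ref)
  write_ihp_tsv(ihp, file.path(out_dir, "ihp.tsv"))

  say("[quantify] aligning %d polyploid replicates", length(poly_fastqs))
  combined <- build_combined_reference(pair)
  lens <- nchar(unclass(naive))
  rpkm_a <- rpkm_c <- matrix(
    0, length(naive), length(poly_fastqs),
    dimnames = list(names(naive),
                    paste0("rep", seq_along(poly_fastqs))))
  count_a <- count_c <- rpkm_a
  stage_stats <- list()
  for (i in seq_along(poly_fastqs)) {
    reads <- read_fastq(poly_fastqs[i], encoding,
                        sample = sprintf("poly_rep%d", i),
                        genome_tag = "polyploid")
    q <- quantify_sample(reads, combined, cfg$max_mismatches,
                         seed = derive_seed(cfg$rng_seed, 5000L + i))
    naive_aln <- align_readset(reads, naive, cfg$max_mismatches,
                               seed = derive_seed(cfg$rng_seed, 6000L + i))
    count_a[, i] <- q$count_A
    count_c[, i] <- q$count_C
    rpkm_a[, i] <- q$rpkm_A
    rpkm_c[, i] <- q$rpkm_C
    stage_stats[[i]] <- list(
      replicate = i, n_input = attr(q, "n_input"),
      n_mapped_combined = attr(q, "n_mapped"),
      n_mapped_naive = naive_aln$n_mapped_reads,
      n_unigenes_detected = sum(q$count_A + q$count_C > 0),
      mapping_gain_pct = report_mapping_gain(
        naive_aln, structure(list(n_mapped_reads = attr(q, "n_mapped")),
                             class = "alignment_set")))
    write_counts_tsv(q, file.path(out_dir, sprintf("counts_rep%d.tsv", i)))
  }

  say("[test] paired quasi-Poisson test over unigenes with IHPs")
  results <- test_homoeologues(rpkm_a, rpkm_c, alpha, ihp_table = ihp)
  write_test_tsv(results, file.path(out_dir, "homeotest.tsv"))

  manifest <- list(
    tool = "homeocure",
    version = as.character(utils::packageVersion("homeocure")),
    config = unclass(cfg), alpha = alpha,
    inputs = list(naive = naive_fasta, reads_a = reads_a_fastq,
                  reads_c = reads_c_fastq, polyploid = poly_fastqs),
    curing = list(
      a_bases_changed = nrow(pair$a_changes),
      c_bases_changed = nrow(pair$c_changes),
      concerted_changes = count_concerted_changes(pair),
      a_cycles = pair$a_stats, c_cycles = pair$c_stats),
    ihp = ihp_summary(ihp)[c("n_unigenes_with_ihps", "total_ihps",
                             "mean_density_per_kb", "max_density_per_kb")],
    quantification = stage_stats,
    test = list(
      n_tested = nrow(results),
      n_a_higher = sum(results$bias == "A_higher"),
      n_c_higher = sum(results$bias == "C_higher"),
      n_dropped_all_zero = length(attr(results, "dropped_all_zero"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] outputs in %s", out_dir)
  invisible(list(pair = pair, ihp = ihp,
                 counts = list(A = count_a, C = count_c),
                 rpkm = list(A = rpkm_a, C = rpkm_c),
                 results = results, manifest = manifest))
}
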
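# homeotest: paired quasi-Poisson test of differential homoeologue
# contribution, BH adjustment, bias classification.
#
# For each unigene the 2n per-replicate abundances (A and C versions) are
# modelled with a log-link GLM with Poisson variance function, replicate
# indicators capturing the paired block structure and a genome indicator
# carrying the effect of interest. The dispersion is not fixed at 1 but
# estimated from the Pearson statistic, so the coefficient estimates equal
# those of an ordinary Poisson fit while inference is over-dispersion
# adjusted (Wald t with the residual degrees of freedom).

#' Fit the paired quasi-Poisson model for one unigene
#'
#' @param rpkm_a,rpkm_c non-negative per-replicate abundances (RPKM by
#'   default) for the A and C versions, aligned by replicate. The model is
#'   fitted to these values directly; quasi-likelihood does not require
#'   integer responses. Pass raw counts plus `offset_log` for a
#'   counts-with-offset fit instead.
#' @param offset_log optional length-`2n` log-offset vector (A replicates
#'   then C replicates), e.g. `log(length * total_mapped / 1e9)` to test
#'   counts on the RPKM scale.
#' @return a list: `genome_effect` (log-scale coefficient for C relative to
#'   A), `dispersion_phi` (Pearson-estimated dispersion), `p_raw`
#'   (two-sided Wald t p-value with residual df), `df_residual`, `ok`
#'   (`FALSE` with `NA` results for untestable input, i.e. all-zero data).
#' @export
fit_paired_quasipoisson <- function(rpkm_a, rpkm_c, offset_log = NULL) {
  n <- length(rpkm_a)
  stopifnot(n == length(rpkm_c), n >= 2, all(rpkm_a >= 0), all(rpkm_c >= 0))
  y <- c(rpkm_a, rpkm_c)
  if (all(y == 0)) {
    return(list(genome_effect = NA_real_, dispersion_phi = NA_real_,
                p_raw = NA_real_, df_residual = n - 1L, ok = FALSE))
  }
  genome <- factor(rep(c("A", "C"), each = n), levels = c("A", "C"))
  replicate <- factor(rep(seq_len(n), times = 2L))
  fit <- tryCatch(
    glm(y ~ replicate + genome, family = quasipoisson(),
        offset = offset_log),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    stop(sprintf("quasi-Poisson fit failed to converge (n = %d)", n),
         call. = FALSE)
  }
  beta <- coef(fit)[["genomeC"]]
  df <- fit$df.residual
  pearson <- sum(residuals(fit, type = "pearson")^2)
  phi <- pearson / df
  if (phi < .Machine$double.eps^0.5) {
    # the replicate terms fit the data exactly: no residual variation, so
    # the genome effect is known without error
    p <- if (abs(beta) < 1e-8) 1 else 0
    return(list(genome_effect = unname(beta), dispersion_phi = phi,
                p_raw = p, df_residual = df, ok = TRUE))
  }
  sm <- summary(fit, dispersion = NULL)
  tab <- sm$coefficients
  p <- tab["genomeC", "Pr(>|t|)"]
  list(genome_effect = unname(beta), dispersion_phi = unname(sm$dispersion),
       p_raw = unname(p), df_residual = df, ok = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values are monotone in rank, capped at 1, and returned in the
#' order of the input. `NA` inputs propagate to `NA` outputs and do not
#' count towards the number of tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Test every unigene for differential homoeologue contribution
#'
#' Fits the paired quasi-Poisson model per unigene, adjusts the raw
#' p-values with [bh_adjust()], and classifies bias at `alpha`. Unigenes
#' without IHPs carry no signal to apportion reads (both versions are
#' identical, so reads split evenly regardless of the true bias); when an
#' `ihp_table` is supplied, unigenes absent from it are excluded before
#' testing. Rows in which both genomes are all-zero are untestable and are
#' dropped, with their ids recorded in the `dropped_all_zero` attribute.
#'
#' @param rpkm_a,rpkm_c numeric matrices (unigenes x replicates) of paired
#'   abundances, identical dimnames.
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param ihp_table optional `ihp_table`; restricts testing to unigenes
#'   containing IHPs.
#' @return a data frame: `unigene`, `mean_rpkm_A`, `mean_rpkm_C`,
#'   `genome_effect`, `dispersion_phi`, `p_raw`, `p_adjusted`, `bias`.
#' @export
test_homoeologues <- function(rpkm_a, rpkm_c, alpha = 0.05,
                              ihp_table = NULL) {
  stopifnot(is.matrix(rpkm_a), is.matrix(rpkm_c),
            identical(dim(rpkm_a), dim(rpkm_c)),
            identical(rownames(rpkm_a), rownames(rpkm_c)))
  keep <- rep(TRUE, nrow(rpkm_a))
  if (!is.null(ihp_table)) {
    keep <- rownames(rpkm_a) %in% ihp_table$per_unigene$unigene
  }
  all_zero <- rowSums(rpkm_a) == 0 & rowSums(rpkm_c) == 0
  dropped <- rownames(rpkm_a)[keep & all_zero]
  keep <- keep & !all_zero
  a <- rpkm_a[keep, , drop = FALSE]
  c_ <- rpkm_c[keep, , drop = FALSE]
  fits <- lapply(seq_len(nrow(a)), function(i) {
    fit_paired_quasipoisson(a[i, ], c_[i, ])
  })
  out <- data.frame(
    unigene = rownames(a),
    mean_rpkm_A = rowMeans(a),
    mean_rpkm_C = rowMeans(c_),
    genome_effect = vapply(fits, `[[`, numeric(1), "genome_effect"),
    dispersion_phi = vapply(fits, `[[`, numeric(1), "dispersion_phi"),
    p_raw = vapply(fits, `[[`, numeric(1), "p_raw"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out <- classify_bias(out, alpha)
  attr(out, "dropped_all_zero") <- dropped
  out
}

#' Classify homoeologue bias from adjusted p-values and effect signs
#'
#' `A_higher` when the adjusted p-value is below `alpha` and the genome
#' effect (log C relative to A) is negative; `C_higher` when it is
#' positive; `none` otherwise.
#'
#' @param results a data frame with `genome_effect` and `p_adjusted`
#'   columns (e.g. from [test_homoeologues()]).
#' @param alpha significance level (default 0.05).
#' @return `results` with a `bias` column filled.
#' @export
classify_bias <- function(results, alpha = 0.05) {
  sig <- !is.na(results$p_adjusted) & results$p_adjusted < alpha
  results$bias <- ifelse(sig & results$genome_effect < 0, "A_higher",
                         ifelse(sig & results$genome_effect > 0,
                                "C_higher", "none"))
  results
}

#' Cross-tabulate bias calls across conditions
#'
#' Given result tables for several conditions (e.g. cultivars) over the
#' same unigene universe, counts unigenes by their joint bias pattern and
#' extracts the consistently biased sets, including the discordant class
#' (significant in different directions in different conditions).
#'
#' @param result_tables named list of data frames from
#'   [test_homoeologues()], sharing the same unigenes.
#' @param mode only `"intersect"` is implemented: consistent calls are
#'   those significant with the same direction in every condition.
#' @return a list: `pattern_counts` (table of joint bias patterns),
#'   `consistent_A`, `consistent_C` (unigene ids significant in the same
#'   direction everywhere), `discordant` (significant everywhere but not in
#'   one direction), `n_conditions`.
#' @export
consistency_across_conditions <- function(result_tables,
                                          mode = "intersect") {
  mode <- match.arg(mode)
  stopifnot(length(result_tables) >= 1)
  universe <- result_tables[[1]]$unigene
  calls <- vapply(result_tables, function(tb) {
    stopifnot(setequal(tb$unigene, universe))
    tb$bias[match(universe, tb$unigene)]
  }, character(length(universe)))
  calls <- matrix(calls, nrow = length(universe))
  pattern <- apply(calls, 1L, paste, collapse = "/")
  all_a <- apply(calls == "A_higher", 1L, all)
  all_c <- apply(calls == "C_higher", 1L, all)
  all_sig <- apply(calls != "none", 1L, all)
  list(pattern_counts = table(pattern),
       consistent_A = universe[all_a],
       consistent_C = universe[all_c],
       discordant = universe[all_sig & !all_a & !all_c],
       n_conditions = length(result_tables))
}

#' Write a homoeologue test table as TSV
#'
#' @param results a data frame from [test_homoeologues()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_test_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
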
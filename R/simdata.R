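# simdata: synthetic allopolyploid transcriptome fixtures with known truth.
#
# The generator emulates the data the pipeline was designed for: a set of
# consensus unigenes (the "ancestral" sequences, which double as the naive
# reference), two progenitor genomes diverged from them by substitution at
# ~3% of positions, fixed-length 80-base reads with per-base Phred
# qualities and substitution sequencing errors, four biological replicates,
# and per-unigene homoeologue expression bias. Divergence and errors are
# substitution-only, matching the ungapped scope of the aligner and the
# substitute-only curing operation.

#' Simulate a diverged homoeologue pair with known truth
#'
#' Ancestral sequences are i.i.d. uniform over `{A,C,G,T}`; each position
#' is independently mutated, with probability `divergence_rate`, in exactly
#' one of the two descendant genomes (chosen with equal probability) to a
#' uniformly random different base. The ancestral set is the naive
#' reference; the mutated positions are the planted IHPs.
#'
#' @param n_unigenes number of unigenes (default 200).
#' @param length_mean,length_sd unigene length model: lengths are drawn
#'   from a normal with these moments and floored at `length_min`
#'   (defaults 1000, 150, 300 — a typical unigene-assembly length scale).
#' @param length_min minimum unigene length.
#' @param divergence_rate per-position divergence probability (default
#'   0.03, the mutual divergence typical of the homoeologous genomes this
#'   pipeline targets); recycled over unigenes, so a vector can plant
#'   zero-divergence unigenes.
#' @param expression_meanlog,expression_sdlog log-normal model for the
#'   per-unigene relative expression level (defaults 0, 0.5).
#' @param a_fraction per-unigene fraction of polyploid transcripts
#'   originating from the A genome (default 0.5 = unbiased; recycled).
#' @param seed RNG seed.
#' @return a `sim_truth` object: `ancestral`, `a_seq`, `c_seq`
#'   ([unigene_reference]s), `divergence` (data frame `unigene`, `pos`
#'   (0-based), `base_a`, `base_c`), `expression` (data frame `unigene`,
#'   `length`, `level`, `a_fraction`), `seed`.
#' @export
simulate_diverged_pair <- function(n_unigenes = 200L, length_mean = 1000,
                                   length_sd = 150, length_min = 300L,
                                   divergence_rate = 0.03,
                                   expression_meanlog = 0,
                                   expression_sdlog = 0.5,
                                   a_fraction = 0.5, seed = 1L) {
  stopifnot(all(divergence_rate >= 0 & divergence_rate <= 1),
            all(a_fraction >= 0 & a_fraction <= 1))
  divergence_rate <- rep_len(divergence_rate, n_unigenes)
  a_fraction <- rep_len(a_fraction, n_unigenes)
  with_seed(seed, {
    lens <- pmax(as.integer(round(rnorm(n_unigenes, length_mean, length_sd))),
                 as.integer(length_min))
    ids <- sprintf("unigene%04d", seq_len(n_unigenes))
    bases <- c("A", "C", "G", "T")
    anc <- a <- c_ <- character(n_unigenes)
    div <- vector("list", n_unigenes)
    for (i in seq_len(n_unigenes)) {
      s <- sample(bases, lens[i], replace = TRUE)
      sa <- sc <- s
      hit <- which(runif(lens[i]) < divergence_rate[i])
      if (length(hit) > 0) {
        to_a <- runif(length(hit)) < 0.5
        mut <- function(orig) {
          vapply(orig, function(b) sample(setdiff(bases, b), 1L),
                 character(1), USE.NAMES = FALSE)
        }
        sa[hit[to_a]] <- mut(s[hit[to_a]])
        sc[hit[!to_a]] <- mut(s[hit[!to_a]])
        div[[i]] <- data.frame(unigene = ids[i], pos = hit - 1L,
                               base_a = sa[hit], base_c = sc[hit],
                               stringsAsFactors = FALSE)
      }
      anc[i] <- paste(s, collapse = "")
      a[i] <- paste(sa, collapse = "")
      c_[i] <- paste(sc, collapse = "")
    }
    names(anc) <- names(a) <- names(c_) <- ids
    divergence <- do.call(rbind, c(list(data.frame(
      unigene = character(0), pos = integer(0), base_a = character(0),
      base_c = character(0), stringsAsFactors = FALSE)), div))
    expression <- data.frame(
      unigene = ids, length = lens,
      level = rlnorm(n_unigenes, expression_meanlog, expression_sdlog),
      a_fraction = a_fraction, stringsAsFactors = FALSE)
    structure(list(ancestral = unigene_reference(anc),
                   a_seq = unigene_reference(a),
                   c_seq = unigene_reference(c_),
                   divergence = divergence, expression = expression,
                   seed = seed),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d unigenes (%s bases), %d planted divergent positions\n",
    length(x$ancestral), format(sum(nchar(x$ancestral)), big.mark = ","),
    nrow(x$divergence)))
  invisible(x)
}

# Per-read quality string model: constant high quality through base 60,
# then a linear decline towards the read end — the within-read quality
# profile typical of the long-read-cycle runs this pipeline targets.
quality_profile <- function(read_length, plateau_q = 35L, plateau_end = 60L,
                            tail_q = 20L) {
  pos <- seq_len(read_length)
  q <- rep(plateau_q, read_length)
  if (read_length > plateau_end) {
    tail_pos <- pos[pos > plateau_end]
    q[tail_pos] <- as.integer(round(
      plateau_q + (tail_q - plateau_q) *
        (tail_pos - plateau_end) / (read_length - plateau_end)))
  }
  q
}

#' Simulate mRNA-Seq reads from a simulated truth
#'
#' Read counts per unigene are Poisson with mean
#' `depth_target * length / read_length`, weighted by the unigene's
#' relative expression level in polyploid mode; start positions are uniform
#' over valid offsets and strands uniform. Substitution errors occur
#' independently per base at `error_rate` (to a uniformly random different
#' base). In polyploid mode each read's template genome is drawn from the
#' unigene's planted `a_fraction`.
#'
#' @param truth a `sim_truth`.
#' @param genome `"A"`, `"C"` (progenitor mode: all reads from that cured
#'   truth sequence) or `"polyploid"`.
#' @param depth_target expected fold-coverage per unigene (default 30).
#' @param read_length read length (default 80).
#' @param error_rate per-base substitution error probability (default 0.01).
#' @param sample sample label stored in the returned set.
#' @param use_expression_levels weight unigene read counts by the planted
#'   expression levels (always on in polyploid mode; default `FALSE` for
#'   progenitor mode so curing coverage is even).
#' @param seed RNG seed.
#' @return a [read_set] with an `origins` attribute (data frame `unigene`,
#'   `start`, `strand`, `genome` giving each read's true template).
#' @export
simulate_reads <- function(truth, genome = c("A", "C", "polyploid"),
                           depth_target = 30, read_length = 80L,
                           error_rate = 0.01, sample = genome,
                           use_expression_levels = (genome == "polyploid"),
                           seed = 1L) {
  genome <- match.arg(genome)
  ids <- names(truth$ancestral)
  lens <- nchar(unclass(truth$ancestral))
  stopifnot(read_length <= min(lens))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    weight <- if (use_expression_levels) {
      truth$expression$level / mean(truth$expression$level)
    } else rep(1, length(ids))
    n_reads <- rpois(length(ids), depth_target * lens / read_length * weight)
    origins <- data.frame(
      unigene = rep(ids, n_reads),
      start = NA_integer_, strand = NA_character_, genome = NA_character_,
      stringsAsFactors = FALSE)
    total <- nrow(origins)
    origins$start <- as.integer(floor(
      runif(total) * (rep(lens, n_reads) - read_length + 1L)))
    origins$strand <- ifelse(runif(total) < 0.5, "+", "-")
    origins$genome <- if (genome == "polyploid") {
      afrac <- rep(truth$expression$a_fraction, n_reads)
      ifelse(runif(total) < afrac, "A", "C")
    } else rep(genome, total)
    templates <- ifelse(origins$genome == "A",
                        unclass(truth$a_seq)[origins$unigene],
                        unclass(truth$c_seq)[origins$unigene])
    seqs <- substr(templates, origins$start + 1L,
                   origins$start + read_length)
    seqs <- ifelse(origins$strand == "-", reverse_complement(seqs), seqs)
    # substitution errors
    if (error_rate > 0 && total > 0) {
      n_err <- rbinom(total, read_length, error_rate)
      with_err <- which(n_err > 0)
      if (length(with_err) > 0) {
        chars <- strsplit(seqs[with_err], "", fixed = TRUE)
        for (j in seq_along(with_err)) {
          pos <- sample.int(read_length, n_err[with_err[j]])
          for (p in pos) {
            chars[[j]][p] <- sample(setdiff(bases, chars[[j]][p]), 1L)
          }
        }
        seqs[with_err] <- vapply(chars, paste, character(1), collapse = "")
      }
    }
    qual <- phred_encode(quality_profile(read_length))
    rs <- read_set(
      id = sprintf("%s_r%06d", sample, seq_len(total)),
      seq = seqs, qual = rep(qual, total), sample = sample,
      genome_tag = if (genome == "polyploid") "polyploid" else genome)
    attr(rs, "origins") <- origins
    rs
  })
}

#' Simulate a replicated polyploid experiment
#'
#' Draws, for every unigene, genome version and replicate, a gamma
#' multiplier calibrated so that replicate read counts are over-dispersed
#' with index approximately `dispersion_phi` (`phi = 1` gives plain Poisson
#' counts), then generates one polyploid read set per replicate. The
#' expected per-version counts are retained for recovery tests.
#'
#' @param truth a `sim_truth`.
#' @param n_replicates number of biological replicates (default 4).
#' @param dispersion_phi target count over-dispersion (>= 1, default 3).
#' @param depth_target expected fold-coverage per unigene per replicate.
#' @param read_length,error_rate as in [simulate_reads()].
#' @param seed RNG seed.
#' @return a list: `replicates` (list of [read_set]s), `expected_counts`
#'   (data frame `unigene`, `expected_A`, `expected_C` per replicate-mean),
#'   `n_replicates`, `dispersion_phi`.
#' @export
simulate_paired_experiment <- function(truth, n_replicates = 4L,
                                       dispersion_phi = 3,
                                       depth_target = 30, read_length = 80L,
                                       error_rate = 0.01, seed = 1L) {
  stopifnot(dispersion_phi >= 1, n_replicates >= 1L)
  ids <- names(truth$ancestral)
  lens <- truth$expression$length
  level <- truth$expression$level / mean(truth$expression$level)
  m_total <- depth_target * lens / read_length * level
  m_a <- m_total * truth$expression$a_fraction
  m_c <- m_total * (1 - truth$expression$a_fraction)
  with_seed(seed, {
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      g_a <- gamma_multiplier(m_a, dispersion_phi)
      g_c <- gamma_multiplier(m_c, dispersion_phi)
      n_a <- rpois(length(ids), m_a * g_a)
      n_c <- rpois(length(ids), m_c * g_c)
      reps[[r]] <- simulate_fixed_counts(
        truth, n_a, n_c, read_length, error_rate,
        sample = sprintf("poly_rep%d", r),
        seed = derive_seed(seed, r))
    }
    list(replicates = reps,
         expected_counts = data.frame(unigene = ids, expected_A = m_a,
                                      expected_C = m_c,
                                      stringsAsFactors = FALSE),
         n_replicates = n_replicates, dispersion_phi = dispersion_phi)
  })
}

# Mean-1 gamma multipliers such that Poisson(m * g) has variance ~ phi * m:
# shape r = m / (phi - 1) gives Var = m + m^2 / r = phi * m.
gamma_multiplier <- function(m, phi) {
  if (phi <= 1) return(rep(1, length(m)))
  shape <- pmax(m / (phi - 1), 1e-8)
  rgamma(length(m), shape = shape, rate = shape)
}

# Generate reads with externally fixed per-unigene per-genome counts.
simulate_fixed_counts <- function(truth, n_a, n_c, read_length = 80L,
                                  error_rate = 0.01, sample = "poly",
                                  seed = 1L) {
  ids <- names(truth$ancestral)
  lens <- nchar(unclass(truth$ancestral))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    origins <- data.frame(
      unigene = c(rep(ids, n_a), rep(ids, n_c)),
      genome = c(rep("A", sum(n_a)), rep("C", sum(n_c))),
      stringsAsFactors = FALSE)
    total <- nrow(origins)
    ulen <- c(rep(lens, n_a), rep(lens, n_c))
    origins$start <- as.integer(floor(runif(total) * (ulen - read_length + 1L)))
    origins$strand <- ifelse(runif(total) < 0.5, "+", "-")
    templates <- ifelse(origins$genome == "A",
                        unclass(truth$a_seq)[origins$unigene],
                        unclass(truth$c_seq)[origins$unigene])
    seqs <- substr(templates, origins$start + 1L, origins$start + read_length)
    seqs <- ifelse(origins$strand == "-", reverse_complement(seqs), seqs)
    if (error_rate > 0 && total > 0) {
      n_err <- rbinom(total, read_length, error_rate)
      with_err <- which(n_err > 0)
      if (length(with_err) > 0) {
        chars <- strsplit(seqs[with_err], "", fixed = TRUE)
        for (j in seq_along(with_err)) {
          pos <- sample.int(read_length, n_err[with_err[j]])
          for (p in pos) {
            chars[[j]][p] <- sample(setdiff(bases, chars[[j]][p]), 1L)
          }
        }
        seqs[with_err] <- vapply(chars, paste, character(1), collapse = "")
      }
    }
    qual <- phred_encode(quality_profile(read_length))
    rs <- read_set(id = sprintf("%s_r%06d", sample, seq_len(total)),
                   seq = seqs, qual = rep(qual, total), sample = sample,
                   genome_tag = "polyploid")
    attr(rs, "origins") <- origins[, c("unigene", "start", "strand", "genome")]
    rs
  })
}

#' Simulate paired over-dispersed abundance values directly
#'
#' Count-scale generator for calibrating the paired quasi-Poisson test
#' without the expense of read simulation: per replicate a shared block
#' multiplier (log-normal) scales both genome versions, and independent
#' gamma-Poisson noise gives marginal over-dispersion approximately
#' `dispersion_phi` at each genome's mean.
#'
#' @param n_unigenes number of unigenes to simulate.
#' @param n_replicates replicates per unigene (default 4).
#' @param mean_a,mean_c per-replicate mean abundance of the A and C
#'   versions (equal means simulate the null).
#' @param dispersion_phi target over-dispersion (default 3).
#' @param replicate_sdlog sd of the log-normal shared replicate effect
#'   (default 0.1).
#' @param seed RNG seed.
#' @return a list of matrices `a` and `c` (`n_unigenes` x `n_replicates`).
#' @export
simulate_paired_abundance <- function(n_unigenes, n_replicates = 4L,
                                      mean_a = 50, mean_c = 50,
                                      dispersion_phi = 3,
                                      replicate_sdlog = 0.1, seed = 1L) {
  with_seed(seed, {
    a <- matrix(0, n_unigenes, n_replicates)
    c_ <- matrix(0, n_unigenes, n_replicates)
    for (r in seq_len(n_replicates)) {
      block <- rlnorm(n_unigenes, -replicate_sdlog^2 / 2, replicate_sdlog)
      ga <- gamma_multiplier(rep(mean_a, n_unigenes), dispersion_phi)
      gc <- gamma_multiplier(rep(mean_c, n_unigenes), dispersion_phi)
      a[, r] <- rpois(n_unigenes, mean_a * block * ga)
      c_[, r] <- rpois(n_unigenes, mean_c * block * gc)
    }
    rownames(a) <- rownames(c_) <- sprintf("unigene%04d", seq_len(n_unigenes))
    list(a = a, c = c_)
  })
}

#' Write a simulation truth to plain-text files
#'
#' Writes the naive (ancestral) reference as FASTA, the planted divergence
#' map as TSV (positions 1-based) and the expression table as TSV.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_sim_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$ancestral, file.path(dir, "naive.fa"))
  div <- truth$divergence
  div$pos <- div$pos + 1L
  write.table(div, file.path(dir, "truth_divergence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$expression, file.path(dir, "truth_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
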
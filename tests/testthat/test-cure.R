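test_that("split_reads cuts 80-base reads into consistent 40-base halves", {
  set.seed(21)
  seqs <- vapply(1:5, function(i) random_read(80), character(1))
  quals <- replicate(5, phred_encode(sample(0:93, 80, replace = TRUE)))
  rs <- read_set(paste0("r", 1:5), seqs, quals)
  halves <- split_reads(rs)
  expect_identical(halves$n_dropped, 0L)
  expect_identical(nchar(halves$first$seq), rep(40L, 5))
  expect_identical(paste0(halves$first$seq, halves$second$seq), seqs)
  expect_identical(paste0(halves$first$qual, halves$second$qual), quals)
})

test_that("split_reads drops and counts reads shorter than both halves", {
  rs <- read_set(c("a", "b"), c(strrep("A", 79), strrep("C", 80)),
                 c(strrep("I", 79), strrep("I", 80)), variable_length = TRUE)
  halves <- split_reads(rs)
  expect_identical(halves$n_dropped, 1L)
  expect_identical(halves$first$id, "b:1")

  empty <- read_set(character(0), character(0), character(0))
  h0 <- split_reads(empty)
  expect_length(h0$first, 0L)
  expect_length(h0$second, 0L)
})

test_that("curing is a fixpoint on error-free reads from the reference itself", {
  set.seed(22)
  ref <- random_reference(3, 300, 400)
  reads <- vapply(1:300, function(i) sample_read_from(ref, 80), character(1))
  rs <- read_set(paste0("r", 1:300), reads, rep(strrep("I", 80), 300))
  halves <- split_reads(rs)
  res <- cure_cycle(ref, halves$first, halves$second, curing_config(), seed = 5)
  expect_identical(nrow(res$changes), 0L)
  expect_identical(unclass(res$ref), unclass(ref))
})

test_that("a planted wrong base with strong correct coverage is corrected", {
  set.seed(23)
  true_seq <- random_read(200)
  wrong <- unclass(unigene_reference(c(u1 = true_seq)))
  pos <- 100L  # 0-based
  old <- substr(wrong[["u1"]], pos + 1, pos + 1)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(wrong[["u1"]], pos + 1, pos + 1) <- new
  naive <- unigene_reference(wrong)
  # 6 error-free reads from the true sequence covering the planted site
  starts <- seq(60L, 85L, by = 5L)
  rs <- read_set(paste0("r", seq_along(starts)),
                 substring(true_seq, starts + 1L, starts + 80L),
                 rep(strrep("I", 80), length(starts)))
  halves <- split_reads(rs)
  res <- cure_cycle(naive, halves$first, halves$second, curing_config(),
                    seed = 9)
  expect_identical(res$changes$pos, pos)
  expect_identical(res$changes$old_base, new)
  expect_identical(res$changes$new_base, old)
  expect_identical(unclass(res$ref)[["u1"]], true_seq)
})

test_that("divergence too dense for the mismatch cap is cured over later cycles", {
  set.seed(24)
  true_seq <- random_read(260)
  sites <- c(96L, 100L, 104L, 108L, 112L, 116L, 120L)  # 0-based
  chars <- strsplit(true_seq, "")[[1]]
  naive_chars <- chars
  for (p in sites) {
    naive_chars[p + 1] <- setdiff(c("A", "C", "G", "T"), chars[p + 1])[1]
  }
  naive <- unigene_reference(c(u1 = paste(naive_chars, collapse = "")))
  # dense tiling of error-free 80-base reads from the true sequence
  starts <- 0:180
  rs <- read_set(paste0("r", starts),
                 substring(true_seq, starts + 1L, starts + 80L),
                 rep(strrep("I", 80), length(starts)))
  out <- cure_reference(naive, rs, curing_config(rng_seed = 3))
  # every planted site eventually cured ...
  expect_identical(unclass(out$ref)[["u1"]], true_seq)
  # ... but the innermost site is unreachable in cycle 1: any 40-base window
  # that covers it spans more than 3 divergent bases
  cyc1 <- out$changes$pos[out$changes$cycle == 1L]
  expect_false(108L %in% cyc1)
  expect_true(all(c(96L, 120L) %in% cyc1))
  expect_gt(max(out$changes$cycle), 1L)
  # mapped reads grow as the reference improves
  expect_true(all(diff(out$stats$n_reads_mapped) >= 0))
})

test_that("zero cycles returns the input untouched", {
  f <- small_fixture()
  out <- cure_reference(f$truth$ancestral, f$reads_a,
                        curing_config(n_cycles = 0))
  expect_identical(unclass(out$ref), unclass(f$truth$ancestral))
  expect_identical(nrow(out$stats), 0L)
  expect_identical(nrow(out$changes), 0L)
})

test_that("curing preserves unigene ids and lengths and converges", {
  f <- small_fixture()
  expect_identical(names(f$pair$a_ref), names(f$truth$ancestral))
  expect_identical(nchar(unclass(f$pair$a_ref)),
                   nchar(unclass(f$truth$ancestral)))
  # converged by cycle 6 on this fixture: re-curing the cured output with
  # the same reads changes nothing
  again <- cure_reference(f$pair$a_ref, f$reads_a,
                          curing_config(n_cycles = 1, rng_seed = 77))
  expect_identical(again$stats$n_bases_changed, 0L)
})

test_that("identical progenitor read sets produce identical cured references", {
  f <- small_fixture()
  pair <- build_cured_pair(f$truth$ancestral, f$reads_a, f$reads_a,
                           curing_config(n_cycles = 2, rng_seed = 31))
  expect_identical(unclass(pair$a_ref), unclass(pair$c_ref))
  expect_identical(nrow(compare_references(pair$a_ref, pair$c_ref)$records),
                   0L)
})

test_that("an empty progenitor read set leaves that genome at the naive state", {
  f <- small_fixture()
  empty <- read_set(character(0), character(0), character(0), genome_tag = "C")
  pair <- build_cured_pair(f$truth$ancestral, f$reads_a, empty,
                           curing_config(n_cycles = 2, rng_seed = 32))
  expect_identical(unclass(pair$c_ref), unclass(f$truth$ancestral))
  expect_true(all(pair$c_stats$n_bases_changed == 0L))
  expect_true(all(pair$c_stats$n_reads_mapped == 0L))
})

test_that("concerted changes are counted from the two change logs", {
  # plant the same assembly error for both genomes
  set.seed(25)
  true_seq <- random_read(200)
  chars <- strsplit(true_seq, "")[[1]]
  chars[101] <- setdiff(c("A", "C", "G", "T"), chars[101])[1]
  naive <- unigene_reference(c(u1 = paste(chars, collapse = "")))
  starts <- seq(40L, 100L, by = 4L)
  rs <- read_set(paste0("r", starts),
                 substring(true_seq, starts + 1L, starts + 80L),
                 rep(strrep("I", 80), length(starts)))
  pair <- build_cured_pair(naive, rs, rs, curing_config(n_cycles = 2))
  expect_identical(count_concerted_changes(pair), 1L)
})

test_that("change-log precision is high under realistic noise", {
  f <- small_fixture()
  ch <- f$pair$a_changes
  expect_gt(nrow(ch), 0L)
  true_base <- base_at(f$truth$a_seq, ch$unigene, ch$pos)
  expect_gte(mean(ch$new_base == true_base), 0.99)
})
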
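test_that("an exact unique window is found with zero mismatches", {
  set.seed(11)
  ref <- random_reference(3, 200, 300)
  read <- substr(ref[["u2"]], 51, 90)
  rec <- align_read(read, ref)
  expect_identical(rec$unigene, "u2")
  expect_identical(rec$start, 50L)
  expect_identical(rec$strand, "+")
  expect_identical(rec$mismatches, 0L)
  expect_false(rec$tie_broken)
})

test_that("a read whose best placement exceeds the cap is unmapped", {
  set.seed(12)
  ref <- random_reference(2, 200, 200)
  read <- substr(ref[["u1"]], 11, 50)
  mutated <- mutate_bases(read, 4L)
  # guard: ensure the mutation really left 4 as the best achievable
  ora <- oracle_align(mutated, ref)
  skip_if(ora$mm < 4, "random sequence happened to contain a closer window")
  expect_null(align_read(mutated, ref, max_mismatches = 3))
  expect_false(is.null(align_read(mutated, ref, max_mismatches = 4)))
})

test_that("reverse-complemented reads map to the same place on the other strand", {
  set.seed(13)
  ref <- random_reference(4, 300, 400)
  for (i in 1:20) {
    read <- sample_read_from(ref, 60, n_subs = 1L)
    fwd <- align_read(read, ref, seed = i)
    rev <- align_read(oracle_revcomp(read), ref, seed = i)
    expect_identical(fwd$unigene, rev$unigene)
    expect_identical(fwd$start, rev$start)
    expect_identical(fwd$mismatches, rev$mismatches)
    if (!fwd$tie_broken) {
      expect_true(fwd$strand != rev$strand)
    }
  }
})

test_that("aligner agrees with the exhaustive Hamming oracle", {
  set.seed(14)
  for (rep in 1:6) {
    ref <- random_reference(sample(2:5, 1), 150, 500)
    reads <- c(
      vapply(1:10, function(i) sample_read_from(ref, 40, sample(0:4, 1)),
             character(1)),
      vapply(1:5, function(i) random_read(40), character(1)))
    cap <- sample(0:3, 1)
    rs <- read_set(paste0("r", seq_along(reads)), reads,
                   rep(strrep("I", 40), length(reads)))
    aln <- align_readset(rs, ref, max_mismatches = cap, seed = rep)
    for (i in seq_along(reads)) {
      ora <- oracle_align(reads[i], ref, cap)
      rec <- aln$records[aln$records$read_id == paste0("r", i), ]
      if (is.infinite(ora$mm) || ora$mm > cap) {
        expect_identical(nrow(rec), 0L)
      } else {
        expect_identical(nrow(rec), 1L)
        expect_identical(rec$mismatches, as.integer(ora$mm))
        hit <- ora$placements
        expect_true(any(hit$unigene == rec$unigene & hit$start == rec$start &
                          hit$strand == rec$strand))
        expect_identical(rec$tie_broken, nrow(hit) > 1L)
      }
    }
  }
})

test_that("error-free reads from the reference all map; alien reads do not", {
  set.seed(15)
  ref <- random_reference(5, 300, 500)
  reads <- vapply(1:200, function(i) sample_read_from(ref, 40), character(1))
  rs <- read_set(paste0("r", 1:200), reads, rep(strrep("I", 40), 200))
  aln <- align_readset(rs, ref, seed = 2)
  expect_identical(aln$n_mapped_reads, aln$n_input_reads)

  alien <- vapply(1:50, function(i) random_read(40), character(1))
  rs2 <- read_set(paste0("x", 1:50), alien, rep(strrep("I", 40), 50))
  aln2 <- align_readset(rs2, ref, seed = 3)
  for (i in 1:50) {
    ora <- oracle_align(alien[i], ref, 3)
    mapped <- alien[i] %in% rs2$seq[rs2$id %in% aln2$records$read_id]
    expect_identical(paste0("x", i) %in% aln2$records$read_id,
                     is.finite(ora$mm) && ora$mm <= 3)
  }
})

test_that("alignment is deterministic given the seed", {
  set.seed(16)
  ref <- unigene_reference(c(u1 = random_read(300), u2 = random_read(300)))
  # force ties: duplicate unigene
  ref2 <- unigene_reference(c(a = ref[["u1"]], b = ref[["u1"]]))
  reads <- vapply(1:100, function(i) {
    start <- sample(1:260, 1)
    substr(ref[["u1"]], start, start + 39)
  }, character(1))
  rs <- read_set(paste0("r", 1:100), reads, rep(strrep("I", 40), 100))
  a1 <- align_readset(rs, ref2, seed = 7)
  a2 <- align_readset(rs, ref2, seed = 7)
  expect_identical(a1, a2)
  expect_true(all(a1$records$tie_broken))
})

test_that("ties between identical duplicated sequences split evenly", {
  set.seed(17)
  base <- random_read(500)
  ref2 <- unigene_reference(c(a = base, b = base))
  n <- 2000
  starts <- sample(1:460, n, replace = TRUE)
  reads <- substring(base, starts, starts + 39)
  rs <- read_set(paste0("r", 1:n), reads, rep(strrep("I", 40), n))
  aln <- align_readset(rs, ref2, seed = 1)
  frac_a <- mean(aln$records$unigene == "a")
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac_a - 0.5), 3 * se)
})

test_that("pileup accumulates depth, qualities and complemented bases", {
  ref <- unigene_reference(c(u1 = "TTAGCCAGACGATTCAGGCAATCG"))
  # forward reads, exact, 12-mer window is unique on both strands
  rs <- read_set(c("f", "f2"), rep(substr(ref[["u1"]], 5, 16), 2),
                 rep(phred_encode(rep(30L, 12)), 2))
  aln <- align_readset(rs, ref, seed = 1)
  expect_false(any(aln$records$tie_broken))
  pile <- build_pileup(aln, rs, ref)
  expect_identical(nrow(pile), 12L)
  expect_true(all(pile$depth == 2L))
  # counts concentrated on the reference base
  hit <- vapply(seq_len(nrow(pile)), function(i) pile[i, pile$ref[i]],
                integer(1))
  expect_true(all(hit == 2L))
  expect_true(all(pile[cbind(seq_len(12), match(paste0("q", pile$ref),
                                                colnames(pile)))] == 60L))
  # depth conservation: total depth equals total aligned bases
  expect_identical(sum(pile$depth), 2L * 12L)

  # reverse-strand read contributes complemented bases at the right spots
  rc <- read_set("r", oracle_revcomp(substr(ref[["u1"]], 5, 16)),
                 phred_encode(rep(30L, 12)))
  aln_rc <- align_readset(rc, ref, seed = 1)
  expect_identical(aln_rc$records$strand, "-")
  expect_identical(aln_rc$records$start, 4L)
  pile_rc <- build_pileup(aln_rc, rc, ref)
  hit_rc <- vapply(seq_len(nrow(pile_rc)), function(i)
    pile_rc[i, pile_rc$ref[i]], integer(1))
  expect_true(all(hit_rc == 1L))
})

test_that("pileup rejects records that fall outside the unigene", {
  ref <- unigene_reference(c(u1 = "ACGTACGTAC"))
  rs <- read_set("r", "ACGT", "IIII")
  bad <- data.frame(read_id = "r", unigene = "u1", start = 8L, strand = "+",
                    mismatches = 0L, tie_broken = FALSE,
                    stringsAsFactors = FALSE)
  expect_error(build_pileup(bad, rs, ref), "beyond")
  bad$unigene <- "nope"
  expect_error(build_pileup(bad, rs, ref), "unknown unigene")
})

test_that("pileup depth conservation holds on a random fixture", {
  set.seed(18)
  ref <- random_reference(3, 200, 400)
  reads <- vapply(1:150, function(i) sample_read_from(ref, 40, sample(0:2, 1)),
                  character(1))
  rs <- read_set(paste0("r", 1:150), reads, rep(strrep("I", 40), 150))
  aln <- align_readset(rs, ref, seed = 4)
  pile <- build_pileup(aln, rs, ref)
  expect_identical(sum(pile$depth), aln$n_mapped_reads * 40L)
})

test_that("consensus calling applies the depth and quality thresholds exactly", {
  col <- function(A = 0, C = 0, G = 0, T = 0, N = 0,
                  qA = 0, qC = 0, qG = 0, qT = 0, qN = 0, ref = "T") {
    data.frame(unigene = "u", pos = 0L, ref = ref,
               depth = A + C + G + T + N, A = A, C = C, G = G, T = T, N = N,
               qA = qA, qC = qC, qG = qG, qT = qT, qN = qN,
               stringsAsFactors = FALSE)
  }
  # 5 x G at Phred 30: quality 150 capped at 93 > 40, depth 5 > 3 -> call G
  expect_identical(call_consensus(col(G = 5, qG = 150))$called, "G")
  expect_identical(call_consensus(col(G = 5, qG = 150))$consensus_quality, 93L)
  # depth exactly 3 is not > 3 -> N
  expect_identical(call_consensus(col(G = 3, qG = 120))$called, "N")
  # summed quality exactly 40 is not > 40 -> N
  expect_identical(call_consensus(col(G = 4, qG = 40))$called, "N")
  # quality tie between two bases -> N
  expect_identical(call_consensus(col(G = 5, T = 5, qG = 100, qT = 100))$called,
                   "N")
  # opposing evidence subtracts: 5xG@30 vs 2xT@30 -> 150 - 60 = 90
  out <- call_consensus(col(G = 5, T = 2, qG = 150, qT = 60))
  expect_identical(out$consensus_quality, 90L)
  expect_identical(out$called, "G")
})

test_that("SAM export writes well-formed minimal records", {
  ref <- unigene_reference(c(u1 = "TTAGCCAGACGATTCAGGCAATCG"))
  rs <- read_set(c("f", "r"),
                 c(substr(ref[["u1"]], 3, 14),
                   oracle_revcomp(substr(ref[["u1"]], 5, 16))),
                 rep(phred_encode(rep(30L, 12)), 2))
  aln <- align_readset(rs, ref, seed = 1)
  fp <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, rs, ref, fp)
  lines <- readLines(fp)
  expect_identical(lines[2], "@SQ\tSN:u1\tLN:24")
  body <- strsplit(grep("^[^@]", lines, value = TRUE), "\t")
  expect_length(body, 2L)
  flags <- vapply(body, `[[`, character(1), 2)
  expect_setequal(flags, c("0", "16"))
  # reverse-strand read written reverse-complemented == reference window
  rrec <- body[[which(flags == "16")]]
  expect_identical(rrec[10], substr(ref[["u1"]], 5, 16))
  expect_true(all(grepl("^NM:i:0$", vapply(body, `[[`, character(1), 12))))
})
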
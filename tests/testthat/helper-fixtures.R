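# Shared simulated fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small end-to-end fixture: 10 unigenes, used by module tests.
small_fixture <- function() {
  memoise_fixture("small", function() {
    truth <- simulate_diverged_pair(n_unigenes = 10, length_mean = 600,
                                    length_sd = 60, seed = 421)
    ra <- simulate_reads(truth, "A", depth_target = 20, error_rate = 0.01,
                         seed = 422)
    rc <- simulate_reads(truth, "C", depth_target = 20, error_rate = 0.01,
                         seed = 423)
    pair <- build_cured_pair(truth$ancestral, ra, rc,
                             curing_config(rng_seed = 424))
    list(truth = truth, reads_a = ra, reads_c = rc, pair = pair,
         ihp = compare_references(pair$a_ref, pair$c_ref))
  })
}

# Full-scale fixture: 200 unigenes x ~1 kb, 3% divergence, 30x coverage,
# 1% sequencing error, 6 curing cycles — the generator's default study
# conditions. Built once; used by the end-to-end recovery tests.
recovery_fixture <- function() {
  memoise_fixture("recovery", function() {
    truth <- simulate_diverged_pair(n_unigenes = 200, seed = 1001)
    ra <- simulate_reads(truth, "A", depth_target = 30, error_rate = 0.01,
                         seed = 1002)
    rc <- simulate_reads(truth, "C", depth_target = 30, error_rate = 0.01,
                         seed = 1003)
    pair <- build_cured_pair(truth$ancestral, ra, rc,
                             curing_config(rng_seed = 1004))
    list(truth = truth, reads_a = ra, reads_c = rc, pair = pair,
         ihp = compare_references(pair$a_ref, pair$c_ref))
  })
}

# Per-unigene read coverage vectors from a simulated read set's true
# origins (start positions known by construction, no alignment involved).
coverage_vectors <- function(reads, lens, read_length = 80L) {
  origins <- attr(reads, "origins")
  starts <- split(origins$start, origins$unigene)
  out <- lapply(names(lens), function(u) {
    M <- lens[[u]]
    st <- starts[[u]]
    if (is.null(st)) return(integer(M))
    delta <- integer(M + 1L)
    inc <- tabulate(st + 1L, nbins = M)
    dec <- tabulate(pmin(st + read_length, M) + 1L, nbins = M + 1L)
    cumsum(inc - dec[seq_len(M)])
  })
  names(out) <- names(lens)
  out
}

# True coverage at each planted divergent position, for one genome's reads.
coverage_at_positions <- function(reads, lens, div, read_length = 80L) {
  cov <- coverage_vectors(reads, lens, read_length)
  vapply(seq_len(nrow(div)), function(i) {
    cov[[div$unigene[i]]][div$pos[i] + 1L]
  }, integer(1))
}

# The planted divergence rows where one genome differs from the ancestor.
divergent_rows <- function(truth, genome = c("A", "C")) {
  genome <- match.arg(genome)
  div <- truth$divergence
  anc <- substring(unclass(truth$ancestral)[div$unigene],
                   div$pos + 1L, div$pos + 1L)
  if (genome == "A") div[div$base_a != anc, , drop = FALSE]
  else div[div$base_c != anc, , drop = FALSE]
}

base_at <- function(ref, unigene, pos0) {
  substring(unclass(ref)[unigene], pos0 + 1L, pos0 + 1L)
}
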
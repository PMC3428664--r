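# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All user-facing stochastic entry points
# funnel their seeds through here so that runs are reproducible without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic derived seed for stage `i` of a multi-stage run, kept within
# the 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 104729) %% 2147483647)
}

#' Decode an ASCII-encoded quality string to Phred integers
#'
#' @param qual character vector of quality strings.
#' @param offset ASCII offset: 33 for Sanger, 64 for legacy Illumina 1.3.
#' @return a list of integer vectors, one per input string.
#' @export
phred_decode <- function(qual, offset = 33L) {
  lapply(qual, function(q) utf8ToInt(q) - as.integer(offset))
}

#' Encode Phred integers as a Sanger (offset 33) quality string
#'
#' @param phred an integer vector of Phred scores in `[0, 93]`.
#' @return a single quality string.
#' @export
phred_encode <- function(phred) {
  stopifnot(all(phred >= 0L & phred <= 93L))
  if (length(phred) == 0L) return("")
  intToUtf8(phred + 33L)
}

# Translate a whole vector of quality strings between ASCII offsets.
shift_qual_encoding <- function(qual, from = 64L, to = 33L) {
  delta <- as.integer(from) - as.integer(to)
  lo <- min(utf8ToInt(paste(qual, collapse = "")), Inf)
  if (is.finite(lo) && lo - from < 0) {
    stop("quality characters below the declared encoding offset; ",
         "wrong encoding selected?", call. = FALSE)
  }
  old <- intToUtf8(seq.int(from, from + 93L))
  new <- intToUtf8(seq.int(to, to + 93L))
  chartr(old, new, qual)
}

reverse_complement <- function(x) {
  rc <- chartr("ACGTN", "TGCAN", x)
  vapply(rc, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

assert_dna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf(
      "%s contains characters outside {A,C,G,T,N} (first offender: '%s')",
      what, names(x)[bad][1] %||% which(bad)[1]), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
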
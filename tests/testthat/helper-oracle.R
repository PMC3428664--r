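# Independent oracles used to validate the package implementations.
# These are deliberately naive and share no code with the package internals.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Exhaustive ungapped scan of one read over every offset and both strands.
# N on either side counts as a mismatch. Returns the minimal mismatch count
# and every placement achieving it.
oracle_align <- function(read, ref, cap = Inf) {
  n_code <- utf8ToInt("N")
  best <- Inf
  placements <- list()
  L <- nchar(read)
  for (u in names(ref)) {
    s <- utf8ToInt(ref[[u]])
    M <- length(s)
    if (L > M) next
    for (orient in c("+", "-")) {
      r <- utf8ToInt(if (orient == "+") read else oracle_revcomp(read))
      n_off <- M - L + 1L
      mm <- integer(n_off)
      for (j in seq_len(L)) {
        seg <- s[j:(j + n_off - 1L)]
        mm <- mm + as.integer(seg != r[j] | seg == n_code | r[j] == n_code)
      }
      hit <- which(mm <= min(best, cap))
      for (o in hit) {
        if (mm[o] < best) {
          best <- mm[o]
          placements <- list()
        }
        if (mm[o] == best) {
          placements[[length(placements) + 1L]] <-
            data.frame(unigene = u, start = o - 1L, strand = orient,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(mm = best,
       placements = if (length(placements)) do.call(rbind, placements)
                    else data.frame(unigene = character(0), start = integer(0),
                                    strand = character(0)))
}

# Textbook Benjamini-Hochberg step-up: sort, scale by m/rank, enforce
# monotonicity from the largest p downwards, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random test reference: unigenes of uniform random bases.
random_reference <- function(n_unigenes, min_len, max_len) {
  lens <- sample(min_len:max_len, n_unigenes, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("u", seq_len(n_unigenes))
  unigene_reference(seqs)
}

# Reads sampled from a reference with a planted number of substitutions,
# plus optional fully random reads.
mutate_bases <- function(seq, n_subs) {
  if (n_subs == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

sample_read_from <- function(ref, read_length, n_subs = 0L) {
  u <- sample(names(ref), 1L)
  M <- nchar(ref[[u]])
  start <- sample.int(M - read_length + 1L, 1L) - 1L
  s <- substr(ref[[u]], start + 1L, start + read_length)
  s <- mutate_bases(s, n_subs)
  if (runif(1) < 0.5) s <- oracle_revcomp(s)
  s
}

random_read <- function(read_length) {
  paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
        collapse = "")
}
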
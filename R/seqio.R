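# seqio: sequence containers and FASTA/FASTQ input/output.

#' Construct a unigene reference
#'
#' A unigene reference is an ordered, named set of nucleotide sequences over
#' the alphabet `{A,C,G,T,N}` — either the original consensus assembly (the
#' "naive" reference) or one of its genome-cured derivatives. Internally it
#' is a named character vector with class `unigene_reference`.
#'
#' @param sequences named character vector of sequences; lowercase input is
#'   uppercased. Identifiers must be unique and sequences non-empty.
#' @return a `unigene_reference` object.
#' @export
unigene_reference <- function(sequences) {
  ids <- names(sequences)
  if (length(sequences) > 0 &&
      (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))) {
    stop("every sequence needs a non-empty identifier", call. = FALSE)
  }
  sequences <- setNames(toupper(as.character(sequences)),
                        ids %||% character(0))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate unigene identifier: '%s'",
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  if (any(!nzchar(sequences))) {
    stop("empty sequences are not allowed", call. = FALSE)
  }
  assert_dna_alphabet(sequences, "reference")
  structure(sequences, class = "unigene_reference")
}

#' @export
print.unigene_reference <- function(x, ...) {
  cat(sprintf("unigene_reference: %d sequences, %s bases total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' @export
`[.unigene_reference` <- function(x, i) {
  unigene_reference(NextMethod())
}

#' Read a unigene reference from FASTA
#'
#' Identifiers are the header token up to the first whitespace; sequence is
#' uppercased; record order is preserved. Ambiguity codes other than `N` are
#' rejected because all downstream curing and polymorphism logic is defined
#' only over `{A,C,G,T,N}`.
#'
#' @param path path to a FASTA file (may be gzip-compressed).
#' @return a [unigene_reference].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  unigene_reference(seqs)
}

#' Write a unigene reference to FASTA
#'
#' @param ref a [unigene_reference].
#' @param path output path.
#' @param line_width wrap width for sequence lines (default 80 columns).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(ref, path, line_width = 80L) {
  stopifnot(line_width >= 1L)
  x <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta",
                              width = as.integer(line_width))
  invisible(path)
}

#' Construct a read set
#'
#' A read set holds fixed-length short reads with per-base Phred qualities
#' (stored Sanger-encoded, offset 33) plus sample metadata. The genome tag
#' records provenance: a diploid progenitor (`"A"` or `"C"`), a polyploid
#' sample, or unknown.
#'
#' @param id,seq,qual parallel character vectors: read identifiers, bases
#'   over `{A,C,G,T,N}`, and Sanger-encoded quality strings of equal length.
#' @param sample sample label.
#' @param genome_tag one of `"A"`, `"C"`, `"polyploid"`, `"unknown"`.
#' @param variable_length set `TRUE` to permit mixed read lengths.
#' @return a `read_set` object.
#' @export
read_set <- function(id, seq, qual, sample = "", genome_tag = "unknown",
                     variable_length = FALSE) {
  genome_tag <- match.arg(genome_tag, c("A", "C", "polyploid", "unknown"))
  seq <- toupper(seq)
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) {
    i <- which(nchar(seq) != nchar(qual))[1]
    stop(sprintf("read '%s': %d bases but %d quality values",
                 id[i], nchar(seq[i]), nchar(qual[i])), call. = FALSE)
  }
  assert_dna_alphabet(seq, "read")
  lens <- unique(nchar(seq))
  if (!variable_length && length(lens) > 1) {
    stop("reads of mixed length in a fixed-length set; ",
         "pass variable_length = TRUE to allow", call. = FALSE)
  }
  structure(
    list(id = as.character(id), seq = seq, qual = qual,
         sample = sample, genome_tag = genome_tag,
         read_length = if (length(lens) == 1) lens else NA_integer_,
         variable_length = variable_length),
    class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads (%s bp), sample='%s', genome=%s\n",
              length(x$id),
              if (is.na(x$read_length)) "variable" else x$read_length,
              x$sample, x$genome_tag))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$id)

#' Read short reads from FASTQ
#'
#' Qualities are decoded with the declared ASCII offset — 33 for Sanger
#' (the default) or 64 for legacy Illumina 1.3 — and stored internally as
#' Sanger. The encoding is never auto-detected: the caller states it.
#'
#' @param path path to a 4-line-record FASTQ file (may be gzipped).
#' @param encoding `"sanger"` (offset 33) or `"illumina13"` (offset 64).
#' @param sample,genome_tag metadata attached to the returned set.
#' @param variable_length allow mixed read lengths.
#' @return a [read_set].
#' @export
read_fastq <- function(path, encoding = c("sanger", "illumina13"),
                       sample = "", genome_tag = "unknown",
                       variable_length = FALSE) {
  encoding <- match.arg(encoding)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  parsed <- tryCatch({
    x <- Biostrings::readBStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
    list(seqs = unname(toupper(as.character(x))),
         quals = unname(as.character(S4Vectors::mcols(x)$qualities)),
         ids = sub("\\s.*$", "", names(x)))
  }, error = function(e) {
    stop(sprintf("malformed FASTQ in '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  seqs <- parsed$seqs
  quals <- parsed$quals
  if (any(nchar(seqs, type = "bytes") != nchar(quals, type = "bytes"))) {
    i <- which(nchar(seqs, type = "bytes") != nchar(quals, type = "bytes"))[1]
    stop(sprintf("FASTQ record %d in '%s': sequence and quality lengths differ",
                 i, path), call. = FALSE)
  }
  offset <- if (encoding == "sanger") 33L else 64L
  if (length(quals) > 0) {
    codes <- suppressWarnings(utf8ToInt(paste(quals, collapse = "")))
    if (anyNA(codes) || any(codes == 0L)) {
      stop(sprintf("malformed FASTQ in '%s': invalid quality characters",
                   path), call. = FALSE)
    }
    if (length(codes) > 0 &&
        (min(codes) < offset || max(codes) > offset + 93L)) {
      stop(sprintf(
        "quality characters outside the %s range in '%s'; wrong encoding?",
        encoding, path), call. = FALSE)
    }
    if (encoding == "illumina13") {
      quals <- shift_qual_encoding(quals, from = 64L, to = 33L)
    }
  }
  read_set(id = parsed$ids, seq = seqs, qual = quals,
           sample = sample, genome_tag = genome_tag,
           variable_length = variable_length)
}

#' Write a read set to Sanger FASTQ
#'
#' @param reads a [read_set].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# Concatenate read sets (used when merging split-read halves for pileups).
combine_read_sets <- function(a, b) {
  read_set(id = c(a$id, b$id), seq = c(a$seq, b$seq), qual = c(a$qual, b$qual),
           sample = a$sample, genome_tag = a$genome_tag,
           variable_length = a$variable_length || b$variable_length ||
             !identical(a$read_length, b$read_length))
}
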
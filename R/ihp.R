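# ihp: inter-homoeologue polymorphism calling from a cured reference pair.

#' Compare the A-cured and C-cured references base by base
#'
#' Every position at which the two cured versions of a unigene carry
#' different bases, neither being `N`, is an inter-homoeologue polymorphism
#' (IHP). Positions where either version remained `N` (uncallable during
#' curing) are silently non-comparable.
#'
#' @param a_ref,c_ref [unigene_reference]s with identical identifiers and
#'   per-unigene lengths.
#' @return an `ihp_table`: `records` (data frame `unigene`, `pos` (0-based),
#'   `base_a`, `base_c`), `per_unigene` (data frame `unigene`, `length`,
#'   `n_ihp`, `density_per_kb` for unigenes with at least one IHP) and
#'   `n_unigenes_total`.
#' @export
compare_references <- function(a_ref, c_ref) {
  if (!identical(names(a_ref), names(c_ref))) {
    stop("references do not share the same unigene identifiers", call. = FALSE)
  }
  if (!identical(nchar(unclass(a_ref)), nchar(unclass(c_ref)))) {
    stop("references do not share per-unigene lengths", call. = FALSE)
  }
  recs <- lapply(names(a_ref), function(u) {
    a <- utf8ToInt(a_ref[[u]])
    b <- utf8ToInt(c_ref[[u]])
    n <- utf8ToInt("N")
    i <- which(a != b & a != n & b != n)
    if (length(i) == 0) return(NULL)
    data.frame(unigene = u, pos = i - 1L,
               base_a = strsplit(intToUtf8(a[i]), "")[[1]],
               base_c = strsplit(intToUtf8(b[i]), "")[[1]],
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, c(list(data.frame(
    unigene = character(0), pos = integer(0), base_a = character(0),
    base_c = character(0), stringsAsFactors = FALSE)), recs))
  counts <- table(factor(records$unigene, levels = names(a_ref)))
  with_ihp <- names(counts)[counts > 0]
  per_unigene <- data.frame(
    unigene = with_ihp,
    length = nchar(unclass(a_ref))[with_ihp],
    n_ihp = as.integer(counts[with_ihp]),
    stringsAsFactors = FALSE, row.names = NULL)
  per_unigene$density_per_kb <- per_unigene$n_ihp * 1000 / per_unigene$length
  structure(list(records = records, per_unigene = per_unigene,
                 n_unigenes_total = length(a_ref)),
            class = "ihp_table")
}

#' @export
print.ihp_table <- function(x, ...) {
  cat(sprintf("ihp_table: %d IHPs in %d / %d unigenes\n",
              nrow(x$records), nrow(x$per_unigene), x$n_unigenes_total))
  invisible(x)
}

#' Summarise an IHP table
#'
#' The mean density is computed over the unigenes that contain at least one
#' IHP (the subset an apportioning analysis can act on); the denominator of
#' each per-unigene density is the full unigene length.
#'
#' @param table an `ihp_table` from [compare_references()].
#' @return a list: `n_unigenes_with_ihps`, `total_ihps`,
#'   `mean_density_per_kb`, `max_density_per_kb`, and `count_histogram`
#'   (table of per-unigene IHP counts).
#' @export
ihp_summary <- function(table) {
  pu <- table$per_unigene
  if (nrow(pu) == 0) {
    return(list(n_unigenes_with_ihps = 0L, total_ihps = 0L,
                mean_density_per_kb = 0, max_density_per_kb = 0,
                count_histogram = table(integer(0))))
  }
  list(n_unigenes_with_ihps = nrow(pu),
       total_ihps = sum(pu$n_ihp),
       mean_density_per_kb = mean(pu$density_per_kb),
       max_density_per_kb = max(pu$density_per_kb),
       count_histogram = table(pu$n_ihp))
}

#' Write an IHP table as TSV (positions 1-based)
#'
#' @param table an `ihp_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ihp_tsv <- function(table, path) {
  out <- table$records
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IHP table written by [write_ihp_tsv()]
#'
#' @param path TSV path.
#' @param lengths optional named vector of unigene lengths; required to
#'   recompute densities, otherwise densities are omitted.
#' @return an `ihp_table` (with `per_unigene` densities only when `lengths`
#'   is supplied).
#' @export
read_ihp_tsv <- function(path, lengths = NULL) {
  records <- read.delim(path, stringsAsFactors = FALSE)
  records$pos <- records$pos - 1L
  counts <- table(records$unigene)
  per_unigene <- data.frame(unigene = names(counts),
                            length = NA_integer_,
                            n_ihp = as.integer(counts),
                            stringsAsFactors = FALSE, row.names = NULL)
  per_unigene$density_per_kb <- NA_real_
  if (!is.null(lengths)) {
    per_unigene$length <- as.integer(lengths[per_unigene$unigene])
    per_unigene$density_per_kb <-
      per_unigene$n_ihp * 1000 / per_unigene$length
  }
  structure(list(records = records, per_unigene = per_unigene,
                 n_unigenes_total = NA_integer_),
            class = "ihp_table")
}
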
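#' Normalize gene symbols to a canonical case
#'
#' Gene identity in this package is case-insensitive: mouse symbols appear in
#' mixed case across sources (DEG callers, network files, STRING aliases,
#' literature lexica). All identifiers are folded to the mouse convention --
#' first character upper case, remainder lower case -- at every I/O boundary,
#' so that downstream set operations can use plain string equality.
#'
#' @param x character vector of gene symbols.
#' @return character vector of the same length, canonical case, with
#'   surrounding whitespace removed.
#' @examples
#' normalize_gene(c("GATA3", "gata3", " Tnf "))
#' @export
normalize_gene <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  x <- trimws(x)
  bad <- !nzchar(x) | is.na(x)
  if (any(bad)) stop("gene symbols must be non-empty strings", call. = FALSE)
  paste0(toupper(substr(x, 1L, 1L)), tolower(substring(x, 2L)))
}

#' Competition ranks from scores
#'
#' Ranks a numeric vector so that tied items share the best rank of their
#' block and the next distinct item gets 1 + the number of strictly better
#' items ("1224" ranking, the convention used throughout the pipeline).
#'
#' @param score numeric vector; by default larger is better.
#' @param decreasing if `TRUE` (default) larger scores rank first.
#' @return integer vector of ranks, same length as `score`.
#' @examples
#' competition_rank(c(0.9, 0.9, 0.1))  # 1 1 3
#' @export
competition_rank <- function(score, decreasing = TRUE) {
  if (length(score) == 0L) return(integer(0))
  key <- if (decreasing) -as.numeric(score) else as.numeric(score)
  as.integer(rank(key, ties.method = "min"))
}
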
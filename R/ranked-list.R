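#' Ranked gene list
#'
#' A `ranked_genes` object is a data frame with (at least) columns `rank`
#' (competition ranks), `gene` (canonical symbols) and `score`, sorted by rank
#' and then by gene symbol. The lexicographic tie-break fixes the presentation
#' order of tied genes only; tied genes keep equal rank values, so nothing
#' downstream may depend on the cosmetic order.
#'
#' @param gene character vector of gene symbols.
#' @param score numeric score per gene; larger means higher priority.
#' @param extra optional data frame of per-gene annotation columns, parallel
#'   to `gene`, carried through the sort.
#' @return a `ranked_genes` data frame with columns `rank`, `gene`, `score`
#'   plus any `extra` columns.
#' @export
ranked_genes <- function(gene, score, extra = NULL) {
  gene <- normalize_gene(as.character(gene))
  if (anyDuplicated(gene)) stop("duplicate genes in ranked list", call. = FALSE)
  score <- as.numeric(score)
  stopifnot(length(gene) == length(score))
  out <- data.frame(rank = competition_rank(score), gene = gene,
                    score = score, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == length(gene))
    out <- cbind(out, extra)
  }
  ord <- order(out$rank, out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' @export
print.ranked_genes <- function(x, n = 10L, ...) {
  cat(sprintf("Ranked gene list: %d genes\n", nrow(x)))
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(as.data.frame(x), n))
    if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  }
  invisible(x)
}

#' Write a ranked gene list to TSV
#'
#' Serializes the final ranking with one row per gene and the columns
#' `rank, gene, relevance_score, relevance_rank, ppi_distance, ppi_rank,
#' borda_points` (missing annotation columns are written as `NA`; infinite
#' PPI distances as the string `Inf`). Output is bit-stable for identical
#' input.
#'
#' @param x a `ranked_genes` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_ranked_list()]
#' @export
write_ranked_list <- function(x, path) {
  cols <- c("rank", "gene", "relevance_score", "relevance_rank",
            "ppi_distance", "ppi_rank", "borda_points")
  out <- as.data.frame(x)
  for (cl in setdiff(cols, names(out))) out[[cl]] <- rep(NA, nrow(out))
  out <- out[, cols, drop = FALSE]
  con <- file(path, open = "wb")  # binary: fixed "\n" EOL on every platform
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0L) {
    fmt <- function(v) {
      s <- vapply(v, function(e) format(e, digits = 15, scientific = FALSE,
                                        trim = TRUE), character(1))
      s[is.na(v)] <- "NA"
      s
    }
    lines <- do.call(paste, c(lapply(out, fmt), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a ranked gene list written by [write_ranked_list()]
#'
#' @param path file written by [write_ranked_list()].
#' @return a `ranked_genes` data frame with the full annotation columns.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rank", "gene", "borda_points")
  if (!all(need %in% names(df)))
    stop("not a ranked-list file: ", path, call. = FALSE)
  df$rank <- as.integer(df$rank)
  df$gene <- if (nrow(df)) normalize_gene(df$gene) else character(0)
  df$ppi_distance <- as.numeric(df$ppi_distance)
  score <- as.numeric(df$borda_points)
  if (nrow(df) && all(is.na(score))) score <- as.numeric(df$relevance_score)
  df$score <- score
  df <- df[, c("rank", "gene", "score", "relevance_score", "relevance_rank",
               "ppi_distance", "ppi_rank", "borda_points"), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ranked_genes", "data.frame")
  df
}
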
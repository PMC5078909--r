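#' Differential-expression call table
#'
#' Constructs the `deg_table` container: one row per gene with an optional
#' numeric DE score and a logical DEG flag. Gene symbols are case-normalized;
#' duplicated genes keep their first occurrence with a warning.
#'
#' @param gene character vector of gene symbols.
#' @param is_deg logical DEG call per gene (default all `TRUE`).
#' @param de_score optional numeric score per gene (`NA` allowed).
#' @return a `deg_table` data frame with columns `gene`, `de_score`, `is_deg`.
#' @export
deg_table <- function(gene, is_deg = TRUE, de_score = NA_real_) {
  gene <- normalize_gene(gene)
  n <- length(gene)
  is_deg <- rep_len(as.logical(is_deg), n)
  de_score <- rep_len(as.numeric(de_score), n)
  dup <- duplicated(gene)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene row(s) dropped, keeping first occurrence",
            call. = FALSE)
    gene <- gene[!dup]; is_deg <- is_deg[!dup]; de_score <- de_score[!dup]
  }
  out <- data.frame(gene = gene, de_score = de_score, is_deg = is_deg,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Read a DEG table from TSV
#'
#' Expects a header line and a gene-id column; a DE-status column (logical or
#' 0/1) and/or a numeric score column are optional. Rows whose gene field is
#' empty are rejected; duplicate genes keep the first occurrence with a
#' warning.
#'
#' @param path TSV file path.
#' @param gene_col,status_col,score_col column names; `status_col`/`score_col`
#'   are used only if present in the header.
#' @return a `deg_table` data frame.
#' @export
read_deg_table <- function(path, gene_col = "gene", status_col = "is_deg",
                           score_col = "de_score") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty DEG table: ", path, call. = FALSE)
  if (!gene_col %in% names(df))
    stop("DEG table lacks gene column '", gene_col, "': ", path, call. = FALSE)
  keep <- nzchar(trimws(df[[gene_col]]))
  if (!all(keep)) {
    warning(sum(!keep), " malformed DEG row(s) dropped", call. = FALSE)
    df <- df[keep, , drop = FALSE]
  }
  is_deg <- if (status_col %in% names(df)) {
    v <- tolower(trimws(df[[status_col]]))
    v %in% c("true", "t", "1", "yes", "deg")
  } else TRUE
  de_score <- if (score_col %in% names(df)) {
    suppressWarnings(as.numeric(df[[score_col]]))
  } else NA_real_
  deg_table(df[[gene_col]], is_deg = is_deg, de_score = de_score)
}

#' Directed transcription-factor regulatory network
#'
#' Builds the `regulatory_network` container from a directed edge list and a
#' transcription-factor list. Edges whose source is not a listed TF are
#' dropped (with a message of the count), as are self-loops.
#'
#' @param from,to character vectors: directed edges `from -> to`.
#' @param tf_set character vector of transcription-factor symbols.
#' @return a `regulatory_network`: list with `tf_set`, `edges` (two-column
#'   data frame) and `graph` (directed [igraph::igraph] object).
#' @export
regulatory_network <- function(from, to, tf_set) {
  tf_set <- unique(normalize_gene(tf_set))
  if (length(tf_set) == 0L) stop("empty TF list", call. = FALSE)
  stopifnot(length(from) == length(to))
  if (length(from)) {
    from <- normalize_gene(from); to <- normalize_gene(to)
    self <- from == to
    if (any(self)) {
      warning(sum(self), " self-loop edge(s) dropped", call. = FALSE)
      from <- from[!self]; to <- to[!self]
    }
    bad_src <- !(from %in% tf_set)
    if (any(bad_src)) {
      message(sum(bad_src), " edge(s) with non-TF source dropped")
      from <- from[!bad_src]; to <- to[!bad_src]
    }
    dup <- duplicated(paste(from, to, sep = "\r"))
    from <- from[!dup]; to <- to[!dup]
  }
  edges <- data.frame(from = as.character(from), to = as.character(to),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = unique(c(edges$from, edges$to)))
  structure(list(tf_set = tf_set, edges = edges, graph = g),
            class = "regulatory_network")
}

#' Read a directed TF-network edge list
#'
#' @param path two-column TSV (`source`, `target`), with or without header
#'   (a header row is detected by the literal column names).
#' @param tf_list path to a TF list, one symbol per line.
#' @return a `regulatory_network`.
#' @export
read_directed_edges <- function(path, tf_list) {
  tfs <- readLines(tf_list, warn = FALSE)
  tfs <- trimws(tfs); tfs <- tfs[nzchar(tfs)]
  if (length(tfs) == 0L) stop("empty TF list: ", tf_list, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("edge list needs two columns: ", path, call. = FALSE)
  if (nrow(df) && tolower(df[1, 1]) %in% c("source", "from", "tf"))
    df <- df[-1, , drop = FALSE]
  regulatory_network(df[[1]], df[[2]], tf_set = tfs)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d TFs, %d directed edges, %d nodes\n",
              length(x$tf_set), nrow(x$edges), igraph::vcount(x$graph)))
  invisible(x)
}

#' Undirected confidence-weighted protein-protein interaction network
#'
#' Builds the `interaction_network` container. Edges are undirected; duplicate
#' pairs (in either orientation) are collapsed keeping the maximum score;
#' self-loops are dropped; scores must lie in \[0, 1000\] (the STRING
#' combined-score convention).
#'
#' @param a,b character vectors: interacting pairs.
#' @param score integer combined scores in \[0, 1000\].
#' @param min_score minimum combined score retained (default 400, STRING's
#'   medium confidence).
#' @return an `interaction_network`: list with `edges` (data frame `a`, `b`,
#'   `score`, with `a < b`) and `graph` (undirected igraph object).
#' @export
interaction_network <- function(a, b, score, min_score = 400L) {
  stopifnot(length(a) == length(b), length(a) == length(score))
  score <- as.numeric(score)
  if (any(!is.finite(score) | score < 0 | score > 1000))
    stop("PPI combined score outside [0, 1000]", call. = FALSE)
  if (length(a)) {
    a <- normalize_gene(a); b <- normalize_gene(b)
    self <- a == b
    a <- a[!self]; b <- b[!self]; score <- score[!self]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    score <- vapply(split(score, key), max, numeric(1))
    pair <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
    keep <- score >= min_score
    edges <- data.frame(a = pair[keep, 1], b = pair[keep, 2],
                        score = unname(score[keep]), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(0), b = character(0), score = numeric(0))
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = unique(c(edges$a, edges$b)))
  structure(list(edges = edges, graph = g, min_score = min_score),
            class = "interaction_network")
}

#' Read a STRING-style PPI edge list
#'
#' @param path three-column TSV (`protein1`, `protein2`, `combined_score`),
#'   header optional.
#' @param min_score minimum combined score retained (default 400).
#' @return an `interaction_network`.
#' @export
read_ppi <- function(path, min_score = 400L) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("PPI file needs three columns: ", path, call. = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[1, 3]))))
    df <- df[-1, , drop = FALSE]
  score <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(score)) stop("non-numeric PPI score in: ", path, call. = FALSE)
  interaction_network(df[[1]], df[[2]], score, min_score = min_score)
}

#' Write a PPI network back to TSV (three columns, no header)
#' @param x an `interaction_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(x, path) {
  utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("PPI network: %d edges (combined score >= %d), %d proteins\n",
              nrow(x$edges), as.integer(x$min_score), igraph::vcount(x$graph)))
  invisible(x)
}
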
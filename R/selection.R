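#' Candidate-selection configuration
#'
#' Parameters for the two selection filters.
#'
#' `tf_mode` controls how "affected by the knockout / affecting other DEGs"
#' is applied:
#' \describe{
#'   \item{`"reachable"`}{(default) keep DEG genes reachable from the knockout
#'     gene by directed regulatory paths. Terminal targets of the knockout are
#'     kept: they are biologically valid candidates.}
#'   \item{`"strict"`}{additionally require at least one outgoing regulatory
#'     edge to another DEG (the literal conjunction of both exclusion
#'     clauses).}
#'   \item{`"regulator"`}{keep genes reachable from the knockout *or*
#'     regulating another DEG.}
#' }
#'
#' @param tf_mode one of `"reachable"`, `"strict"`, `"regulator"`.
#' @param max_depth maximum regulatory path length followed from the knockout
#'   gene; `Inf` (default) follows paths of any length, `1` gives the
#'   direct-target-only reading.
#' @param max_snv_rate maximum tolerated variant rate in variants per kb
#'   (default 3.0); genes above it are discarded as plausible genetic-
#'   background effects. `Inf` disables the filter.
#' @return a `selection_config` list.
#' @export
selection_config <- function(tf_mode = c("reachable", "strict", "regulator"),
                             max_depth = Inf, max_snv_rate = 3.0) {
  tf_mode <- match.arg(tf_mode)
  if (!(is.infinite(max_depth) || (max_depth >= 1 && max_depth == floor(max_depth))))
    stop("max_depth must be a positive integer or Inf", call. = FALSE)
  if (!(is.numeric(max_snv_rate) && max_snv_rate >= 0))
    stop("max_snv_rate must be a non-negative number", call. = FALSE)
  structure(list(tf_mode = tf_mode, max_depth = max_depth,
                 max_snv_rate = max_snv_rate),
            class = "selection_config")
}

#' Genes reachable from a source by directed regulatory paths
#'
#' Directed reachability on the regulatory network: all nodes at the end of a
#' directed path of length between 1 and `max_depth` starting at `source`.
#' The source itself is returned only if it lies on a directed cycle (a path
#' of length >= 1 returns to it). A source absent from the network reaches
#' nothing.
#'
#' @param network a `regulatory_network`.
#' @param source gene symbol.
#' @param max_depth maximum path length (default `Inf`).
#' @return character vector of reachable gene symbols (sorted).
#' @export
reachable_from <- function(network, source, max_depth = Inf) {
  stopifnot(inherits(network, "regulatory_network"))
  source <- normalize_gene(source)
  g <- network$graph
  verts <- igraph::V(g)$name
  if (!(source %in% verts)) return(character(0))
  d <- igraph::distances(g, v = source, to = igraph::V(g), mode = "out")[1, ]
  out <- verts[is.finite(d) & d >= 1 & d <= max_depth]
  # source on a cycle: shortest return path = 1 + min distance back from an
  # out-neighbour
  nb <- igraph::neighbors(g, source, mode = "out")$name
  if (length(nb)) {
    back <- igraph::distances(g, v = nb, to = source, mode = "out")[, 1]
    if (any(is.finite(back)) && (1 + min(back, na.rm = TRUE)) <= max_depth)
      out <- union(out, source)
  }
  sort(out)
}

#' Select candidate DEGs with the TF regulatory network
#'
#' First selection stage: restrict the DEG list to genes whose expression
#' change the regulatory network can explain as a (possibly indirect)
#' consequence of the knockout. The knocked-out gene itself is never a
#' candidate. See [selection_config()] for the three interpretations of the
#' exclusion rule.
#'
#' @param degs a `deg_table`.
#' @param network a `regulatory_network`.
#' @param ko knockout gene symbol.
#' @param cfg a `selection_config`.
#' @return character vector of candidate gene symbols (sorted).
#' @export
tf_filter <- function(degs, network, ko, cfg = selection_config()) {
  stopifnot(inherits(degs, "deg_table"))
  ko <- normalize_gene(ko)
  deg_genes <- sort(setdiff(degs$gene[degs$is_deg], ko))
  reach <- reachable_from(network, ko, cfg$max_depth)
  affected <- intersect(deg_genes, reach)
  if (cfg$tf_mode == "reachable") {
    keep <- affected
  } else {
    # genes with >= 1 outgoing regulatory edge to another DEG
    e <- network$edges
    regulates_deg <- unique(e$from[e$to %in% deg_genes & e$from != e$to])
    regulates_deg <- intersect(deg_genes, regulates_deg)
    keep <- switch(cfg$tf_mode,
                   strict = intersect(affected, regulates_deg),
                   regulator = union(affected, regulates_deg))
  }
  keep <- sort(setdiff(keep, ko))
  if (length(keep) == 0L)
    warning("TF filter left no candidate genes", call. = FALSE)
  keep
}

#' Discard candidates with a high variant rate
#'
#' Second selection stage: genes whose SNV rate in the knockout samples
#' exceeds `max_snv_rate` variants/kb are discarded -- their expression
#' difference may reflect genetic background rather than the knockout. Genes
#' absent from the profile are treated as rate 0 (absence of evidence of
#' genetic difference) and pass.
#'
#' @param candidates character vector of gene symbols.
#' @param profile an `snv_profile`.
#' @param cfg a `selection_config`.
#' @return character vector, the retained subset of `candidates` (sorted).
#' @export
snv_filter <- function(candidates, profile, cfg = selection_config()) {
  if (length(candidates) == 0L) return(character(0))
  candidates <- normalize_gene(candidates)
  stopifnot(inherits(profile, "snv_profile"))
  rate <- stats::setNames(profile$rate, profile$gene)[candidates]
  rate[is.na(rate)] <- 0
  sort(candidates[rate <= cfg$max_snv_rate])
}
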
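#' Shortest interaction path to the knockout gene, in hops
#'
#' Unweighted breadth-first shortest-path length on the score-thresholded PPI
#' network. `Inf` when either endpoint is absent from the network or no path
#' exists; 0 only for the knockout gene itself (which is never a candidate).
#'
#' @param ppi an `interaction_network`.
#' @param ko knockout gene symbol.
#' @param gene character vector of gene symbols.
#' @return numeric vector of hop counts (named by gene), `Inf` where
#'   disconnected.
#' @export
shortest_hops <- function(ppi, ko, gene) {
  stopifnot(inherits(ppi, "interaction_network"))
  ko <- normalize_gene(ko)
  gene <- normalize_gene(gene)
  verts <- igraph::V(ppi$graph)$name
  out <- stats::setNames(rep(Inf, length(gene)), gene)
  out[gene == ko] <- 0
  if (ko %in% verts) {
    d <- igraph::distances(ppi$graph, v = ko, to = igraph::V(ppi$graph),
                           weights = NA)[1, ]
    present <- gene %in% verts
    out[present] <- d[gene[present]]
  }
  out
}

#' Rank candidates by PPI distance to the knockout gene
#'
#' Shorter interaction paths to the knockout gene indicate closer functional
#' coupling, so fewer hops rank first. Competition ranking: all direct
#' interactors share rank 1; genes unreachable in the PPI share the last rank
#' block after all finite distances (they are kept, not dropped). On a dense
#' PPI this ranking alone is extremely tie-heavy, which is why it is fused
#' with the literature ranking rather than used on its own.
#'
#' @param candidates character vector of gene symbols (must not contain the
#'   knockout gene).
#' @param ppi an `interaction_network`.
#' @param ko knockout gene symbol.
#' @return a `ranked_genes` data frame with columns `rank`, `gene`,
#'   `ppi_distance`, `ppi_rank`.
#' @export
rank_by_path <- function(candidates, ppi, ko) {
  ko <- normalize_gene(ko)
  candidates <- sort(unique(normalize_gene(candidates)))
  if (ko %in% candidates)
    stop("knockout gene cannot be a candidate", call. = FALSE)
  hops <- shortest_hops(ppi, ko, candidates)
  # score = -hops so that fewer hops rank first under the shared ranker
  out <- ranked_genes(candidates, -as.numeric(hops))
  out$score <- NULL
  out$ppi_distance <- unname(hops[out$gene])
  out$ppi_rank <- out$rank
  out
}

#' Fuse rankings with an unweighted Borda count
#'
#' Every input list must rank exactly the same gene universe (genes rejected
#' by the relevance stage are excluded from the universe before fusion). Each
#' list awards a gene `N - rank + 1` points, where `N` is the number of genes
#' in the list and `rank` its competition rank there (tied genes receive the
#' full points of their shared rank); points are summed with equal weight per
#' criterion. The fused list is sorted by points, descending, with
#' competition ranks; ties are broken by gene symbol for presentation order
#' only.
#'
#' @param lists a list of `ranked_genes` data frames over the same genes.
#' @param names optional criterion names for the per-list rank columns in the
#'   output (default `rank_1`, `rank_2`, ...).
#' @return a `ranked_genes` data frame with columns `rank`, `gene`,
#'   `borda_points`, plus one source-rank column per input list.
#' @export
borda_combine <- function(lists, names = NULL) {
  stopifnot(is.list(lists), length(lists) >= 1L)
  if (is.null(names)) names <- paste0("rank_", seq_along(lists))
  universe <- sort(lists[[1]]$gene)
  pts <- stats::setNames(numeric(length(universe)), universe)
  src <- list()
  for (i in seq_along(lists)) {
    l <- lists[[i]]
    if (!setequal(l$gene, universe) || length(l$gene) != length(universe)) {
      missing <- setdiff(universe, l$gene)
      extra <- setdiff(l$gene, universe)
      stop("rankings disagree on the gene universe (",
           paste(c(missing, extra), collapse = ", "), ")", call. = FALSE)
    }
    r <- stats::setNames(l$rank, l$gene)[universe]
    pts <- pts + (length(universe) - r + 1)
    src[[names[i]]] <- unname(r)
  }
  out <- ranked_genes(universe, unname(pts),
                      extra = as.data.frame(src, optional = TRUE))
  names(out)[names(out) == "score"] <- "borda_points"
  out
}

#' Select and prioritize candidate genes for a knockout experiment
#'
#' Runs the full pipeline: (1) restrict the DEG list to genes the regulatory
#' network connects to the knockout gene ([tf_filter()]); (2) discard genes
#' with a high variant rate ([snv_filter()]); (3) score and rank the survivors
#' by literature relevance to the context and the knockout gene, rejecting
#' zero-evidence genes ([rank_by_relevance()]); (4) rank the same (surviving)
#' set by PPI hop distance to the knockout ([rank_by_path()]); (5) fuse both
#' rankings with an unweighted Borda count ([borda_combine()]).
#'
#' @param degs a `deg_table`.
#' @param tf_network a `regulatory_network`.
#' @param snv an `snv_profile`, or `NULL` to skip the variant filter.
#' @param ppi an `interaction_network`.
#' @param corp a `corpus` (documents + gene lexicon).
#' @param context a `ko_context` or character vector of keyword phrases.
#' @param ko knockout gene symbol.
#' @param cfg a `selection_config`.
#' @param scorer relevance scorer, `"cosine"` or `"count"`.
#' @param reject_zero drop zero-relevance genes before fusion (default
#'   `TRUE`).
#' @return a `gene_prioritization` object: list with `ranking` (a
#'   `ranked_genes` data frame with the full annotation columns), `rejected`
#'   (zero-evidence genes), `diagnostics` (stage sizes and the effective
#'   configuration) and `ko`.
#' @examples
#' study <- simulate_knockout_study(simulation_config(seed = 7))
#' fit <- prioritize_genes(study$degs, study$tf_network, study$snv,
#'                         study$ppi, study$corpus, study$context, study$ko)
#' head(fit$ranking)
#' @export
prioritize_genes <- function(degs, tf_network, snv, ppi, corp, context, ko,
                             cfg = selection_config(),
                             scorer = c("cosine", "count"),
                             reject_zero = TRUE) {
  scorer <- match.arg(scorer)
  ko <- normalize_gene(ko)
  stages <- list(deg = sum(degs$is_deg))
  cand <- tryCatch(tf_filter(degs, tf_network, ko, cfg),
                   warning = function(w) {
                     warning(w); character(0)
                   })
  stages$tf_filter <- length(cand)
  if (!is.null(snv)) cand <- snv_filter(cand, snv, cfg)
  stages$snv_filter <- length(cand)
  empty <- function(stage) {
    ranking <- ranked_genes(character(0), numeric(0))
    for (cl in c("relevance_score", "relevance_rank", "ppi_distance",
                 "ppi_rank", "borda_points")) ranking[[cl]] <- numeric(0)
    ranking$score <- NULL
    structure(list(ranking = ranking, rejected = character(0),
                   diagnostics = list(stages = stages, empty_after = stage,
                                      config = diag_config(cfg, scorer,
                                                           reject_zero, ppi)),
                   ko = ko),
              class = "gene_prioritization")
  }
  if (length(cand) == 0L) {
    warning("no candidates survive the selection filters", call. = FALSE)
    return(empty(if (stages$tf_filter == 0L) "tf_filter" else "snv_filter"))
  }
  scores <- score_candidates(corp, context, ko, cand, scorer = scorer)
  rel <- rank_by_relevance(scores, reject_zero = reject_zero)
  rejected <- attr(rel, "rejected")
  stages$relevance <- nrow(rel)
  if (nrow(rel) == 0L) {
    warning("all candidates rejected for zero literature relevance",
            call. = FALSE)
    res <- empty("relevance")
    res$rejected <- rejected
    return(res)
  }
  path <- rank_by_path(rel$gene, ppi, ko)
  fused <- borda_combine(list(rel, path),
                         names = c("relevance_rank", "ppi_rank"))
  fused$relevance_score <-
    stats::setNames(rel$relevance_score, rel$gene)[fused$gene]
  fused$ppi_distance <- stats::setNames(path$ppi_distance, path$gene)[fused$gene]
  fused <- fused[, c("rank", "gene", "relevance_score", "relevance_rank",
                     "ppi_distance", "ppi_rank", "borda_points")]
  class(fused) <- c("ranked_genes", "data.frame")
  stages$final <- nrow(fused)
  structure(list(ranking = fused, rejected = rejected,
                 diagnostics = list(stages = stages,
                                    config = diag_config(cfg, scorer,
                                                         reject_zero, ppi)),
                 ko = ko),
            class = "gene_prioritization")
}

diag_config <- function(cfg, scorer, reject_zero, ppi) {
  list(tf_mode = cfg$tf_mode, max_depth = cfg$max_depth,
       max_snv_rate = cfg$max_snv_rate, scorer = scorer,
       reject_zero = reject_zero, ppi_min_score = ppi$min_score)
}

#' @export
print.gene_prioritization <- function(x, n = 10L, ...) {
  cat(sprintf("Gene prioritization for %s knockout\n", x$ko))
  st <- x$diagnostics$stages
  cat("  stage sizes: ",
      paste(sprintf("%s=%d", names(st), unlist(st)), collapse = ", "), "\n",
      sep = "")
  if (length(x$rejected))
    cat(sprintf("  %d gene(s) rejected for zero literature relevance\n",
                length(x$rejected)))
  print(x$ranking, n = n)
  invisible(x)
}

#' @export
summary.gene_prioritization <- function(object, k = 10L, ...) {
  r <- object$ranking
  top <- r$gene[r$rank <= k]
  out <- list(ko = object$ko, n_ranked = nrow(r),
              n_rejected = length(object$rejected),
              stages = object$diagnostics$stages,
              config = object$diagnostics$config, top = top, k = k)
  class(out) <- "summary.gene_prioritization"
  out
}

#' @export
print.summary.gene_prioritization <- function(x, ...) {
  cat(sprintf("Knockout: %s\n", x$ko))
  cat(sprintf("Ranked genes: %d (plus %d rejected for zero relevance)\n",
              x$n_ranked, x$n_rejected))
  st <- x$stages
  cat("Stage sizes: ",
      paste(sprintf("%s=%d", names(st), unlist(st)), collapse = " -> "),
      "\n", sep = "")
  cfg <- x$config
  cat(sprintf("Config: tf_mode=%s, max_depth=%s, max_snv_rate=%s, scorer=%s, ppi_min_score=%s\n",
              cfg$tf_mode, format(cfg$max_depth), format(cfg$max_snv_rate),
              cfg$scorer, format(cfg$ppi_min_score)))
  cat(sprintf("Top %d: %s\n", x$k, paste(x$top, collapse = ", ")))
  invisible(x)
}

#' @export
plot.gene_prioritization <- function(x, n = 20L, ...) {
  r <- utils::head(x$ranking, n)
  if (nrow(r) == 0L) {
    warning("nothing to plot: empty ranking", call. = FALSE)
    return(invisible(x))
  }
  op <- graphics::par(mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(r$borda_points), names.arg = rev(r$gene), horiz = TRUE,
                    las = 1, xlab = "Borda points",
                    main = sprintf("Top candidates (%s knockout)", x$ko), ...)
  invisible(x)
}
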
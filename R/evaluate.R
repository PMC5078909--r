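#' F-measure (harmonic mean of precision and recall)
#'
#' @param precision,recall numeric in \[0, 1\] (vectorized).
#' @return `2 * P * R / (P + R)`, 0 where `P + R == 0`.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Evaluate a ranking against a validated gene set
#'
#' Computes the precision/recall/F protocol: the prediction set is the whole
#' post-rejection ranking (its size is the denominator of precision -- this
#' is what makes precision context-dependent), true positives are ranked
#' genes present in the validated set, and `top_k_hits` counts validated
#' genes at rank <= `k` (all members of a tied rank block at the boundary are
#' included, so the count never depends on the cosmetic order of ties).
#'
#' @param ranked a `ranked_genes` data frame (the prediction set).
#' @param validated character vector of publication-validated gene symbols
#'   (the relevant set; non-empty).
#' @param k top-rank cutoff for `top_k_hits` (default 10).
#' @return an `eval_result` list: `tp`, `predicted`, `relevant`, `precision`,
#'   `recall`, `f_measure`, `top_k_hits`, `k`.
#' @export
evaluate_ranking <- function(ranked, validated, k = 10L) {
  stopifnot(is.data.frame(ranked), all(c("rank", "gene") %in% names(ranked)))
  validated <- unique(normalize_gene(validated))
  if (length(validated) == 0L)
    stop("validated gene set must be non-empty", call. = FALSE)
  genes <- ranked$gene
  tp <- length(intersect(genes, validated))
  predicted <- length(genes)
  relevant <- length(validated)
  P <- if (predicted == 0L) 0 else tp / predicted
  R <- tp / relevant
  structure(list(tp = tp, predicted = predicted, relevant = relevant,
                 precision = P, recall = R, f_measure = f_measure(P, R),
                 top_k_hits = sum(genes %in% validated & ranked$rank <= k),
                 k = as.integer(k)),
            class = "eval_result")
}

#' Precision/recall/F from true-positive and set-size counts
#'
#' Convenience wrapper for recomputing published table cells of the form
#' "reproduced true positives / predicted candidates" against a validated-set
#' size.
#'
#' @param tp true positives.
#' @param predicted size of the prediction set.
#' @param relevant size of the validated set.
#' @return an `eval_result` (with `top_k_hits = NA`).
#' @export
eval_from_counts <- function(tp, predicted, relevant) {
  stopifnot(tp >= 0, predicted >= 0, relevant > 0, tp <= min(predicted, relevant))
  P <- if (predicted == 0) 0 else tp / predicted
  R <- tp / relevant
  structure(list(tp = tp, predicted = predicted, relevant = relevant,
                 precision = P, recall = R, f_measure = f_measure(P, R),
                 top_k_hits = NA_integer_, k = NA_integer_),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, digits = 4L, ...) {
  cat(sprintf("Evaluation: %d/%d predicted, %d relevant\n",
              x$tp, x$predicted, x$relevant))
  cat(sprintf("  precision = %.*f  recall = %.*f  F = %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$f_measure))
  if (!is.na(x$top_k_hits))
    cat(sprintf("  validated genes in top %d: %d\n", x$k, x$top_k_hits))
  invisible(x)
}
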
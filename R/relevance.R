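#' Documents mentioning any phrase of a term set
#'
#' Case-insensitive whole-phrase match with word boundaries: "Il2" matches
#' "... of Il2 in ...", not "Il24". Internal whitespace in a phrase matches
#' any whitespace run in the document.
#'
#' @param corp a `corpus`.
#' @param terms character vector of phrases (non-empty).
#' @return character vector of matching `doc_id`s.
#' @export
mention_docs <- function(corp, terms) {
  stopifnot(inherits(corp, "corpus"))
  terms <- trimws(as.character(terms))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("empty term set", call. = FALSE)
  hit <- rep(FALSE, nrow(corp$docs))
  for (term in terms) {
    esc <- gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", term, perl = TRUE)
    pat <- paste0("(?<![A-Za-z0-9_])",
                  gsub("\\s+", "\\\\s+", esc),
                  "(?![A-Za-z0-9_])")
    hit <- hit | grepl(pat, corp$docs$text, perl = TRUE, ignore.case = TRUE)
  }
  corp$docs$doc_id[hit]
}

#' Literature relevance of a gene to a keyword set
#'
#' Relevance between a set of query phrases and a gene over the local corpus.
#' The default `"cosine"` scorer is the co-occurrence cosine
#' \deqn{|D(q) \cap D(g)| / \sqrt{|D(q)| \, |D(g)|}}
#' where `D(q)` / `D(g)` are the document sets mentioning any query phrase /
#' any gene synonym; it is 0 when either set is empty, and bounded in
#' \[0, 1\]. The `"count"` scorer is the raw co-mention count
#' `|D(q) \cap D(g)|`, useful on corpora too small for normalization to
#' matter. A gene without a lexicon entry (and thus without even its own
#' symbol as synonym) scores 0.
#'
#' @param corp a `corpus` (with lexicon).
#' @param query character vector of query phrases.
#' @param gene gene symbol.
#' @param scorer `"cosine"` (default) or `"count"`.
#' @return non-negative numeric scalar.
#' @export
relevance_score <- function(corp, query, gene, scorer = c("cosine", "count")) {
  scorer <- match.arg(scorer)
  gene <- normalize_gene(gene)
  syn <- corp$lexicon[[gene]]
  if (is.null(syn)) syn <- gene
  dq <- mention_docs(corp, query)
  dg <- mention_docs(corp, syn)
  ov <- length(intersect(dq, dg))
  if (scorer == "count") return(as.numeric(ov))
  if (length(dq) == 0L || length(dg) == 0L) return(0)
  ov / sqrt(length(dq) * length(dg))
}

#' Score candidates against the context and the knockout gene
#'
#' For each candidate, computes the relevance of the gene to every context
#' keyword phrase (the per-gene context score is the maximum over phrases)
#' and to the knockout gene symbol, then combines them as
#' `combined = max(context_score, ko_score)`: a candidate is interesting if
#' the literature ties it to *either* the user's hypothesis or the knocked-out
#' gene.
#'
#' @param corp a `corpus`.
#' @param context a `ko_context` (or character vector of phrases).
#' @param ko knockout gene symbol.
#' @param candidates character vector of candidate symbols.
#' @param scorer `"cosine"` or `"count"`, see [relevance_score()].
#' @return data frame (class `relevance_scores`) with columns `gene`,
#'   `context_score`, `ko_score`, `combined`, ordered by gene symbol.
#' @export
score_candidates <- function(corp, context, ko, candidates,
                             scorer = c("cosine", "count")) {
  scorer <- match.arg(scorer)
  context <- ko_context(unclass(context))
  ko <- normalize_gene(ko)
  ko_terms <- corp$lexicon[[ko]]
  if (is.null(ko_terms)) ko_terms <- ko
  candidates <- sort(unique(normalize_gene(candidates)))
  cs <- vapply(candidates, function(g) {
    if (length(context) == 1L) relevance_score(corp, context, g, scorer)
    else max(vapply(context, function(k) relevance_score(corp, k, g, scorer),
                    numeric(1)))
  }, numeric(1))
  ks <- vapply(candidates, function(g) relevance_score(corp, ko_terms, g,
                                                       scorer), numeric(1))
  out <- data.frame(gene = candidates, context_score = unname(cs),
                    ko_score = unname(ks),
                    combined = pmax(unname(cs), unname(ks)),
                    stringsAsFactors = FALSE)
  class(out) <- c("relevance_scores", "data.frame")
  out
}

#' Rank candidates by literature relevance
#'
#' Sorts by combined relevance, descending, with competition ranks. With
#' `reject_zero = TRUE` (default) genes with no literature evidence at all
#' (combined score 0) are removed from the candidate set entirely -- they do
#' not appear in the final ranking and shrink the prediction denominator, the
#' behaviour that makes precision context-dependent.
#'
#' @param scores a `relevance_scores` data frame.
#' @param reject_zero drop zero-evidence genes (default `TRUE`).
#' @return a `ranked_genes` data frame with an extra `rejected` attribute
#'   holding the dropped gene symbols.
#' @export
rank_by_relevance <- function(scores, reject_zero = TRUE) {
  stopifnot(is.data.frame(scores), all(c("gene", "combined") %in% names(scores)))
  rejected <- character(0)
  keep <- scores
  if (reject_zero) {
    rejected <- sort(scores$gene[scores$combined == 0])
    keep <- scores[scores$combined > 0, , drop = FALSE]
  }
  out <- ranked_genes(keep$gene, keep$combined)
  names(out)[names(out) == "score"] <- "relevance_score"
  out$relevance_rank <- out$rank
  attr(out, "rejected") <- rejected
  out
}
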
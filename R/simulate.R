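#' Configuration for the synthetic knockout-study generator
#'
#' Defaults describe a small but structured mouse TF-knockout experiment:
#' 300 genes of which 30 are transcription factors, a knockout gene whose
#' regulatory cascade (out-degree 5, depth 3) reaches 15 planted true target
#' genes, 60 noise DEGs disconnected from the knockout (the decoys the TF
#' filter must remove), and a 10% SNV-contamination fraction -- contaminated
#' genes are cascade-reachable DEGs given a variant rate far above any
#' sensible threshold, so only the variant filter can remove them.
#'
#' @param n_genes total number of genes (TFs included).
#' @param n_tfs number of transcription factors (>= 3: the knockout, at least
#'   one cascade TF, and one rogue TF regulating decoys).
#' @param ko_out_degree direct regulatory targets of the knockout gene.
#' @param cascade_depth maximum regulatory path length from the knockout.
#' @param n_true_targets planted true targets, reachable from the knockout,
#'   PPI-close, and co-mentioned with the context/knockout in the corpus.
#' @param n_noise_degs noise DEGs disconnected from the knockout.
#' @param snv_contaminated_fraction fraction (of the planted DEG pool,
#'   `n_true_targets + n_noise_degs`) of additional cascade-reachable DEGs
#'   carrying a high variant rate.
#' @param docs_per_planted_gene context co-mention documents per planted gene.
#' @param n_background_docs filler documents (half mention the context phrase
#'   alone, diluting the co-occurrence normalization).
#' @param ppi_attachment mean number of random background PPI edges per
#'   background protein.
#' @param seed RNG seed; the whole bundle is reproducible from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 300L, n_tfs = 30L, ko_out_degree = 5L,
                              cascade_depth = 3L, n_true_targets = 15L,
                              n_noise_degs = 60L,
                              snv_contaminated_fraction = 0.1,
                              docs_per_planted_gene = 3L,
                              n_background_docs = 100L, ppi_attachment = 2,
                              seed = 7L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              ko_out_degree = as.integer(ko_out_degree),
              cascade_depth = as.integer(cascade_depth),
              n_true_targets = as.integer(n_true_targets),
              n_noise_degs = as.integer(n_noise_degs),
              snv_contaminated_fraction = snv_contaminated_fraction,
              docs_per_planted_gene = as.integer(docs_per_planted_gene),
              n_background_docs = as.integer(n_background_docs),
              ppi_attachment = ppi_attachment, seed = as.integer(seed))
  counts <- unlist(cfg[c("n_genes", "n_tfs", "ko_out_degree", "cascade_depth",
                         "n_true_targets", "n_noise_degs",
                         "docs_per_planted_gene", "n_background_docs")])
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$snv_contaminated_fraction < 0 || cfg$snv_contaminated_fraction > 1)
    stop("snv_contaminated_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$n_true_targets + cfg$n_noise_degs > cfg$n_genes)
    stop("planted DEGs exceed the gene universe", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a coherent knockout study with planted ground truth
#'
#' Generates every input the pipeline consumes -- DEG table, TF regulatory
#' network, SNV profile, PPI network, literature corpus with lexicon, context
#' and knockout gene -- plus the planted truth, with these guarantees:
#' \itemize{
#'   \item the knockout regulates a cascade reaching every true target within
#'     `cascade_depth`; noise DEGs are regulated only by a rogue TF
#'     unreachable from the knockout;
#'   \item contaminated genes are cascade-reachable DEGs whose variant rate
#'     (>= 15/kb) exceeds any sensible threshold; all other genes stay below
#'     2/kb;
#'   \item true targets (and contaminated genes) sit within 2 PPI hops of the
#'     knockout; decoys are at least 3 hops away by construction;
#'   \item the corpus co-mentions every true target (and contaminated gene)
#'     with the context phrase and with the knockout gene; decoys are
#'     mentioned only in isolation, so their relevance is exactly 0.
#' }
#'
#' @param cfg a `simulation_config`.
#' @return a `knockout_study` list: `degs`, `tf_network`, `snv`, `ppi`,
#'   `corpus`, `context`, `ko`, `truth` (list `true_targets`, `decoys`,
#'   `contaminated`), `config`.
#' @examples
#' study <- simulate_knockout_study(simulation_config(seed = 1))
#' study$ko
#' length(study$truth$true_targets)
#' @export
simulate_knockout_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_tfs < 3L) stop("need at least 3 TFs", call. = FALSE)
  if (cfg$cascade_depth < 1L) stop("cascade_depth must be >= 1", call. = FALSE)
  set.seed(cfg$seed)

  tfs <- sprintf("Tf%03d", seq_len(cfg$n_tfs))
  genes <- sprintf("Gene%03d", seq_len(cfg$n_genes - cfg$n_tfs))
  ko <- tfs[1]
  rogue <- tfs[cfg$n_tfs]
  cascade_tfs <- tfs[2:(cfg$n_tfs - 1L)]

  n_contam <- round(cfg$snv_contaminated_fraction *
                      (cfg$n_true_targets + cfg$n_noise_degs))
  overhead <- 6L  # PPI adapters (3) + far-side chain (3)
  if (cfg$n_true_targets + cfg$n_noise_degs + n_contam + overhead > length(genes))
    stop("infeasible config: planted genes exceed the non-TF gene pool",
         call. = FALSE)
  pool <- sample(genes)
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  true_targets <- sort(take(cfg$n_true_targets))
  decoys <- sort(take(cfg$n_noise_degs))
  contaminated <- sort(take(n_contam))
  adapters <- take(3L)
  chain <- take(3L)
  background <- pool

  ## --- TF regulatory network: random out-tree rooted at the knockout -------
  lvl1 <- cascade_tfs[seq_len(min(cfg$ko_out_degree, length(cascade_tfs)))]
  edges_from <- rep(ko, length(lvl1)); edges_to <- lvl1
  depth <- stats::setNames(rep(1L, length(lvl1)), lvl1)
  for (tf in setdiff(cascade_tfs, lvl1)) {
    eligible <- names(depth)[depth < cfg$cascade_depth]
    parent <- if (length(eligible)) sample(eligible, 1L) else ko
    edges_from <- c(edges_from, parent); edges_to <- c(edges_to, tf)
    depth[tf] <- if (parent == ko) 1L else depth[parent] + 1L
  }
  attach_to_cascade <- function(targets) {
    parents <- names(depth)[depth <= cfg$cascade_depth - 1L]
    if (length(parents) == 0L) parents <- ko
    p <- sample(parents, length(targets), replace = TRUE)
    edges_from <<- c(edges_from, p); edges_to <<- c(edges_to, targets)
  }
  if (length(true_targets)) attach_to_cascade(true_targets)
  if (length(contaminated)) attach_to_cascade(contaminated)
  if (length(decoys))  # rogue TF is never reached from the knockout
    for (d in decoys) {
      edges_from <- c(edges_from, rogue); edges_to <- c(edges_to, d)
    }
  tf_network <- regulatory_network(edges_from, edges_to, tf_set = tfs)

  ## --- DEG table -----------------------------------------------------------
  deg_genes <- c(true_targets, contaminated, decoys)
  n_nondeg <- min(20L, length(background))
  nondeg <- sort(sample(background, n_nondeg))
  degs <- deg_table(c(deg_genes, nondeg),
                    is_deg = c(rep(TRUE, length(deg_genes)),
                               rep(FALSE, length(nondeg))),
                    de_score = round(stats::runif(length(deg_genes) + n_nondeg,
                                                  0.5, 1), 3))

  ## --- SNV profile ----------------------------------------------------------
  all_genes <- c(tfs, genes)
  len <- sample(1000:3000, length(all_genes), replace = TRUE)
  names(len) <- all_genes
  # clean genes stay strictly below 2 variants/kb by construction
  count <- floor(stats::runif(length(all_genes)) * 2 * len / 1000)
  names(count) <- all_genes
  count[contaminated] <- as.integer(ceiling(len[contaminated] / 1000 * 15) +
                                      stats::rpois(length(contaminated), 5))
  snv <- snv_profile(all_genes, count, len)

  ## --- PPI network: planted genes close, decoys far -------------------------
  pa <- character(0); pb <- character(0)
  add_edge <- function(x, y) {
    pa <<- c(pa, x); pb <<- c(pb, y)
  }
  for (ad in adapters) add_edge(ko, ad)
  if (length(true_targets)) {
    direct <- stats::runif(length(true_targets)) < 0.5
    for (i in seq_along(true_targets))
      add_edge(if (direct[i]) ko else sample(adapters, 1L), true_targets[i])
  }
  for (g in contaminated) add_edge(sample(c(ko, adapters), 1L), g)
  add_edge(ko, chain[1]); add_edge(chain[1], chain[2]); add_edge(chain[2], chain[3])
  far <- c(decoys, background)
  for (g in far) add_edge(sample(chain[2:3], 1L), g)
  # extra density among the far side only: never a shortcut to the knockout
  n_extra <- stats::rpois(1L, cfg$ppi_attachment * length(far))
  if (n_extra > 0L && length(far) >= 2L) {
    x <- sample(far, n_extra, replace = TRUE)
    y <- sample(far, n_extra, replace = TRUE)
    keep <- x != y
    pa <- c(pa, x[keep]); pb <- c(pb, y[keep])
  }
  score <- sample(400:1000, length(pa), replace = TRUE)
  ppi <- interaction_network(pa, pb, score, min_score = 400L)

  ## --- corpus and lexicon ----------------------------------------------------
  context <- ko_context("cell differentiation")
  lexicon <- lapply(stats::setNames(all_genes, all_genes),
                    function(g) c(g, paste0(toupper(g), "-syn")))
  title <- character(0); abstract <- character(0)
  add_doc <- function(t, a) {
    title <<- c(title, t); abstract <<- c(abstract, a)
  }
  planted <- c(true_targets, contaminated)
  for (g in planted) {
    for (i in seq_len(cfg$docs_per_planted_gene))
      add_doc(sprintf("Role of %s in cell differentiation", g),
              sprintf("We show that %s drives cell differentiation in mouse.", g))
    add_doc(sprintf("%s is a target of %s", g, ko),
            sprintf("Loss of %s alters %s expression in knockout mice.", ko, g))
  }
  for (g in decoys)
    add_doc(sprintf("Cloning of %s", g),
            sprintf("The %s locus was characterized.", g))
  add_doc(sprintf("Functions of %s", ko),
          sprintf("%s is a transcription factor studied in mouse.", ko))
  add_doc(sprintf("%s reviews", ko),
          sprintf("A review of %s biology.", ko))
  for (i in seq_len(cfg$n_background_docs)) {
    if (i %% 2L == 0L)
      add_doc("Advances in cell differentiation",
              "General mechanisms of cell differentiation are reviewed.")
    else
      add_doc(sprintf("Background study %d", i),
              "Unrelated laboratory methods are described.")
  }
  corp <- corpus(sprintf("doc%05d", seq_along(title)),
                 trimws(paste(title, abstract)), lexicon = lexicon)
  corp$docs$title <- title
  corp$docs$abstract <- abstract

  structure(list(degs = degs, tf_network = tf_network, snv = snv, ppi = ppi,
                 corpus = corp, context = context, ko = ko,
                 truth = list(true_targets = true_targets, decoys = decoys,
                              contaminated = contaminated),
                 config = cfg),
            class = "knockout_study")
}

#' @export
print.knockout_study <- function(x, ...) {
  cat(sprintf("Synthetic knockout study (seed %d): KO = %s\n",
              x$config$seed, x$ko))
  cat(sprintf("  %d genes, %d TFs; %d true targets, %d decoys, %d contaminated\n",
              x$config$n_genes, x$config$n_tfs,
              length(x$truth$true_targets), length(x$truth$decoys),
              length(x$truth$contaminated)))
  cat(sprintf("  %d DEG calls, %d PPI edges, %d corpus documents\n",
              sum(x$degs$is_deg), nrow(x$ppi$edges), nrow(x$corpus$docs)))
  invisible(x)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Writes `deg.tsv`, `tf_edges.tsv`, `tf_list.txt`, `snv.tsv`, `ppi.tsv`,
#' `corpus.jsonl`, `lexicon.tsv`, `context.txt`, `ko.txt` and `validated.txt`
#' (the planted true targets, for evaluation) under `dir`. Byte-identical for
#' identical studies.
#'
#' @param study a `knockout_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_files <- function(study, dir) {
  stopifnot(inherits(study, "knockout_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  wt <- function(df, f, col.names = TRUE)
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = col.names)
  wt(as.data.frame(study$degs), "deg.tsv")
  wt(study$tf_network$edges, "tf_edges.tsv", col.names = FALSE)
  writeLines(study$tf_network$tf_set, p("tf_list.txt"))
  wt(as.data.frame(study$snv)[, c("gene", "variant_count", "length_bp")],
     "snv.tsv")
  wt(study$ppi$edges, "ppi.tsv", col.names = FALSE)
  docs <- study$corpus$docs
  if (is.null(docs$title)) {
    docs$title <- docs$text; docs$abstract <- ""
  }
  writeLines(vapply(seq_len(nrow(docs)), function(i)
    jsonlite::toJSON(list(doc_id = docs$doc_id[i], title = docs$title[i],
                          abstract = docs$abstract[i]), auto_unbox = TRUE),
    character(1)), p("corpus.jsonl"))
  lex <- study$corpus$lexicon
  wt(data.frame(symbol = names(lex),
                synonyms = vapply(lex, paste, character(1), collapse = "|"),
                stringsAsFactors = FALSE), "lexicon.tsv")
  writeLines(unclass(study$context), p("context.txt"))
  writeLines(study$ko, p("ko.txt"))
  writeLines(study$truth$true_targets, p("validated.txt"))
  invisible(dir)
}
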
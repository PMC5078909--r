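# Stage 2-2: PPI hop ranking and Borda fusion; the full pipeline.

mini_ppi <- function(a, b, score = 900) {
  interaction_network(a, b, rep_len(score, length(a)), min_score = 400L)
}

rank_list <- function(genes, ranks) {
  # hand-built ranked list for fusion tests
  out <- data.frame(rank = as.integer(ranks), gene = normalize_gene(genes),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("ranked_genes", "data.frame")
  out
}

test_that("hop distances: direct edge is 1, absent or disconnected is Inf", {
  ppi <- mini_ppi(c("Ko", "G1"), c("G1", "G2"))
  expect_equal(unname(shortest_hops(ppi, "Ko", c("G1", "G2", "G9"))),
               c(1, 2, Inf))
  expect_equal(unname(shortest_hops(ppi, "Ko", "Ko")), 0)
  # knockout gene absent from the graph: everything is unreachable
  expect_equal(unname(shortest_hops(mini_ppi("A", "B"), "Ko", c("A", "B"))),
               c(Inf, Inf))
})

test_that("hop distances equal adjacency-powering enumeration on random graphs", {
  for (seed in 1:4) {
    set.seed(seed)
    nodes <- sprintf("P%02d", 1:30)
    n_edges <- 45
    a <- sample(nodes, n_edges, replace = TRUE)
    b <- sample(nodes, n_edges, replace = TRUE)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    ppi <- mini_ppi(a, b)
    ko <- nodes[1]
    got <- shortest_hops(ppi, ko, nodes[-1])
    for (g in nodes[-1])
      expect_equal(unname(got[g]), oracle_hops(nodes, a, b, ko, g),
                   info = sprintf("seed %d gene %s", seed, g))
  }
})

test_that("PPI ranking: fewer hops first, competition ties, unreachable last", {
  ppi <- mini_ppi(c("Ko", "Ko", "G3"), c("G1", "G2", "G4"))
  r <- rank_by_path(c("G1", "G2", "G4"), ppi, "Ko")
  expect_equal(setNames(r$ppi_rank, r$gene), c(G1 = 1L, G2 = 1L, G4 = 3L))
  expect_equal(setNames(r$ppi_distance, r$gene),
               c(G1 = 1, G2 = 1, G4 = Inf))
  # all candidates disconnected -> one big tie at rank 1
  r2 <- rank_by_path(c("X1", "X2"), mini_ppi("A", "B"), "Ko")
  expect_equal(r2$ppi_rank, c(1L, 1L))
  expect_error(rank_by_path(c("Ko", "G1"), ppi, "Ko"), "candidate")
})

test_that("PPI rank order equals a sort-by-distance oracle on synthetic candidates", {
  set.seed(17)
  nodes <- sprintf("Q%02d", 1:40)
  a <- sample(nodes, 60, replace = TRUE)
  b <- sample(nodes, 60, replace = TRUE)
  keep <- a != b
  ppi <- mini_ppi(a[keep], b[keep])
  ko <- nodes[1]
  cand <- nodes[-1]
  r <- rank_by_path(cand, ppi, ko)
  hops <- shortest_hops(ppi, ko, cand)
  expected <- r$gene[order(hops[r$gene], r$gene)]
  expect_equal(r$gene, expected)
  expect_equal(r$ppi_rank,
               vapply(r$gene, function(g) 1L + sum(hops < hops[g]),
                      integer(1), USE.NAMES = FALSE))
})

test_that("Borda fusion reproduces hand tallies", {
  # identical lists agree with themselves: points 2*(N - r + 1)
  l <- rank_list(c("A", "B", "C"), 1:3)
  f <- borda_combine(list(l, l))
  expect_equal(f$gene, c("A", "B", "C"))
  expect_equal(f$borda_points, c(6, 4, 2))

  # L1: A=1,B=2,C=3; L2: B=1,A=2,C=3 -> A,B tie at 5, C gets 2
  f2 <- borda_combine(list(rank_list(c("A", "B", "C"), 1:3),
                           rank_list(c("B", "A", "C"), 1:3)))
  expect_equal(setNames(f2$borda_points, f2$gene), c(A = 5, B = 5, C = 2))
  expect_equal(setNames(f2$rank, f2$gene), c(A = 1L, B = 1L, C = 3L))

  # reversed lists cancel: everyone ties at N + 1 points
  f3 <- borda_combine(list(rank_list(c("A", "B", "C"), 1:3),
                           rank_list(c("C", "B", "A"), 1:3)))
  expect_equal(f3$borda_points, rep(4, 3))
  expect_equal(f3$rank, rep(1L, 3))

  # a gene missing from one list is a contract violation naming the gene
  expect_error(borda_combine(list(rank_list(c("A", "B"), 1:2),
                                  rank_list(c("A", "C"), 1:2))),
               "universe.*(B|C)")
})

test_that("Borda fusion agrees with the exhaustive points table on all small instances", {
  set.seed(23)
  for (n in c(2, 3, 5, 7)) {
    genes <- sprintf("B%02d", seq_len(n))
    for (rep in 1:10) {
      mk <- function() {
        score <- sample(1:4, n, replace = TRUE)  # coarse -> frequent ties
        rank_list(genes, competition_rank(score))
      }
      lists <- list(mk(), mk())
      got <- borda_combine(lists)
      exp <- oracle_borda(lists)
      expect_equal(got$gene, exp$gene)
      expect_equal(got$borda_points, exp$points)
      expect_equal(got$rank, exp$rank)
    }
  }
})

test_that("Borda fusion is unanimous, order-invariant, and idempotent on copies", {
  set.seed(29)
  genes <- sprintf("U%02d", 1:9)
  # unanimity: strict winner of both lists wins overall
  r1 <- competition_rank(c(10, sample(1:5, 8, replace = TRUE)))
  r2 <- competition_rank(c(10, sample(1:5, 8, replace = TRUE)))
  f <- borda_combine(list(rank_list(genes, r1), rank_list(genes, r2)))
  expect_equal(f$gene[1], "U01")
  expect_equal(f$rank[1], 1L)
  expect_equal(sum(f$rank == 1L), 1L)

  # permuting candidate order never changes any output rank
  l1 <- rank_list(genes, r1)
  l2 <- rank_list(genes, r2)
  perm <- sample(nrow(l1))
  l1p <- l1[perm, ]
  class(l1p) <- class(l1)
  fp <- borda_combine(list(l1p, l2))
  expect_equal(fp, f)

  # k copies of one list reproduce that list's order, for several k
  for (k in c(1, 3, 5)) {
    fk <- borda_combine(rep(list(l1), k))
    expect_equal(fk$gene, l1$gene)
    expect_equal(fk$rank, l1$rank)
  }
})

# A 6-gene worked instance, computed by hand with the count scorer:
# context co-mention counts  Fa=5, Aa=3, Bb=2, Cc=1, Dd=1, Ee=0 (rejected)
# relevance ranks            Fa=1, Aa=2, Bb=3, Cc=4, Dd=4
# PPI hops  Bb=1, Cc=1, Aa=2, Dd=2, Fa=3 -> ranks Bb=1, Cc=1, Aa=3, Dd=3, Fa=5
# Borda (N=5): Aa=4+3=7, Bb=3+5=8, Cc=2+5=7, Dd=2+3=5, Fa=5+1=6
# final: Bb(1), Aa(2), Cc(2), Fa(4), Dd(5)
hand_instance <- function() {
  genes <- c("Aa", "Bb", "Cc", "Dd", "Ee", "Fa")
  degs <- deg_table(genes)
  net <- regulatory_network(rep("Ko", 6), genes, tf_set = "Ko")
  snv <- snv_profile(genes, rep(0L, 6), rep(1000L, 6))
  counts <- c(Aa = 3, Bb = 2, Cc = 1, Dd = 1, Ee = 0, Fa = 5)
  texts <- c("Ee in isolation",
             unlist(lapply(names(counts), function(g)
       if (counts[[g]] > 0) paste(g, "links to histone modification", seq_len(counts[[g]]))
       else character(0))))
  corp <- corpus(sprintf("h%02d", seq_along(texts)), texts,
                 lexicon = setNames(rep(list(character(0))), "Ko"))
  ppi <- interaction_network(
    a = c("Ko", "Ko", "Bb", "Cc", "Aa"),
    b = c("Bb", "Cc", "Aa", "Dd", "Fa"),
    score = rep(900, 5), min_score = 400L)
  list(degs = degs, net = net, snv = snv, corp = corp, ppi = ppi)
}

test_that("the full pipeline matches an end-to-end hand computation", {
  hi <- hand_instance()
  fit <- prioritize_genes(hi$degs, hi$net, hi$snv, hi$ppi, hi$corp,
                          "histone modification", "Ko", scorer = "count")
  r <- fit$ranking
  expect_equal(r$gene, c("Bb", "Aa", "Cc", "Fa", "Dd"))
  expect_equal(r$rank, c(1L, 2L, 2L, 4L, 5L))
  expect_equal(setNames(r$borda_points, r$gene),
               c(Bb = 8, Aa = 7, Cc = 7, Fa = 6, Dd = 5))
  expect_equal(fit$rejected, "Ee")
  st <- fit$diagnostics$stages
  expect_equal(unlist(st[c("deg", "tf_filter", "snv_filter", "relevance",
                           "final")]),
               c(deg = 6L, tf_filter = 6L, snv_filter = 6L, relevance = 5L,
                 final = 5L))
  # stage sizes are monotone non-increasing
  expect_true(all(diff(unlist(st)) <= 0))
})

test_that("a gene dominating both criteria is ranked first by the pipeline", {
  genes <- c("Win", "Xx", "Yy")
  degs <- deg_table(genes)
  net <- regulatory_network(rep("Ko", 3), genes, tf_set = "Ko")
  corp <- corpus(c("c1", "c2", "c3"),
                 c("Win and fibrosis", "Win and fibrosis again",
                   "Xx fibrosis Yy"),
                 lexicon = list())
  ppi <- interaction_network(c("Ko", "Ko", "Xx"), c("Win", "Xx", "Yy"),
                             rep(900, 3), min_score = 400L)
  # Win: relevance rank 1 alone (2 co-mentions), hops 1 tied -> rank 1 overall
  fit <- prioritize_genes(degs, net, NULL, ppi, corp, "fibrosis", "Ko",
                          scorer = "count")
  expect_equal(fit$ranking$gene[1], "Win")
  expect_equal(fit$ranking$rank[1], 1L)
})

test_that("the pipeline reports the emptying stage gracefully", {
  genes <- c("Aa", "Bb")
  degs <- deg_table(genes)
  lonely <- regulatory_network("T2", "Cc", tf_set = "T2")  # KO not present
  corp <- corpus("c1", "nothing relevant", lexicon = list())
  ppi <- interaction_network("Aa", "Bb", 900, min_score = 400L)
  suppressWarnings(expect_warning(
    fit <- prioritize_genes(degs, lonely, NULL, ppi, corp, "fibrosis", "Ko"),
    "no candidates"))
  expect_equal(nrow(fit$ranking), 0L)
  expect_equal(fit$diagnostics$empty_after, "tf_filter")

  # all relevance rejected
  net <- regulatory_network(c("Ko", "Ko"), genes, tf_set = "Ko")
  suppressWarnings(expect_warning(
    fit2 <- prioritize_genes(degs, net, NULL, ppi, corp, "fibrosis", "Ko"),
    "zero literature relevance"))
  expect_equal(nrow(fit2$ranking), 0L)
  expect_setequal(fit2$rejected, genes)
  expect_equal(fit2$diagnostics$empty_after, "relevance")
})
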
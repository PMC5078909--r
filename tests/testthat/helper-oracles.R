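# Independent brute-force oracles used to cross-check the implementation.
# They avoid igraph and regular expressions on purpose: reachability and hop
# distance via boolean adjacency-matrix powering, Borda via an explicit
# points table, phrase mentions via a character scan.

# directed reachability: genes reachable from `source` by paths of length
# 1..max_depth, source included only if a path returns to it
oracle_reachable <- function(nodes, from, to, source, max_depth = Inf) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(from, nodes), match(to, nodes))] <- TRUE
  if (!source %in% nodes) return(character(0))
  reach <- rep(FALSE, n)
  names(reach) <- nodes
  P <- A
  k <- 1
  while (k <= min(max_depth, n)) {
    reach <- reach | P[source, ]
    P <- (P %*% A) > 0
    k <- k + 1
  }
  sort(nodes[reach])
}

# undirected hop distance between two nodes by adjacency powering
oracle_hops <- function(nodes, a, b, x, y) {
  n <- length(nodes)
  if (!(x %in% nodes) || !(y %in% nodes)) return(Inf)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(a, nodes), match(b, nodes))] <- TRUE
  A[cbind(match(b, nodes), match(a, nodes))] <- TRUE
  if (x == y) return(0)
  P <- A
  for (k in seq_len(n)) {
    if (P[x, y]) return(k)
    P <- (P %*% A) > 0
  }
  Inf
}

# exhaustive Borda points table over rank lists (data frames with gene, rank)
oracle_borda <- function(lists) {
  genes <- sort(lists[[1]]$gene)
  N <- length(genes)
  pts <- setNames(numeric(N), genes)
  for (l in lists)
    for (g in genes)
      pts[g] <- pts[g] + (N - l$rank[l$gene == g] + 1)
  # competition rank: 1 + number of strictly better genes
  rk <- vapply(genes, function(g) 1L + sum(pts > pts[g]), integer(1))
  out <- data.frame(gene = genes, points = unname(pts), rank = unname(rk),
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$gene), ]
}

# regex-free case-insensitive whole-phrase scan with word boundaries
oracle_mentions <- function(doc_id, text, phrase) {
  is_word <- function(ch) grepl("^[a-z0-9_]$", ch)
  phrase <- tolower(gsub("\\s+", " ", trimws(phrase)))
  hits <- vapply(text, function(t) {
    t <- tolower(gsub("\\s+", " ", t))
    start <- 1L
    repeat {
      i <- regexpr(phrase, substring(t, start), fixed = TRUE)[1]
      if (i == -1L) return(FALSE)
      s <- start + i - 1L
      e <- s + nchar(phrase) - 1L
      ok_l <- s == 1L || !is_word(substring(t, s - 1L, s - 1L))
      ok_r <- e == nchar(t) || !is_word(substring(t, e + 1L, e + 1L))
      if (ok_l && ok_r) return(TRUE)
      start <- s + 1L
    }
  }, logical(1))
  doc_id[hits]
}

# exhaustive per-record interval membership (BED 0-based half-open)
oracle_snv_counts <- function(pos_1based, chrom, bed) {
  # bed: data.frame chrom, start0, end0, gene
  genes <- sort(unique(bed$gene))
  sapply(genes, function(g) {
    iv <- bed[bed$gene == g, , drop = FALSE]
    sum(vapply(seq_along(pos_1based), function(i) {
      p0 <- pos_1based[i] - 1L
      any(iv$chrom == chrom[i] & iv$start0 <= p0 & p0 < iv$end0)
    }, logical(1)))
  })
}

# small random digraph as an edge data frame
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  idx <- which(matrix(runif(n * n) < p, n, n) & !diag(n), arr.ind = TRUE)
  list(nodes = nodes,
       from = nodes[idx[, 1]], to = nodes[idx[, 2]])
}

make_corpus <- function(texts, lexicon = list()) {
  corpus(sprintf("d%03d", seq_along(texts)), texts, lexicon = lexicon)
}
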
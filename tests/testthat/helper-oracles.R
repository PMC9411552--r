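# Independent oracles kept deliberately separate from the implementation.

# dense personalized-PageRank oracle: direct linear solve of
# r = alpha * M r + (1-alpha) v with dangling columns redirected to v
dense_pagerank_oracle <- function(graph, seeds, damping = 0.85,
                                  weighted = TRUE) {
  nodes <- graph$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w <- if (weighted) graph$edges$score / 1000 else rep(1, nrow(graph$edges))
  for (k in seq_len(nrow(graph$edges))) {
    A[graph$edges$a[k], graph$edges$b[k]] <- w[k]
    A[graph$edges$b[k], graph$edges$a[k]] <- w[k]
  }
  v <- numeric(n); names(v) <- nodes
  v[intersect(seeds, nodes)] <- 1 / length(intersect(seeds, nodes))
  s <- rowSums(A)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    M[, j] <- if (s[j] > 0) A[j, ] / s[j] else v
  }
  setNames(drop(solve(diag(n) - damping * M, (1 - damping) * v)), nodes)
}

# brute-force GSEA enrichment score: walk the whole ranking position by
# position, accumulating the running sum, return its signed extremum
gsea_es_oracle <- function(ranking, gene_set, weight_exponent = 1) {
  ord <- order(-ranking, names(ranking))
  genes <- names(ranking)[ord]
  scores <- abs(unname(ranking)[ord])^weight_exponent
  hit <- genes %in% gene_set
  nh <- sum(scores[hit])
  inc <- ifelse(hit, if (nh > 0) scores / nh else 1 / sum(hit),
                -1 / (length(genes) - sum(hit)))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# exhaustive maximal modularity over all partitions of small node sets,
# enumerating set partitions via restricted-growth strings
max_modularity_oracle <- function(graph, weighted = TRUE) {
  n <- length(graph$nodes)
  stopifnot(n <= 10)
  best <- -Inf
  rgs <- integer(n); rgs[1] <- 1L
  recurse <- function(i, m) {
    if (i > n) {
      memb <- setNames(rgs, graph$nodes)
      q <- modularity_q(graph, memb, weighted)
      if (q > best) best <<- q
      return()
    }
    for (c in seq_len(m + 1L)) {
      rgs[i] <<- c
      recurse(i + 1L, max(m, c))
    }
  }
  recurse(2L, 1L)
  best
}

# confusion-table oracle computed entry by entry
metrics_oracle <- function(truth, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tab <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_along(truth)) {
    key <- if (pred[i] == 1 && truth[i] == 1) "tp"
      else if (pred[i] == 1) "fp"
      else if (truth[i] == 0) "tn" else "fn"
    tab[key] <- tab[key] + 1L
  }
  tab
}
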
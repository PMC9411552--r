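#' Personalized PageRank over a PPI graph
#'
#' Computes the stationary distribution of a random walk that, with
#' probability `1 - damping`, restarts at a seed gene chosen uniformly from
#' the seed set: the fixed point of `r = alpha * t(P) r + (1 - alpha) v`,
#' where `P` is the degree-normalized (weight-proportional) transition
#' matrix and `v` the uniform restart vector over the seeds.  Mass landing
#' on dangling (isolated) nodes is redirected to `v`.  Solved by sparse
#' power iteration to an L1 tolerance.
#'
#' @param graph a `ppi_graph`.
#' @param seeds seed gene ids; at least one must be a graph node.
#' @param damping walk-continuation probability alpha, default 0.85.
#' @param tol L1 convergence tolerance, default 1e-10.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param weighted use `score/1000` edge weights (default) or treat all
#'   edges equally.
#' @return a `pagerank_vector`: `scores` (named, sums to 1), `damping`,
#'   `seeds` (those present in the graph), `iterations`.
#' @export
personalized_pagerank <- function(graph, seeds, damping = 0.85, tol = 1e-10,
                                  max_iter = 1000L, weighted = TRUE) {
  stopifnot(inherits(graph, "ppi_graph"), damping > 0, damping < 1)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) stop("empty graph")
  seeds_in <- intersect(seeds, nodes)
  if (length(seeds_in) == 0L) stop("no seed gene is present in the graph")
  ai <- match(graph$edges$a, nodes); bi <- match(graph$edges$b, nodes)
  w <- if (weighted) graph$edges$score / 1000 else rep(1, nrow(graph$edges))
  A <- Matrix::sparseMatrix(i = c(ai, bi), j = c(bi, ai), x = c(w, w),
                            dims = c(n, n))
  strength <- Matrix::rowSums(A)
  dangling <- strength == 0
  inv_s <- ifelse(dangling, 0, 1 / strength)
  # t(P) r computed as A %*% (r / strength) since A is symmetric
  v <- numeric(n); v[match(seeds_in, nodes)] <- 1 / length(seeds_in)
  r <- v
  for (it in seq_len(max_iter)) {
    walk <- as.numeric(A %*% (r * inv_s)) + sum(r[dangling]) * v
    r_new <- damping * walk + (1 - damping) * v
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tol) {
      return(structure(list(scores = setNames(r, nodes), damping = damping,
                            seeds = seeds_in, tol = tol, iterations = it),
                       class = "pagerank_vector"))
    }
  }
  stop("personalized PageRank did not converge in ", max_iter, " iterations")
}

#' @export
print.pagerank_vector <- function(x, ...) {
  cat(sprintf("pagerank_vector: %d nodes, %d seeds, alpha=%.2f, %d iterations\n",
              length(x$scores), length(x$seeds), x$damping, x$iterations))
  invisible(x)
}

# ES of a gene set given sorted hit positions in a ranking of length N.
# weights: |score|^exponent at the hit positions (same order as positions).
# Candidate extrema of the running sum occur immediately after each hit
# (maximum side) and immediately before each hit (minimum side).
.gsea_es <- function(positions, weights, N) {
  ns <- length(positions)
  o <- order(positions)
  positions <- positions[o]; weights <- weights[o]
  total <- sum(weights)
  if (total <= 0) weights <- rep(1 / ns, ns) else weights <- weights / total
  step <- 1 / (N - ns)
  cum <- cumsum(weights)
  i <- seq_len(ns)
  after <- cum - (positions - i) * step
  before <- c(0, cum[-ns]) - (positions - i) * step
  max_up <- max(after); min_down <- min(before)
  if (max_up >= -min_down) max_up else min_down
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are ordered by descending score; the running sum gains
#' `|score|^exponent` (normalized over the set) at each set member and loses
#' `1/(N - n_set)` at each non-member; the enrichment score ES is the
#' signed extremum of the running sum.  The null distribution is built from
#' random gene sets of the same size drawn from the ranked universe; NES
#' divides ES by the mean magnitude of same-sign null scores.  The empirical
#' p-value counts null scores whose magnitude is at least `|ES|` (the signed
#' extremum's magnitude is exchangeable across permutations, so this count
#' is exactly uniform for a random gene set), with the conventional +1
#' correction giving a floor of `1/(n_perm + 1)`.
#'
#' @param ranking named numeric vector, gene id -> score; all finite.
#' @param gene_set character vector of member gene ids (>= 2 must be in the
#'   ranking).
#' @param n_perm number of null permutations, default 10000.
#' @param weight_exponent score-weighting exponent `p`, default 1 (0 gives
#'   the classic Kolmogorov-Smirnov form).
#' @param seed permutation seed.
#' @return a `gsea_result`: `es`, `nes`, `p_value`, `n_perm`,
#'   `weight_exponent`, `leading_edge`, `set_size`, `seed`.
#' @export
preranked_gsea <- function(ranking, gene_set, n_perm = 10000L,
                           weight_exponent = 1, seed = 1L) {
  if (any(!is.finite(ranking))) stop("ranking scores must be finite")
  ord <- order(-ranking, names(ranking))
  genes <- names(ranking)[ord]
  scores <- unname(ranking)[ord]
  N <- length(genes)
  hit <- which(genes %in% gene_set)
  ns <- length(hit)
  if (ns < 2L) stop("fewer than 2 gene-set members present in the ranking")
  if (ns >= N) stop("gene set covers the whole ranking")
  wts <- abs(scores)^weight_exponent
  es <- .gsea_es(hit, wts[hit], N)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(N, ns)
    .gsea_es(pos, wts[pos], N)
  }, 0)
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  denom <- mean(abs(same_sign))
  nes <- if (length(same_sign) && denom > 0) es / denom else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(es))) / (1 + n_perm)
  # leading edge: members at or before the running-sum extremum
  cum <- cumsum(wts[hit] / sum(wts[hit]))
  i <- seq_len(ns)
  after <- cum - (hit - i) / (N - ns)
  le <- if (es >= 0) genes[hit[seq_len(which.max(after))]]
        else genes[hit[hit >= hit[which.min(c(0, cum[-ns]) - (hit - i) / (N - ns))]]]
  structure(list(es = es, nes = nes, p_value = p, n_perm = as.integer(n_perm),
                 weight_exponent = weight_exponent, leading_edge = le,
                 set_size = ns, seed = as.integer(seed)),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES=%.3f NES=%.3f p=%.4g (n=%d members, %d permutations)\n",
              x$es, x$nes, x$p_value, x$set_size, x$n_perm))
  invisible(x)
}

#' Network validation of predicted genes against known positives
#'
#' Runs personalized PageRank from the known Class-1 genes, removes the
#' seeds themselves from the ranking (so the enrichment measures only novel
#' predictions), and tests whether the predicted genes concentrate at the
#' top of the PageRank ordering by preranked GSEA.
#'
#' @param graph a `ppi_graph`.
#' @param seeds known positive gene ids (PageRank restart set).
#' @param predictions candidate gene ids to test.
#' @param damping,weighted passed to [personalized_pagerank()].
#' @param n_perm,weight_exponent,seed passed to [preranked_gsea()].
#' @return list: `gsea` (a `gsea_result`), `pagerank` (the full
#'   `pagerank_vector`), `table` (ranked data.frame gene_id, pagerank_score,
#'   is_prediction).
#' @export
validate_predictions <- function(graph, seeds, predictions, damping = 0.85,
                                 weighted = TRUE, n_perm = 10000L,
                                 weight_exponent = 1, seed = 1L) {
  pr <- personalized_pagerank(graph, seeds, damping = damping,
                              weighted = weighted)
  ranking <- pr$scores[!(names(pr$scores) %in% seeds)]
  preds_in <- intersect(predictions, names(ranking))
  if (length(preds_in) < 2L)
    stop("fewer than 2 predictions present in the ranked network")
  gsea <- preranked_gsea(ranking, preds_in, n_perm = n_perm,
                         weight_exponent = weight_exponent, seed = seed)
  ord <- order(-ranking, names(ranking))
  tab <- data.frame(gene_id = names(ranking)[ord],
                    pagerank_score = unname(ranking)[ord],
                    is_prediction = names(ranking)[ord] %in% preds_in)
  list(gsea = gsea, pagerank = pr, table = tab)
}
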
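#' Induced subnetwork of known plus predicted genes
#'
#' @param graph a `ppi_graph`.
#' @param known known positive gene ids.
#' @param predicted predicted candidate gene ids.
#' @return a `ppi_graph` induced on `(known U predicted)` intersected with
#'   the graph's nodes (edges between retained nodes only).
#' @export
subnetwork <- function(graph, known, predicted) {
  keep <- intersect(union(known, predicted), graph$nodes)
  if (length(keep) == 0L) stop("no known or predicted gene is in the graph")
  e <- graph$edges[graph$edges$a %in% keep & graph$edges$b %in% keep, , drop = FALSE]
  ppi_graph(e, nodes = keep, min_score = graph$min_score)
}

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`, computed
#' community-by-community from within-community edge weight and community
#' strength.  Edge weights are `score/1000` when `weighted = TRUE`.
#'
#' @param graph a `ppi_graph` with at least one edge.
#' @param membership named vector (gene id -> community id) covering every
#'   graph node.
#' @param weighted use combined-score weights, default TRUE.
#' @return modularity Q, a number in `[-1, 1]`.
#' @export
modularity_q <- function(graph, membership, weighted = TRUE) {
  if (nrow(graph$edges) == 0L) stop("modularity undefined on an edgeless graph")
  miss <- setdiff(graph$nodes, names(membership))
  if (length(miss)) stop("membership missing nodes: ", paste(head(miss, 3), collapse = ", "))
  w <- if (weighted) graph$edges$score / 1000 else rep(1, nrow(graph$edges))
  m2 <- 2 * sum(w)                                    # total weight, both directions
  ca <- membership[graph$edges$a]; cb <- membership[graph$edges$b]
  within <- sum(w[ca == cb])                          # each undirected edge once
  strength <- numeric(0)
  for (side in list(graph$edges$a, graph$edges$b)) {
    s <- tapply(w, membership[side], sum)
    strength[names(s)] <- (if (length(strength)) strength[names(s)] else 0) + s
  }
  strength[is.na(strength)] <- 0
  2 * within / m2 - sum((strength / m2)^2)
}

#' Louvain community detection
#'
#' Two-phase greedy modularity optimization (local moves followed by graph
#' aggregation), as implemented in igraph, run on the combined-score-weighted
#' graph.  The node visit order depends on the R random seed, which is set
#' from `seed` so partitions are reproducible.
#'
#' @param graph a `ppi_graph` with at least one edge.
#' @param resolution resolution parameter gamma, default 1.
#' @param seed integer seed for the (randomized) visit order.
#' @param weighted use combined-score weights, default TRUE.
#' @return a `community_partition`: `membership` (named integer),
#'   `modularity` (Q of the returned partition at resolution 1, computed by
#'   [modularity_q()]), `resolution`, `n_communities`, `seed`.
#' @export
louvain_communities <- function(graph, resolution = 1.0, seed = 1L,
                                weighted = TRUE) {
  if (nrow(graph$edges) == 0L) stop("community detection needs at least one edge")
  g <- as_igraph(graph, weighted = weighted)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  membership <- setNames(as.integer(igraph::membership(cl)),
                         igraph::V(g)$name)
  membership <- membership[graph$nodes]
  structure(list(membership = membership,
                 modularity = modularity_q(graph, membership, weighted),
                 resolution = resolution,
                 n_communities = length(unique(membership)),
                 seed = as.integer(seed)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, Q = %.3f (resolution %.2f)\n",
              x$n_communities, x$modularity, x$resolution))
  invisible(x)
}

#' Hypergeometric over-representation of gene sets in communities
#'
#' For each (community, gene set) pair, tests whether the community contains
#' more set members than expected under hypergeometric sampling from the
#' universe: upper-tail `p = P(X >= k)` with population `N`, successes `K`
#' (set members in the universe), draws `n` (community size).  p-values are
#' Benjamini-Hochberg adjusted across all pairs jointly.
#'
#' @param partition a `community_partition`.
#' @param sets a `gene_set_collection`.
#' @param universe character vector of background gene ids; must contain
#'   every community member.  Sets with no member in the universe are
#'   skipped with a warning.
#' @return data.frame with columns `community`, `set_name`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`, ordered by `q_value`.
#' @export
enrich_communities <- function(partition, sets, universe) {
  members <- names(partition$membership)
  out <- setdiff(members, universe)
  if (length(out)) stop("community members outside universe: ",
                        paste(head(out, 3), collapse = ", "))
  N <- length(unique(universe))
  rows <- list()
  for (set_name in names(sets$sets)) {
    set_u <- intersect(sets$sets[[set_name]], universe)
    if (length(set_u) == 0L) {
      warning("gene set '", set_name, "' has no member in the universe; skipped")
      next
    }
    K <- length(set_u)
    for (cm in sort(unique(partition$membership))) {
      comm <- members[partition$membership == cm]
      n <- length(comm)
      k <- length(intersect(comm, set_u))
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(community = cm, set_name = set_name,
                   k = k, K = K, n = n, N = N, p_value = p)
    }
  }
  if (!length(rows)) stop("no testable (community, set) pair")
  tab <- do.call(rbind, rows)
  tab$q_value <- p.adjust(tab$p_value, method = "BH")
  tab[order(tab$q_value, tab$p_value, tab$set_name, tab$community), ]
}
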
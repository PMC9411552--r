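two_triangles <- function() {
  graph_from_triples(list("a", "b", 1000), list("b", "c", 1000),
                     list("a", "c", 1000), list("d", "e", 1000),
                     list("e", "f", 1000), list("d", "f", 1000))
}

two_cliques_bridged <- function(m = 5) {
  nodes1 <- sprintf("p%d", 1:m); nodes2 <- sprintf("q%d", 1:m)
  mk <- function(nodes) do.call(rbind, apply(
    which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE), 1, function(ij)
      data.frame(a = nodes[ij[1]], b = nodes[ij[2]], score = 1000L)))
  ppi_graph(rbind(mk(nodes1), mk(nodes2),
                  data.frame(a = "p1", b = "q1", score = 1000L)))
}

test_that("subnetwork induces on known plus predicted genes", {
  g <- graph_from_triples(list("a", "b", 500), list("b", "c", 600),
                          list("c", "d", 700), list("d", "e", 800))
  sub <- subnetwork(g, known = c("a", "b"), predicted = "c")
  expect_setequal(sub$nodes, c("a", "b", "c"))
  expect_identical(nrow(sub$edges), 2L)  # a-b and b-c; c-d dropped
  # isolated members are retained as nodes
  sub2 <- subnetwork(g, known = "a", predicted = "e")
  expect_setequal(sub2$nodes, c("a", "e"))
  expect_identical(nrow(sub2$edges), 0L)
  # covering all nodes returns the graph itself
  sub3 <- subnetwork(g, known = g$nodes, predicted = character(0))
  expect_identical(sub3$edges, g$edges)
  expect_error(subnetwork(g, "x", "y"), "no known or predicted")
  # planted two-block fixture: edge count by direct enumeration
  cfg <- small_config(seed = 67)
  fm <- generate_feature_matrix(cfg)
  net <- generate_ppi_network(cfg, fm$labels)
  keep <- c(fm$labels$positives, fm$labels$negatives[1:50])
  subp <- subnetwork(net, fm$labels$positives, fm$labels$negatives[1:50])
  manual <- sum(net$edges$a %in% keep & net$edges$b %in% keep)
  expect_identical(nrow(subp$edges), manual)
})

test_that("modularity formula: single community, triangles, singletons", {
  tt <- two_triangles()
  memb_one <- setNames(rep(1L, 6), tt$nodes)
  expect_equal(modularity_q(tt, memb_one), 0)
  memb_tri <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularity_q(tt, memb_tri), 0.5)
  # all singletons on a connected graph: only null-model terms remain
  g <- two_cliques_bridged()
  memb_singl <- setNames(seq_along(g$nodes), g$nodes)
  expect_lt(modularity_q(g, memb_singl), 0)
  expect_error(modularity_q(ppi_graph(data.frame(a = character(0),
                                                 b = character(0),
                                                 score = integer(0)),
                                      nodes = c("a", "b")),
                            c(a = 1, b = 1)), "edgeless")
  # agreement with igraph on a weighted graph
  gi <- as_igraph(g, weighted = TRUE)
  memb_half <- setNames(rep(c(1L, 2L), each = 5), g$nodes)
  expect_equal(modularity_q(g, memb_half),
               igraph::modularity(gi, memb_half[igraph::V(gi)$name],
                                  weights = igraph::E(gi)$weight))
})

test_that("louvain recovers two bridged cliques at the brute-force optimum", {
  g <- two_cliques_bridged()
  part <- louvain_communities(g, seed = 2)
  expect_identical(part$n_communities, 2L)
  memb <- part$membership
  expect_length(unique(memb[sprintf("p%d", 1:5)]), 1L)
  expect_length(unique(memb[sprintf("q%d", 1:5)]), 1L)
  expect_equal(part$modularity, max_modularity_oracle(g), tolerance = 1e-12)
  # self-consistency: reported Q equals recomputed Q
  expect_equal(part$modularity, modularity_q(g, part$membership))
  # Q never below the all-singleton partition
  singl <- setNames(seq_along(g$nodes), g$nodes)
  expect_gte(part$modularity, modularity_q(g, singl))
})

test_that("disconnected components never share a community", {
  tt <- two_triangles()
  part <- louvain_communities(tt, seed = 5)
  memb <- part$membership
  expect_false(memb[["a"]] %in% memb[c("d", "e", "f")])
  expect_equal(part$modularity, 0.5)
})

test_that("planted blocks are recovered across seeds (adjusted Rand)", {
  cfg <- synthetic_config(
    seed = 71, n_genes = 120L, n_positives = 12L,
    families = data.frame(name = "A", n_features = 10L, n_signal = 2L),
    block_sizes = c(40L, 40L, 40L), p_within = 0.3, p_between = 0.01)
  fm <- generate_feature_matrix(cfg)
  g <- generate_ppi_network(cfg, fm$labels)
  blocks <- attr(g, "blocks")[g$nodes]
  aris <- vapply(1:20, function(s) {
    part <- louvain_communities(g, seed = s)
    igraph::compare(part$membership[g$nodes], blocks,
                    method = "adjusted.rand")
  }, 0)
  expect_gte(mean(aris), 0.8)
})

test_that("hypergeometric enrichment matches exact arithmetic and BH", {
  # N=10, K=5, n=5, k=5 -> p = 1/C(10,5) = 1/252
  universe <- sprintf("u%02d", 1:10)
  part <- structure(list(membership = setNames(rep(c(1L, 2L), each = 5),
                                               universe)),
                    class = "community_partition")
  sets <- gene_set_collection(list(hit = universe[1:5], all = universe))
  enr <- enrich_communities(part, sets, universe)
  p_hit <- enr$p_value[enr$set_name == "hit" & enr$community == 1]
  expect_equal(p_hit, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(enr$p_value[enr$set_name == "all"], c(1, 1))
  expect_true(all(enr$k <= pmin(enr$K, enr$n)))
  # BH step-up on (0.01, 0.02, 0.03) gives (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_warning(
    enrich_communities(part,
                       gene_set_collection(list(out = "zzz", hit = universe[1:5])),
                       universe),
    "no member in the universe")
})
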
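test_that("gene_feature_matrix enforces its invariants", {
  vals <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), c("f1", "f2")))
  m <- tiny_matrix(vals)
  expect_s3_class(m, "gene_feature_matrix")
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(gene_ids(m), c("g1", "g2", "g3"))

  dup <- vals; rownames(dup) <- c("g1", "g1", "g3")
  expect_error(tiny_matrix(dup), "duplicate gene id: g1")

  bad <- vals; bad[2, 1] <- 0.5
  expect_error(tiny_matrix(bad), "non-binary cell at gene 'g2', feature 'f1'")

  expect_error(gene_feature_matrix(vals, c(f1 = "A")), "without family label")
})

test_that("feature matrix TSV round trip is lossless", {
  set.seed(1)
  vals <- matrix(rbinom(40, 1, 0.4), nrow = 8,
                 dimnames = list(sprintf("g%d", 1:8), sprintf("f%d", 1:5)))
  m <- tiny_matrix(vals, setNames(rep(c("GO", "GTEx"), c(2, 3)),
                                  colnames(vals)))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(m, p1, p2)
  m2 <- read_feature_matrix(p1, p2)
  expect_identical(as.matrix(m2$values), as.matrix(m$values))
  expect_identical(m2$feature_family, m$feature_family)
})

test_that("read_feature_matrix rejects a non-binary cell naming its position", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfA\tfB", "g1\t0\t1", "g2\t0.5\t0"), p1)
  writeLines(c("feature_id\tfamily", "fA\tGO", "fB\tGO"), p2)
  expect_error(read_feature_matrix(p1, p2),
               "non-binary cell at gene 'g2', feature 'fA': 0.5")
})

test_that("read_ppi_edges applies inclusive threshold, dedup and loop rules", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t399", "a\tc\t400", "b\tc\t401",
               "c\ta\t500", "d\td\t900"), p)
  expect_message(g <- read_ppi_edges(p, 400), "self-loop")
  # a-b dropped (399 < 400); a-c keeps max(400, 500) = 500; d-d dropped
  expect_identical(nrow(g$edges), 2L)
  ac <- g$edges[g$edges$a == "a" & g$edges$b == "c", ]
  expect_identical(ac$score, 500L)
  expect_false("d" %in% c(g$edges$a, g$edges$b))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\t1500", bad)
  expect_error(suppressMessages(read_ppi_edges(bad, 400)), "0, 1000")
})

test_that("ppi edge IO is idempotent", {
  g <- graph_from_triples(list("a", "b", 500), list("b", "c", 800),
                          list("a", "c", 401))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_edges(g, p)
  g2 <- read_ppi_edges(p, 0)
  expect_identical(g2$edges, g$edges)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_edges(g2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("GMT round trip and error contract", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tg1\tg2", "S2\tother\tg3"), p)
  gs <- read_gmt(p)
  expect_identical(gs$sets$S1, c("g1", "g2"))
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, p2)
  expect_identical(readLines(p2), readLines(p))
  expect_error(gene_set_collection(list(S1 = character(0))), "empty gene set: S1")
})

test_that("prediction TSV is ranked with lexicographic tie-break and round-trips", {
  pred <- structure(list(
    mean_probability = c(gB = 0.5, gA = 0.5, gC = 0.9, gD = 0.1),
    per_model = NULL, model_type = "GB", n_models = 2L),
    class = "ensemble_prediction")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(pred, p)
  tab <- read.delim(p)
  expect_identical(tab$gene_id, c("gC", "gA", "gB", "gD"))
  back <- read_predictions(p)
  expect_identical(names(back$mean_probability), tab$gene_id)
  expect_equal(unname(back$mean_probability), tab$mean_probability)
})

test_that("compute_metrics matches the exhaustive confusion oracle on length-6 toys", {
  combos <- expand.grid(replicate(6, 0:1, simplify = FALSE))
  scores6 <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  for (i in seq_len(nrow(combos))) {
    truth <- as.integer(combos[i, ])
    for (sc in list(scores6, rev(scores6), rep(0.7, 6))) {
      m <- suppressWarnings(compute_metrics(truth, sc))
      o <- metrics_oracle(truth, sc)
      expect_identical(c(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn), o)
      expect_equal(m$tp + m$fp + m$tn + m$fn, 6)
    }
  }
})

test_that("compute_metrics reproduces reported hold-out rate arithmetic", {
  # 425 false positives among 5,368 negatives
  truth <- rep(0L, 5368)
  scores <- c(rep(0.9, 425), rep(0.1, 4943))
  m <- suppressWarnings(compute_metrics(truth, scores))
  expect_identical(m$fp, 425L)
  expect_identical(m$tn, 4943L)
  expect_equal(round(m$fpr, 3), 0.079)
  # 14 FP among top 25 with 11 TP
  m2 <- compute_metrics(rep(c(1L, 0L), c(11, 14)), rep(0.8, 25))
  expect_equal(m2$fdr, 0.56)
})

test_that("metrics are perfect when scores equal labels and AUROC inverts", {
  truth <- c(1L, 0L, 1L, 0L, 1L, 0L)
  m <- compute_metrics(truth, as.numeric(truth))
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1, m$auroc),
               rep(1, 5))
  sc <- c(0.9, 0.1, 0.7, 0.3, 0.8, 0.2)
  a1 <- compute_metrics(truth, sc)$auroc
  a2 <- compute_metrics(truth, 1 - sc)$auroc
  expect_equal(a2, 1 - a1)
  expect_warning(compute_metrics(rep(1L, 4), runif(4)), "single-class")
})
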
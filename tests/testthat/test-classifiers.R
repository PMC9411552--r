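test_that("all five model types separate a linearly separable toy set", {
  d <- separable_data(40)
  for (tp in c("LR", "GNB", "SVM", "RF", "GB")) {
    spec <- model_spec(tp, tune = FALSE, seed = 1,
                       defaults = if (tp == "SVM") list(n_iter = 4000L) else list())
    rec <- tune_and_train(spec, d$matrix, d$training_set,
                          c("f01", "f02"), set_index = 1)
    sc <- score_genes(rec, d$matrix, d$training_set$gene_id)
    acc <- mean((sc >= 0.5) == (d$training_set$label == 1L))
    expect_equal(acc, 1, info = tp)
    expect_true(all(sc >= 0 & sc <= 1), info = tp)
  }
})

test_that("hyperparameter tuning is deterministic given the seed", {
  d <- toy_signal_data(n = 40, n_sig = 3, n_noise = 5, seed = 7)
  spec <- model_spec("GB", tune = TRUE, seed = 3, n_random = 3,
                     grids = list(GB = list(learning_rate = c(0.1, 0.3),
                                            n_trees = c(20L, 40L))))
  r1 <- tune_and_train(spec, d$matrix, d$training_set, d$features, 1)
  r2 <- tune_and_train(spec, d$matrix, d$training_set, d$features, 1)
  expect_identical(r1$hyperparameters, r2$hyperparameters)
  expect_true(r1$hyperparameters$n_trees %in% c(20L, 40L))
})

test_that("SVM grid search picks a grid member and stays deterministic", {
  d <- toy_signal_data(n = 30, n_sig = 2, n_noise = 2, seed = 8)
  spec <- model_spec("SVM", tune = TRUE, seed = 5,
                     grids = list(SVM = list(kernel = c("linear", "rbf"),
                                             cost = c(1, 10), gamma = 0.1)),
                     defaults = list(n_iter = 1500L))
  r1 <- tune_and_train(spec, d$matrix, d$training_set, d$features, 1)
  r2 <- tune_and_train(spec, d$matrix, d$training_set, d$features, 1)
  expect_identical(r1$hyperparameters, r2$hyperparameters)
  expect_true(r1$hyperparameters$kernel %in% c("linear", "rbf"))
  expect_true(r1$hyperparameters$cost %in% c(1, 10))
})

test_that("GNB probabilities are invariant to feature permutation", {
  d <- toy_signal_data(n = 40, n_sig = 3, n_noise = 5, seed = 9)
  spec <- model_spec("GNB", tune = FALSE, seed = 1)
  r1 <- tune_and_train(spec, d$matrix, d$training_set, d$features, 1)
  r2 <- tune_and_train(spec, d$matrix, d$training_set, rev(d$features), 1)
  s1 <- score_genes(r1, d$matrix, d$training_set$gene_id)
  s2 <- score_genes(r2, d$matrix, d$training_set$gene_id)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("cross-validation folds partition the set and metrics behave", {
  d <- toy_signal_data(n = 60, n_sig = 6, n_noise = 10,
                       p1 = 0.9, p0 = 0.01, seed = 10)
  spec <- model_spec("GB", tune = FALSE, seed = 2)
  cv <- cross_validate(spec, d$matrix, d$training_set, d$features, k = 10)
  expect_identical(nrow(cv$per_fold), 10L)
  expect_true(all(cv$per_fold >= 0 & cv$per_fold <= 1))
  expect_gte(cv$mean[["accuracy"]], 0.95)  # near-perfect planted signal

  # shuffled labels: AUROC near chance
  set.seed(11)
  shuffled <- d$training_set
  shuffled$label <- sample(shuffled$label)
  cv_null <- cross_validate(spec, d$matrix, shuffled, d$features, k = 10)
  expect_gt(cv_null$mean[["auroc"]], 0.35)
  expect_lt(cv_null$mean[["auroc"]], 0.65)

  expect_error(cross_validate(spec, d$matrix, d$training_set, d$features,
                              k = 100), "smaller than fold count")
})

test_that("fold assignment covers each sample exactly once", {
  y <- rep(c(0L, 1L), 20)
  folds <- rmethpred:::.stratified_folds(y, 5L, seed = 3)
  expect_setequal(unlist(folds), seq_along(y))
  expect_identical(anyDuplicated(unlist(folds)), 0L)
  # stratification: each fold has both classes
  expect_true(all(vapply(folds, function(f) length(unique(y[f])) == 2L, TRUE)))
})

test_that("ensemble_cv_table averages across training sets per model type", {
  mk_cv <- function(tp, acc) {
    structure(list(model_type = tp, k = 10L,
                   per_fold = NULL,
                   mean = c(accuracy = acc, precision = acc, recall = acc,
                            f1 = acc, auroc = acc),
                   sd = c(accuracy = 0.01, precision = 0.01, recall = 0.01,
                          f1 = 0.01, auroc = 0.01)),
              class = "cv_metrics")
  }
  tab1 <- ensemble_cv_table(list(mk_cv("GB", 0.9)))
  expect_equal(tab1$accuracy_mean, 0.9)
  tab2 <- ensemble_cv_table(list(mk_cv("GB", 0.8), mk_cv("GB", 0.9),
                                 mk_cv("LR", 0.7)))
  expect_equal(tab2$accuracy_mean[tab2$model_type == "GB"], 0.85)
  tab5 <- ensemble_cv_table(lapply(c("GB", "GNB", "LR", "RF", "SVM"),
                                   mk_cv, acc = 0.8))
  expect_identical(tab5$model_type, c("GB", "GNB", "LR", "RF", "SVM"))
})

test_that("GB feature ranking recovers planted signal and counts families", {
  d <- toy_signal_data(n = 80, n_sig = 6, n_noise = 24,
                       p1 = 0.9, p0 = 0.05, seed = 12)
  fam <- setNames(rep(c("SIG", "NOISE"), c(6, 24)), d$features)
  m <- gene_feature_matrix(as.matrix(d$matrix$values), fam)
  spec <- model_spec("GB", tune = FALSE, seed = 4)
  recs <- lapply(1:3, function(i)
    tune_and_train(spec, m, d$training_set, d$features, i))
  rk <- rank_features(recs, m, top_k = 6)
  expect_gte(mean(rk$ranking$family == "SIG"), 0.8)
  expect_identical(sum(rk$family_counts), 3L * 6L)  # models x top_k
  # identical importances across models: average equals each
  recs_same <- list(recs[[1]], recs[[1]])
  rk_same <- rank_features(recs_same, m, top_k = 6)
  expect_equal(rk_same$ranking$mean_importance,
               unname(sort(recs[[1]]$importances, decreasing = TRUE))[1:6])
  # records without importances are excluded with a warning
  bad <- recs[[1]]; bad$importances <- NULL
  expect_warning(rank_features(c(recs, list(bad)), m, top_k = 6),
                 "without importances")
})
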
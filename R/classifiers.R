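#' Model specification for one classifier type
#'
#' The five supported types are logistic regression (`LR`), Gaussian naive
#' Bayes (`GNB`), support vector machine (`SVM`), random forest (`RF`) and
#' gradient boosting (`GB`).  SVM is tuned by 3-fold grid search over kernel,
#' cost and (RBF) bandwidth; RF by a grid over tree count followed by a
#' randomized search over tree-shape parameters; GB by a grid over learning
#' rate and tree count followed by the same randomized tree-shape search.
#' LR and GNB train with defaults.  Setting `tune = FALSE` skips all search
#' and trains at `defaults` — useful to keep large synthetic runs fast.
#'
#' @param model_type one of `"LR"`, `"GNB"`, `"SVM"`, `"RF"`, `"GB"`.
#' @param tune logical; run the hyperparameter search protocol for this type.
#' @param grids named list overriding the default search grids.
#' @param defaults named list overriding default hyperparameters.
#' @param n_random number of randomized-search draws for RF/GB, default 20.
#' @param tune_folds folds for search cross-validation, default 3.
#' @param seed integer seed for all tuning/training randomness.
#' @return a `model_spec`.
#' @export
model_spec <- function(model_type, tune = TRUE, grids = list(),
                       defaults = list(), n_random = 20L, tune_folds = 3L,
                       seed = 1L) {
  model_type <- match.arg(model_type, c("LR", "GNB", "SVM", "RF", "GB"))
  base_grids <- list(
    SVM = list(kernel = c("linear", "rbf"), cost = c(0.1, 1, 10, 100),
               gamma = c(0.001, 0.01, 0.1, 1)),
    RF = list(n_trees = c(100L, 200L, 500L)),
    GB = list(learning_rate = c(0.01, 0.1, 0.3), n_trees = c(100L, 200L, 500L)),
    tree_random = list(max_features = c(0.1, 0.3, 0.5, NA),  # NA = sqrt(p)
                       max_depth = c(2L, 3L, 5L, 8L, 12L),
                       min_split = c(2L, 5L, 10L),
                       min_leaf = c(1L, 2L, 5L)))
  structure(list(model_type = model_type, tune = isTRUE(tune),
                 grids = modifyList(base_grids, grids),
                 defaults = defaults, n_random = as.integer(n_random),
                 tune_folds = as.integer(tune_folds), seed = as.integer(seed)),
            class = "model_spec")
}

.cv_score <- function(model_type, X, y, hyper, k, seed) {
  folds <- .stratified_folds(y, k, seed)
  accs <- vapply(folds, function(f) {
    tr <- setdiff(seq_along(y), f)
    fit <- .fit_model(model_type, X[tr, , drop = FALSE], y[tr], hyper, seed)
    mean((.predict_model(fit, X[f, , drop = FALSE]) >= 0.5) == (y[f] == 1L))
  }, 0)
  mean(accs)
}

.grid_expand <- function(grid) {
  df <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

.random_tree_params <- function(spec, p, n_draws) {
  g <- spec$grids$tree_random
  lapply(seq_len(n_draws), function(i) {
    mf <- sample(g$max_features, 1L)
    list(mtry = if (is.na(mf)) max(1L, floor(sqrt(p))) else max(1L, floor(mf * p)),
         max_depth = sample(g$max_depth, 1L),
         min_split = sample(g$min_split, 1L),
         min_leaf = sample(g$min_leaf, 1L))
  })
}

.tune_hyper <- function(spec, X, y) {
  k <- spec$tune_folds; seed <- spec$seed
  pick_best <- function(cands) {
    scores <- vapply(cands, function(h)
      .cv_score(spec$model_type, X, y, h, k, seed), 0)
    cands[[which.max(scores)]]  # ties: first in order, deterministic
  }
  if (spec$model_type == "SVM") {
    g <- spec$grids$SVM
    cands <- c(lapply(g$cost, function(co) list(kernel = "linear", cost = co)),
               if ("rbf" %in% g$kernel)
                 .grid_expand(list(kernel = "rbf", cost = g$cost, gamma = g$gamma)))
    cands <- Filter(function(h) h$kernel %in% g$kernel, cands)
    return(pick_best(cands))
  }
  if (spec$model_type == "RF") {
    best <- pick_best(lapply(spec$grids$RF$n_trees, function(nt) list(n_trees = nt)))
    set.seed(seed + 17L)
    cands <- lapply(.random_tree_params(spec, ncol(X), spec$n_random),
                    function(h) c(best, h))
    return(pick_best(cands))
  }
  if (spec$model_type == "GB") {
    best <- pick_best(.grid_expand(spec$grids$GB))
    set.seed(seed + 17L)
    cands <- lapply(.random_tree_params(spec, ncol(X), spec$n_random),
                    function(h) c(best, h))
    return(pick_best(cands))
  }
  list()
}

#' Tune and train one classifier on one balanced training set
#'
#' Runs the type-specific hyperparameter search (unless `tune = FALSE` in the
#' spec), then fits the final model on the full training set with the chosen
#' hyperparameters.
#'
#' @param spec a [model_spec()].
#' @param matrix a `gene_feature_matrix`.
#' @param training_set data.frame with `gene_id` and binary `label` columns
#'   (one element of a `balanced_ensemble_design`).
#' @param merged_features the fixed post-filter feature list.
#' @param set_index index of the training set within the ensemble (recorded,
#'   and folded into the seed so sibling models differ).
#' @return a `trained_model_record` with the fit, chosen hyperparameters and
#'   (for RF/GB) normalized feature importances.
#' @export
tune_and_train <- function(spec, matrix, training_set, merged_features,
                           set_index = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  X <- .design_matrix(matrix, training_set$gene_id, merged_features)
  y <- as.integer(training_set$label)
  if (!all(y %in% c(0L, 1L))) stop("training labels must be binary 0/1")
  seed <- spec$seed + 1000L * set_index
  spec_local <- spec; spec_local$seed <- seed
  hyper <- spec$defaults
  if (spec$tune && spec$model_type %in% c("SVM", "RF", "GB"))
    hyper <- modifyList(.tune_hyper(spec_local, X, y), spec$defaults)
  fit <- .fit_model(spec$model_type, X, y, hyper, seed)
  structure(list(model_type = spec$model_type, set_index = as.integer(set_index),
                 hyperparameters = hyper, fit = fit,
                 features = merged_features,
                 importances = fit$importances, seed = seed),
            class = "trained_model_record")
}

#' Score genes with a trained model record
#' @param record a `trained_model_record`.
#' @param matrix a `gene_feature_matrix`.
#' @param genes gene ids to score (default all genes in the matrix).
#' @return named numeric vector of Class-1 probabilities.
#' @export
score_genes <- function(record, matrix, genes = gene_ids(matrix)) {
  X <- .design_matrix(matrix, genes, record$features)
  setNames(.predict_model(record$fit, X), genes)
}

#' Stratified k-fold cross-validation of one classifier on one training set
#'
#' Folds are stratified by class and seeded.  Metrics are computed
#' out-of-fold per fold and then averaged; the per-fold AUROC uses the
#' out-of-fold scores of that fold.
#'
#' @inheritParams tune_and_train
#' @param k number of folds, default 10.
#' @param hyper hyperparameters for the fits (default: the spec defaults).
#' @param seed fold seed.
#' @return a `cv_metrics`: data.frame `per_fold` plus `mean` / `sd` rows over
#'   accuracy, precision, recall, f1, auroc.
#' @export
cross_validate <- function(spec, matrix, training_set, merged_features,
                           k = 10L, hyper = spec$defaults, seed = spec$seed) {
  X <- .design_matrix(matrix, training_set$gene_id, merged_features)
  y <- as.integer(training_set$label)
  if (length(y) < k) stop("training set smaller than fold count")
  folds <- .stratified_folds(y, k, seed)
  if (any(vapply(folds, function(f) length(unique(y[f])) < 2L, TRUE)))
    stop("a fold contains a single class; reduce k")
  rows <- lapply(folds, function(f) {
    tr <- setdiff(seq_along(y), f)
    fit <- .fit_model(spec$model_type, X[tr, , drop = FALSE], y[tr], hyper, seed)
    m <- compute_metrics(y[f], .predict_model(fit, X[f, , drop = FALSE]))
    data.frame(accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, auroc = m$auroc)
  })
  per_fold <- do.call(rbind, rows)
  rownames(per_fold) <- NULL
  structure(list(model_type = spec$model_type, k = as.integer(k),
                 per_fold = per_fold,
                 mean = colMeans(per_fold), sd = apply(per_fold, 2, sd)),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("cv_metrics (%s, %d-fold): acc %.3f+/-%.3f auroc %.3f+/-%.3f\n",
              x$model_type, x$k, x$mean["accuracy"], x$sd["accuracy"],
              x$mean["auroc"], x$sd["auroc"]))
  invisible(x)
}

#' Summarize cross-validation metrics across a model-type ensemble
#'
#' Averages per-training-set CV means (and their sds) across the ensemble,
#' one row per model type, alphabetical row order.
#'
#' @param cv_list list of `cv_metrics` objects (any mix of model types).
#' @return data.frame with columns `model_type`, then `<metric>_mean` and
#'   `<metric>_sd` for accuracy, precision, recall, f1, auroc.
#' @export
ensemble_cv_table <- function(cv_list) {
  stopifnot(length(cv_list) >= 1L)
  types <- sort(unique(vapply(cv_list, `[[`, "", "model_type")))
  metrics <- c("accuracy", "precision", "recall", "f1", "auroc")
  rows <- lapply(types, function(tp) {
    sub <- Filter(function(cv) cv$model_type == tp, cv_list)
    means <- colMeans(do.call(rbind, lapply(sub, `[[`, "mean")))[metrics]
    sds <- colMeans(do.call(rbind, lapply(sub, `[[`, "sd")))[metrics]
    out <- data.frame(model_type = tp)
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- means[[m]]
      out[[paste0(m, "_sd")]] <- sds[[m]]
    }
    out
  })
  do.call(rbind, rows)
}

#' Rank features by averaged gradient-boosting importance
#'
#' Averages normalized importances across the supplied tree-model records,
#' returns the `top_k` features, and tabulates the dataset-family composition
#' of each model's individual top-`top_k` list.
#'
#' @param records list of `trained_model_record`s carrying importances
#'   (GB, or RF); records without importances are dropped with a warning.
#' @param matrix the `gene_feature_matrix` (for family labels).
#' @param top_k how many features to report, default 100.
#' @return list: `ranking` (data.frame feature_id, mean_importance, family),
#'   `family_counts` (family x count over all models' top-k lists).
#' @export
rank_features <- function(records, matrix, top_k = 100L) {
  has_imp <- vapply(records, function(r) !is.null(r$importances), TRUE)
  if (any(!has_imp)) {
    warning(sum(!has_imp), " record(s) without importances excluded")
    records <- records[has_imp]
  }
  if (!length(records)) stop("no records with feature importances")
  imp_mat <- do.call(rbind, lapply(records, `[[`, "importances"))
  mean_imp <- colMeans(imp_mat)
  ord <- order(-mean_imp, names(mean_imp))
  top <- head(ord, top_k)
  ranking <- data.frame(feature_id = names(mean_imp)[top],
                        mean_importance = unname(mean_imp)[top],
                        family = unname(matrix$feature_family[names(mean_imp)[top]]))
  per_model_top <- lapply(seq_len(nrow(imp_mat)), function(i) {
    o <- order(-imp_mat[i, ], colnames(imp_mat))
    matrix$feature_family[colnames(imp_mat)[head(o, top_k)]]
  })
  family_counts <- table(unlist(per_model_top))
  list(ranking = ranking, family_counts = family_counts)
}
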
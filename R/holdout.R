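#' Evaluate an ensemble on balanced held-out test sets
#'
#' Every model is evaluated on every balanced test set; the report averages
#' each metric over all (model, test set) pairs.
#'
#' @param records list of `trained_model_record`s.
#' @param matrix a `gene_feature_matrix`.
#' @param test_sets list of data.frames (`gene_id`, `label`) from
#'   [build_test_sets()].
#' @param train_genes optional character vector of genes used in training;
#'   overlap with any test set is a hard error.
#' @return a `holdout_report` with `pair_metrics` (data.frame over model x
#'   test set) and `averaged` (named means).
#' @export
evaluate_on_test_sets <- function(records, matrix, test_sets,
                                  train_genes = NULL) {
  stopifnot(length(records) >= 1L, length(test_sets) >= 1L)
  if (!is.null(train_genes)) {
    overlap <- intersect(train_genes, unlist(lapply(test_sets, `[[`, "gene_id")))
    if (length(overlap))
      stop("train/test contamination: ", paste(head(overlap, 5), collapse = ", "))
  }
  metrics <- c("accuracy", "precision", "recall", "f1", "auroc")
  rows <- list()
  for (mi in seq_along(records)) {
    # score the union of test genes once per model, reuse across test sets
    all_genes <- unique(unlist(lapply(test_sets, `[[`, "gene_id")))
    sc <- score_genes(records[[mi]], matrix, all_genes)
    for (ti in seq_along(test_sets)) {
      ts <- test_sets[[ti]]
      m <- compute_metrics(ts$label, sc[ts$gene_id])
      rows[[length(rows) + 1L]] <-
        data.frame(model = mi, test_set = ti,
                   accuracy = m$accuracy, precision = m$precision,
                   recall = m$recall, f1 = m$f1, auroc = m$auroc)
    }
  }
  pair_metrics <- do.call(rbind, rows)
  structure(list(pair_metrics = pair_metrics,
                 averaged = colMeans(pair_metrics[, metrics])),
            class = "holdout_report")
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf("holdout_report: %d (model x test set) pairs | acc %.3f auroc %.3f\n",
              nrow(x$pair_metrics), x$averaged["accuracy"], x$averaged["auroc"]))
  invisible(x)
}

#' Pooled hold-out scoring and false positive rate
#'
#' Pools all held-out positives and negatives, averages each gene's
#' predicted probability across every model of the ensemble, and reports the
#' false positive rate FP/(FP+TN) at the classification threshold.
#'
#' @param records list of `trained_model_record`s.
#' @param matrix a `gene_feature_matrix`.
#' @param pos_test,neg_test held-out gene-id vectors.
#' @param threshold probability threshold calling Class 1, default 0.5.
#' @return list: `scores` (named mean probability over the pool), `labels`,
#'   `fpr`, `metrics` (full [compute_metrics()] object).
#' @export
pooled_holdout_rates <- function(records, matrix, pos_test, neg_test,
                                 threshold = 0.5) {
  if (length(neg_test) == 0L) stop("empty negative pool")
  pool <- c(pos_test, neg_test)
  pred <- predict_genome(records, matrix, genes = pool, keep_per_model = FALSE)
  labels <- rep(c(1L, 0L), c(length(pos_test), length(neg_test)))
  m <- compute_metrics(labels, pred$mean_probability[pool], threshold)
  list(scores = pred$mean_probability[pool], labels = setNames(labels, pool),
       fpr = m$fpr, metrics = m)
}

#' Error rates within the top-k pooled predictions
#'
#' Selects the `k` genes with the highest pooled mean scores (ties broken by
#' gene id) and reports the false discovery rate FP/(FP+TP) within the
#' selection and the false positive rate FP/(FP+TN) over the whole pool.
#'
#' @param scores named numeric vector of pooled mean probabilities.
#' @param labels named 0/1 vector over the same genes.
#' @param k size of the prediction window, default 25.
#' @return list with `fdr`, `fpr`, `selected` (gene ids), `tp`, `fp`.
#' @export
top_k_rates <- function(scores, labels, k = 25L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= length(scores))
  labels <- labels[names(scores)]
  ord <- order(-scores, names(scores))
  sel <- names(scores)[ord][seq_len(k)]
  tp <- sum(labels[sel] == 1L); fp <- k - tp
  tn <- sum(labels == 0L) - fp
  list(fdr = if (fp + tp > 0) fp / (fp + tp) else 0,
       fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
       selected = sel, tp = tp, fp = fp)
}
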
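#' Zero-fraction feature filter
#'
#' Removes features whose value is zero in strictly more than
#' `max_zero_fraction` of the genes in a training set (the "excessive
#' missingness" rule); a feature that is zero in exactly 70% of samples is
#' kept.
#'
#' @param matrix a `gene_feature_matrix`.
#' @param gene_subset character vector of gene ids (a training set).
#' @param max_zero_fraction removal threshold, default 0.7.
#' @return character vector of kept feature ids.
#' @export
zero_fraction_filter <- function(matrix, gene_subset, max_zero_fraction = 0.7) {
  sub <- .subset_rows(matrix, gene_subset)
  zero_frac <- 1 - Matrix::colSums(sub) / nrow(sub)
  colnames(sub)[zero_frac <= max_zero_fraction]
}

#' Variance feature filter
#'
#' Keeps features whose population variance over the training set is at
#' least `min_variance` (inclusive).  For a binary feature with frequency
#' `p` the population variance is `p(1-p)`, so the default 0.16 keeps
#' exactly the frequencies `p` in `[0.2, 0.8]`.
#'
#' @inheritParams zero_fraction_filter
#' @param min_variance minimum population variance retained, default 0.16.
#' @return character vector of kept feature ids.
#' @export
variance_filter <- function(matrix, gene_subset, min_variance = 0.16) {
  sub <- .subset_rows(matrix, gene_subset)
  p <- Matrix::colSums(sub) / nrow(sub)
  v <- p * (1 - p)  # population variance of a 0/1 feature
  colnames(sub)[v >= min_variance - 1e-12]
}

.subset_rows <- function(matrix, gene_subset) {
  stopifnot(inherits(matrix, "gene_feature_matrix"))
  if (length(gene_subset) == 0L) stop("empty gene subset")
  miss <- setdiff(gene_subset, gene_ids(matrix))
  if (length(miss)) stop("genes not in matrix: ", paste(head(miss, 5), collapse = ", "))
  matrix$values[gene_subset, , drop = FALSE]
}

#' Select features across the balanced training ensemble
#'
#' Applies both filters to every balanced training set, keeps per set the
#' features surviving either filter (`combine = "union"`, the default) or
#' both (`combine = "intersection"`), then merges the per-set kept lists
#' across the ensemble (union).  The merged list is fixed for all subsequent
#' training, cross-validation and genome-wide prediction.
#'
#' The default is union-within-set: a binary feature passes the variance
#' rule iff its in-set frequency lies in `[0.2, 0.8]` and the zero-fraction
#' rule iff its frequency is at least `0.3`, so requiring both would silently
#' discard every feature with frequency in `[0.2, 0.3)` — including planted
#' class signal at frequency `(p1 + p0)/2` for moderate `p1` — and an
#' all-noise set would always come out empty.  Either-filter retention keeps
#' exactly the frequencies `[0.2, 1.0]` and preserves the intended
#' low-information screen.
#'
#' @param matrix a `gene_feature_matrix`.
#' @param design a `balanced_ensemble_design`.
#' @param max_zero_fraction,min_variance filter thresholds.
#' @param combine how the two filters combine within a training set.
#' @return a `filter_report`: `per_set_kept` (list), `merged` (character,
#'   matrix column order), and the thresholds used.
#' @export
select_features <- function(matrix, design,
                            max_zero_fraction = 0.7, min_variance = 0.16,
                            combine = c("union", "intersection")) {
  stopifnot(inherits(design, "balanced_ensemble_design"))
  combine <- match.arg(combine)
  comb_fun <- if (combine == "union") union else intersect
  per_set <- lapply(design$training_sets, function(ts) {
    genes <- ts$gene_id
    intersect(feature_ids(matrix),
              comb_fun(zero_fraction_filter(matrix, genes, max_zero_fraction),
                       variance_filter(matrix, genes, min_variance)))
  })
  merged <- intersect(feature_ids(matrix), unique(unlist(per_set)))
  if (length(merged) == 0L)
    stop("no features survive filtering in any training set")
  structure(list(per_set_kept = per_set, merged = merged,
                 max_zero_fraction = max_zero_fraction,
                 min_variance = min_variance),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d merged features from %d training sets\n",
              length(x$merged), length(x$per_set_kept)))
  invisible(x)
}

#' Write a filter report as a per-feature TSV
#' @param report a `filter_report`.
#' @param matrix the `gene_feature_matrix` the report was computed on.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_filter_report <- function(report, matrix, path) {
  counts <- table(factor(unlist(report$per_set_kept), levels = feature_ids(matrix)))
  tab <- data.frame(feature_id = feature_ids(matrix),
                    n_sets_kept = as.integer(counts),
                    merged_flag = as.integer(feature_ids(matrix) %in% report$merged))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
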
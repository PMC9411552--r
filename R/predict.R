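#' Genome-wide ensemble prediction
#'
#' Scores every gene in the matrix with every model of one model-type
#' ensemble and averages the Class-1 probabilities per gene.  Genes that
#' served as training negatives for one block are still scored by all
#' models, including the model trained on "their" block: with hundreds of
#' models the contribution of any single one to the mean is negligible.
#'
#' @param records list of `trained_model_record`s (all the same model type).
#' @param matrix a `gene_feature_matrix`.
#' @param genes gene ids to score; default all genes.
#' @param keep_per_model store the per-model score matrix, default TRUE.
#' @return an `ensemble_prediction`: `mean_probability` (named numeric),
#'   `per_model` (genes x models matrix or NULL), `model_type`, `n_models`.
#' @export
predict_genome <- function(records, matrix, genes = gene_ids(matrix),
                           keep_per_model = TRUE) {
  stopifnot(length(records) >= 1L)
  types <- unique(vapply(records, `[[`, "", "model_type"))
  if (length(types) != 1L)
    stop("records mix model types: ", paste(types, collapse = ", "))
  scores <- vapply(records, score_genes, numeric(length(genes)),
                   matrix = matrix, genes = genes)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = length(genes))
  rownames(scores) <- genes
  colnames(scores) <- paste0("model_", vapply(records, `[[`, 1L, "set_index"))
  structure(list(mean_probability = setNames(rowMeans(scores), genes),
                 per_model = if (keep_per_model) scores else NULL,
                 model_type = types, n_models = length(records)),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("ensemble_prediction (%s): %d genes x %d models, mean prob %.3f\n",
              x$model_type, length(x$mean_probability), x$n_models,
              mean(x$mean_probability)))
  invisible(x)
}

#' High-confidence call set: top fraction of the probability distribution
#'
#' The cutoff is the score of the `ceil(fraction * n)`-th ranked gene; all
#' genes scoring at or above the cutoff are returned, so ties at the
#' boundary expand the set rather than being broken arbitrarily (a
#' classifier that assigns one probability to many genes yields a larger
#' call set).
#'
#' @param pred an `ensemble_prediction`.
#' @param fraction top fraction called, default 0.01.
#' @return character vector of gene ids, ordered by descending probability
#'   then gene id.
#' @export
top_fraction <- function(pred, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  p <- pred$mean_probability
  n_call <- ceiling(fraction * length(p))
  cutoff <- sort(p, decreasing = TRUE)[n_call]
  called <- p[p >= cutoff]
  names(called)[order(-called, names(called))]
}

#' Consensus genes across model-type ensembles
#'
#' @param top_sets named list of high-confidence gene-id vectors, one per
#'   model type.
#' @param min_models minimum number of ensembles a gene must appear in.
#' @return list: `consensus` (gene ids, sorted), `support` (named integer
#'   count per gene appearing in at least one set).
#' @export
ensemble_overlap <- function(top_sets, min_models = 3L) {
  if (min_models > length(top_sets))
    stop("min_models exceeds the number of ensembles")
  support <- table(unlist(lapply(top_sets, unique)))
  support <- setNames(as.integer(support), names(support))
  list(consensus = sort(names(support)[support >= min_models]),
       support = support)
}

#' Top novel candidates, excluding known positives
#'
#' @param pred an `ensemble_prediction`.
#' @param k number of candidates, default 100.
#' @param exclude gene ids to drop before ranking (the known Class-1 genes).
#' @return data.frame `gene_id`, `mean_probability`, ranked by descending
#'   probability with lexicographic tie-break.
#' @export
top_candidates <- function(pred, k = 100L, exclude = character(0)) {
  stopifnot(k >= 1L)
  p <- pred$mean_probability[!(names(pred$mean_probability) %in% exclude)]
  if (k > length(p)) stop("k exceeds the number of candidate genes")
  ord <- order(-p, names(p))
  data.frame(gene_id = names(p)[ord][seq_len(k)],
             mean_probability = unname(p)[ord][seq_len(k)])
}
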
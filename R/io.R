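#' Read a binary gene-by-feature matrix from TSV
#'
#' Expects a header row of feature ids with the first column holding gene
#' ids, and a companion two-column TSV (`feature_id<TAB>family`) mapping each
#' feature to its dataset family.  Cells are coerced strictly to `{0,1}`; any
#' other value is a hard error naming the offending gene and feature.
#'
#' @param path TSV file of 0/1 values.
#' @param family_path two-column TSV (with header) of feature id, family.
#' @return a [gene_feature_matrix()].
#' @export
read_feature_matrix <- function(path, family_path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  gid <- tab[[1L]]
  if (anyDuplicated(gid)) stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  fid <- colnames(tab)[-1L]
  if (anyDuplicated(fid)) stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!(vals %in% c("0", "1")))
  if (length(bad)) {
    i <- (bad[1L] - 1L) %% nrow(vals) + 1L
    j <- (bad[1L] - 1L) %/% nrow(vals) + 1L
    stop(sprintf("non-binary cell at gene '%s', feature '%s': %s",
                 gid[i], fid[j], vals[bad[1L]]))
  }
  m <- matrix(as.numeric(vals), nrow = nrow(vals),
              dimnames = list(gid, fid))
  fam <- utils::read.delim(family_path, colClasses = "character")
  gene_feature_matrix(m, setNames(fam[[2L]], fam[[1L]]))
}

#' Write a gene feature matrix (and its family map) to TSV
#'
#' @param x a `gene_feature_matrix`.
#' @param path output TSV path for the matrix.
#' @param family_path output TSV path for the feature-family map.
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(x, path, family_path) {
  dense <- as.matrix(x$values)
  tab <- data.frame(gene_id = rownames(dense), dense, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fam <- data.frame(feature_id = names(x$feature_family),
                    family = unname(x$feature_family))
  utils::write.table(fam, family_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style PPI edge list
#'
#' Three columns (node, node, combined score on 0-1000).  Edges at or above
#' `min_score` are retained (inclusive threshold); duplicate pairs collapse
#' to their maximum score; self-loops are dropped with a message.
#'
#' @param path TSV with three columns, with or without a header row.
#' @param min_score minimum combined score retained, default 400.
#' @return a [ppi_graph()].
#' @export
read_ppi_edges <- function(path, min_score = 400L) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3L])))
  tab <- utils::read.delim(path, header = has_header,
                           colClasses = c("character", "character", "numeric"))
  names(tab) <- c("a", "b", "score")
  if (any(tab$score != floor(tab$score)))
    stop("combined scores must be integers on the 0-1000 scale")
  ppi_graph(tab, min_score = min_score)
}

#' Write a PPI graph back to a STRING-style TSV
#' @param graph a `ppi_graph`
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_ppi_edges <- function(graph, path) {
  out <- graph$edges
  names(out) <- c("protein1", "protein2", "combined_score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path GMT file path.
#' @return [gene_set_collection()] for `read_gmt`; invisibly `path` for
#'   `write_gmt`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", "")
  members <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(members) <- nm
  gene_set_collection(members, desc)
}

#' @rdname read_gmt
#' @param x a `gene_set_collection`
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(nm)
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write ranked genome-wide predictions to TSV
#'
#' Rows are sorted by descending mean probability with ties broken
#' lexicographically by gene id, so output files are reproducible.
#'
#' @param pred an `ensemble_prediction` (see [predict_genome()]).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_predictions <- function(pred, path) {
  ord <- order(-pred$mean_probability, names(pred$mean_probability))
  tab <- data.frame(gene_id = names(pred$mean_probability)[ord],
                    mean_probability = unname(pred$mean_probability)[ord])
  if (!is.null(pred$per_model))
    tab <- cbind(tab, as.data.frame(pred$per_model[ord, , drop = FALSE],
                                    check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#' @param path TSV path.
#' @return an `ensemble_prediction` with the stored per-model columns, if any.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  per_model <- NULL
  if (ncol(tab) > 2L) {
    per_model <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(per_model) <- tab$gene_id
  }
  structure(list(mean_probability = setNames(tab$mean_probability, tab$gene_id),
                 per_model = per_model,
                 model_type = NA_character_,
                 n_models = if (is.null(per_model)) NA_integer_ else ncol(per_model)),
            class = "ensemble_prediction")
}
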
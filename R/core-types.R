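#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t crossprod
#' @importFrom stats var phyper p.adjust predict glm binomial quantile
#'   plogis rbinom runif rnorm setNames wilcox.test sd
#' @importFrom utils head modifyList
NULL

#' Construct a binary gene-by-attribute feature matrix
#'
#' The central container of the pipeline: a sparse binary matrix of genes
#' (rows) by one-hot attribute features (columns), where a 1 records that the
#' gene is among the strongest associations of that attribute in its source
#' dataset.  Every feature carries a dataset-family tag (e.g. `"GTEx"`,
#' `"GO"`) used for the family breakdown of feature-importance rankings.
#'
#' @param values matrix or `Matrix` coercible to sparse, with unique rownames
#'   (gene ids) and colnames (feature ids); all entries must be 0 or 1.
#' @param feature_family named character vector mapping every feature id to
#'   exactly one family label.
#' @return An object of class `gene_feature_matrix` with elements `values`
#'   (a `dgCMatrix`) and `feature_family`.
#' @export
gene_feature_matrix <- function(values, feature_family) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  gid <- rownames(values); fid <- colnames(values)
  if (is.null(gid) || is.null(fid))
    stop("values must carry gene rownames and feature colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  bad <- which(!(values@x %in% c(0, 1)))
  if (length(bad)) {
    ij <- .x_slot_position(values, bad[1L])
    stop(sprintf("non-binary cell at gene '%s', feature '%s': %s",
                 gid[ij[1L]], fid[ij[2L]], format(values@x[bad[1L]])))
  }
  values <- Matrix::drop0(values)
  feature_family <- .check_family(feature_family, fid)
  structure(list(values = values, feature_family = feature_family),
            class = "gene_feature_matrix")
}

.x_slot_position <- function(m, k) {
  # row/col of the k-th stored element of a dgCMatrix
  col <- findInterval(k - 1L, m@p[-1L]) + 1L
  c(m@i[k] + 1L, col)
}

.check_family <- function(feature_family, fid) {
  if (is.null(names(feature_family)))
    stop("feature_family must be a named character vector")
  miss <- setdiff(fid, names(feature_family))
  if (length(miss))
    stop("features without family label: ", paste(head(miss, 5), collapse = ", "))
  as.character(feature_family)[match(fid, names(feature_family))] |>
    setNames(fid)
}

#' @export
print.gene_feature_matrix <- function(x, ...) {
  cat(sprintf("gene_feature_matrix: %d genes x %d features (%d families, %.2f%% nonzero)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$feature_family)),
              100 * length(x$values@x) / prod(dim(x$values))))
  invisible(x)
}

#' @export
dim.gene_feature_matrix <- function(x) dim(x$values)

#' Gene and feature identifiers of a feature matrix
#' @param x a `gene_feature_matrix`
#' @return character vector of ids, in storage order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Positive / universe label set
#'
#' Class 1 is the positive gene list; Class 0 is implicitly everything else
#' in the universe.
#'
#' @param positives character vector of positive (Class 1) gene ids.
#' @param universe character vector of all gene ids under consideration.
#' @return `label_set` object with `positives`, `universe` and the derived
#'   `negatives`.
#' @export
label_set <- function(positives, universe) {
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  out <- setdiff(positives, universe)
  if (length(out))
    stop("positives not in universe: ", paste(head(out, 5), collapse = ", "))
  structure(list(positives = positives, universe = universe,
                 negatives = setdiff(universe, positives)),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %d positives / %d universe\n",
              length(x$positives), length(x$universe)))
  invisible(x)
}

#' Undirected weighted protein-protein interaction graph
#'
#' Stored as a canonical edge table (`a < b` lexicographically) with integer
#' combined scores on the 0-1000 STRING scale.  Self-loops are dropped and
#' duplicate pairs collapsed keeping the maximum score.
#'
#' @param edges data.frame with columns `a`, `b`, `score`.
#' @param nodes optional character vector of node ids; defaults to the nodes
#'   present in `edges`.  Extra isolated nodes are allowed.
#' @param min_score threshold recorded on the object; edges below it are
#'   removed (inclusive retention: `score >= min_score`).
#' @return `ppi_graph` object with `nodes`, `edges`, `min_score`.
#' @export
ppi_graph <- function(edges, nodes = NULL, min_score = 0L) {
  stopifnot(all(c("a", "b", "score") %in% names(edges)))
  edges$a <- as.character(edges$a); edges$b <- as.character(edges$b)
  edges$score <- as.integer(edges$score)
  if (any(edges$score < 0L | edges$score > 1000L))
    stop("combined score outside [0, 1000]")
  loops <- edges$a == edges$b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  if (nrow(edges)) {
    key <- paste(edges$a, edges$b, sep = "\r")
    edges <- do.call(rbind, lapply(split(edges, key), function(d)
      d[which.max(d$score), , drop = FALSE]))
  }
  edges <- edges[edges$score >= min_score, , drop = FALSE]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(nodes, edges$a, edges$b)))
  structure(list(nodes = nodes, edges = edges, min_score = as.integer(min_score)),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges (combined score >= %d)\n",
              length(x$nodes), nrow(x$edges), x$min_score))
  invisible(x)
}

#' Convert a ppi_graph to an igraph object
#' @param graph a `ppi_graph`
#' @param weighted logical; attach `score/1000` as edge weight.
#' @return an `igraph` undirected graph.
#' @export
as_igraph <- function(graph, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  if (weighted)
    igraph::E(g)$weight <- graph$edges$score / 1000
  g
}

#' Named collection of gene sets (GMT semantics)
#'
#' @param sets named list of character vectors (members); names are set ids.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene set names must be present and unique")
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set: ", empty[1L])
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets,
                 descriptions = setNames(as.character(descriptions), names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Confusion-derived classification metrics
#'
#' Computes the standard binary-classification metrics from labels and
#' scores at a probability threshold; the AUROC uses the rank statistic with
#' midranks so ties are handled exactly.
#'
#' @param truth integer/logical vector of true labels (1 = positive class).
#' @param scores numeric vector of Class-1 probabilities in `[0,1]`.
#' @param threshold decision threshold; `score >= threshold` calls Class 1.
#' @return `metrics` object: counts `tp fp tn fn` plus `accuracy precision
#'   recall f1 auroc fpr fdr`.  AUROC is `NA` (with a warning) when truth is
#'   single-class.
#' @export
compute_metrics <- function(truth, scores, threshold = 0.5) {
  truth <- as.integer(truth)
  stopifnot(length(truth) == length(scores),
            all(truth %in% c(0L, 1L)))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  call1 <- scores >= threshold
  tp <- sum(call1 & truth == 1L); fp <- sum(call1 & truth == 0L)
  tn <- sum(!call1 & truth == 0L); fn <- sum(!call1 & truth == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("single-class truth: AUROC undefined")
    auroc <- NA_real_
  } else {
    r <- rank(scores)  # midranks
    auroc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(truth),
                 precision = precision, recall = recall, f1 = f1,
                 auroc = auroc,
                 fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
                 fdr = if (fp + tp > 0) fp / (fp + tp) else 0),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf(paste0("metrics: tp=%d fp=%d tn=%d fn=%d | acc=%.3f prec=%.3f ",
                     "rec=%.3f f1=%.3f auroc=%s fpr=%.3f fdr=%.3f\n"),
              x$tp, x$fp, x$tn, x$fn, x$accuracy, x$precision, x$recall, x$f1,
              ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
              x$fpr, x$fdr))
  invisible(x)
}
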
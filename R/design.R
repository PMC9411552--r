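#' Stratified train/test split of the labelled genome
#'
#' Splits positives and negatives independently, keeping `test_fraction` of
#' each class (floor on the test side) for final evaluation.  With 92
#' positives and a 0.2 test fraction this yields the canonical 74 training /
#' 18 test positives.
#'
#' @param labels a [label_set()].
#' @param test_fraction fraction held out per class, in (0, 1).
#' @param seed integer seed controlling membership.
#' @return a `split_spec` with `pos_train`, `pos_test`, `neg_train`,
#'   `neg_test`, plus the fraction and seed used.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(labels, "label_set"),
            test_fraction > 0, test_fraction < 1,
            length(labels$positives) >= 2L)
  n_pos_test <- floor(test_fraction * length(labels$positives))
  n_neg_test <- floor(test_fraction * length(labels$negatives))
  if (n_pos_test == 0L || n_pos_test == length(labels$positives))
    stop("test fraction leaves an empty positive partition")
  if (length(labels$negatives) > 0L &&
      (n_neg_test == 0L || n_neg_test == length(labels$negatives)))
    stop("test fraction leaves an empty negative partition")
  set.seed(seed)
  pos_test <- sort(sample(labels$positives, n_pos_test))
  neg_test <- sort(sample(labels$negatives, n_neg_test))
  structure(list(pos_train = sort(setdiff(labels$positives, pos_test)),
                 pos_test = pos_test,
                 neg_train = sort(setdiff(labels$negatives, neg_test)),
                 neg_test = neg_test,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec: pos %d/%d train/test, neg %d/%d train/test\n",
              length(x$pos_train), length(x$pos_test),
              length(x$neg_train), length(x$neg_test)))
  invisible(x)
}

#' Partition negatives into disjoint balanced blocks
#'
#' Randomly assigns negative gene ids to `floor(n / block_size)` disjoint
#' blocks of exactly `block_size` genes each; the `n %% block_size` leftover
#' genes are returned unassigned (and reported), since an exact
#' use-each-gene-once partition is impossible when the pool size is not a
#' multiple of the block size.
#'
#' @param neg_ids character vector of negative gene ids.
#' @param block_size number of genes per block (the training positive count).
#' @param seed integer seed for the random assignment.
#' @return list with `blocks` (list of character vectors) and `leftover`.
#' @export
partition_negatives <- function(neg_ids, block_size, seed = 1L) {
  stopifnot(block_size >= 1L)
  neg_ids <- as.character(neg_ids)
  n_blocks <- length(neg_ids) %/% block_size
  if (n_blocks == 0L) {
    warning("fewer negatives than block_size: zero blocks produced")
    return(list(blocks = list(), leftover = neg_ids))
  }
  set.seed(seed)
  shuffled <- sample(neg_ids)
  used <- n_blocks * block_size
  blocks <- split(shuffled[seq_len(used)],
                  rep(seq_len(n_blocks), each = block_size))
  names(blocks) <- NULL
  leftover <- shuffled[seq_len(length(neg_ids) - used) + used]
  if (length(leftover))
    message(length(leftover), " leftover negative(s) not assigned to any block")
  list(blocks = blocks, leftover = sort(leftover))
}

#' Build the balanced-ensemble training design
#'
#' Combines every negative training block with the full positive training
#' set, producing one balanced training set (size `2 * |pos_train|`) per
#' block; one classifier is later fitted per set, and each negative gene is
#' used by at most one of them.
#'
#' @param split a `split_spec` from [stratified_split()].
#' @param seed seed for the negative partition (defaults to the split seed
#'   plus one so the two draws are distinct).
#' @return a `balanced_ensemble_design` with `training_sets` (list of
#'   data.frames `gene_id`, `label`), `neg_blocks`, `leftover_negatives`.
#' @export
build_training_design <- function(split, seed = split$seed + 1L) {
  stopifnot(inherits(split, "split_spec"))
  part <- partition_negatives(split$neg_train, length(split$pos_train), seed)
  training_sets <- lapply(part$blocks, function(blk)
    data.frame(gene_id = c(split$pos_train, blk),
               label = rep(c(1L, 0L), c(length(split$pos_train), length(blk)))))
  structure(list(training_sets = training_sets,
                 neg_blocks = part$blocks,
                 leftover_negatives = part$leftover,
                 seed = as.integer(seed)),
            class = "balanced_ensemble_design")
}

#' @export
print.balanced_ensemble_design <- function(x, ...) {
  cat(sprintf("balanced_ensemble_design: %d training sets of %d genes (%d leftover negatives)\n",
              length(x$training_sets),
              if (length(x$training_sets)) nrow(x$training_sets[[1L]]) else 0L,
              length(x$leftover_negatives)))
  invisible(x)
}

#' Build balanced test sets from held-out genes
#'
#' Each test set combines all held-out positives with one disjoint block of
#' held-out negatives of the same size.
#'
#' @param pos_test character vector of held-out positive gene ids.
#' @param neg_test_blocks list of negative blocks from
#'   [partition_negatives()] applied to the held-out negatives.
#' @return list of data.frames (`gene_id`, `label`), one per block.
#' @export
build_test_sets <- function(pos_test, neg_test_blocks) {
  if (length(pos_test) == 0L) stop("pos_test is empty")
  lapply(neg_test_blocks, function(blk)
    data.frame(gene_id = c(pos_test, blk),
               label = rep(c(1L, 0L), c(length(pos_test), length(blk)))))
}

#' Serialize a split plus design to a provenance manifest table
#'
#' @param split a `split_spec`.
#' @param design a `balanced_ensemble_design`.
#' @return data.frame with columns `gene_id`, `role`, `block_index` (NA for
#'   genes not in a negative block).
#' @export
design_manifest <- function(split, design) {
  blk <- rep(seq_along(design$neg_blocks), lengths(design$neg_blocks))
  names(blk) <- unlist(design$neg_blocks)
  ids <- c(split$pos_train, split$pos_test, split$neg_train, split$neg_test)
  role <- rep(c("pos_train", "pos_test", "neg_train", "neg_test"),
              c(length(split$pos_train), length(split$pos_test),
                length(split$neg_train), length(split$neg_test)))
  data.frame(gene_id = ids, role = role,
             block_index = unname(blk[ids]))
}
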
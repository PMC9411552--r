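#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic genome whose statistical structure matches what the
#' prediction pipeline assumes: sparse one-hot features grouped into dataset
#' families, a subset of "signal" features enriched in the positive class
#' (Bernoulli `p1` for positives versus background `p0`), and an undirected
#' weighted PPI network with stochastic-block-model structure that
#' concentrates the positives in designated blocks.
#'
#' Defaults emulate the real data at roughly 1/10 genome scale: 3,000 genes,
#' 90 positives (the same ~0.3% class prevalence as 92 of 26,935), six
#' dataset families totalling 2,000 features of which 50 carry signal,
#' background rate `p0 = 0.05`, signal rate `p1 = 0.4`.
#'
#' @param seed integer master seed; all stage randomness derives from it by
#'   fixed offsets.
#' @param n_genes,n_positives genome size and positive-class size.
#' @param families data.frame with columns `name`, `n_features`,
#'   `n_signal`; one row per dataset family.
#' @param p0 background Bernoulli rate for every feature on negatives and for
#'   non-signal features on positives.
#' @param p1 Bernoulli rate of signal features on positive genes; must
#'   satisfy `p1 >= p0` (equality gives the null configuration).
#' @param block_sizes integer vector of network block sizes summing to
#'   `n_genes`.
#' @param positive_block_ids indices of blocks into which positives are
#'   placed (filled in order; must have capacity for all positives).
#' @param p_within,p_between stochastic-block-model edge probabilities.
#' @param score_within,score_between inclusive integer ranges (length-2) for
#'   combined scores of within- and between-block edges.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 3000L,
                             n_positives = 90L,
                             families = data.frame(
                               name = c("GTEx", "GO", "InterPro", "HPA",
                                        "BioGPS", "PathCommons"),
                               n_features = c(600L, 400L, 200L, 300L, 300L, 200L),
                               n_signal = c(15L, 15L, 5L, 5L, 5L, 5L)),
                             p0 = 0.05, p1 = 0.4,
                             block_sizes = c(150L, rep(570L, 5L)),
                             positive_block_ids = 1L,
                             p_within = 0.10, p_between = 0.002,
                             score_within = c(700L, 1000L),
                             score_between = c(400L, 699L)) {
  families <- as.data.frame(families)  # tolerate YAML column lists
  stopifnot(n_positives < n_genes,
            p0 > 0, p0 < 1, p1 > 0, p1 < 1,
            all(c("name", "n_features", "n_signal") %in% names(families)),
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            length(score_within) == 2L, length(score_between) == 2L)
  if (p1 < p0) stop("p1 < p0: the planted effect must be non-negative")
  if (any(families$n_signal > families$n_features))
    stop("n_signal exceeds n_features for family ",
         families$name[families$n_signal > families$n_features][1L])
  if (sum(block_sizes) != n_genes)
    stop("block sizes must sum to n_genes")
  if (any(positive_block_ids < 1L | positive_block_ids > length(block_sizes)))
    stop("invalid positive block id")
  if (sum(block_sizes[positive_block_ids]) < n_positives)
    stop("positive blocks cannot hold all positives")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_positives = as.integer(n_positives), families = families,
                 p0 = p0, p1 = p1,
                 block_sizes = as.integer(block_sizes),
                 positive_block_ids = as.integer(positive_block_ids),
                 p_within = p_within, p_between = p_between,
                 score_within = as.integer(score_within),
                 score_between = as.integer(score_between)),
            class = "synthetic_config")
}

.syn_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a synthetic feature matrix with planted class signal
#'
#' Each non-signal feature is i.i.d. Bernoulli(`p0`) for every gene; each
#' signal feature is Bernoulli(`p1`) on positives and Bernoulli(`p0`) on
#' negatives.  Signal feature ids end in `"_sig"` and are also recorded in
#' the `signal_features` attribute of the returned matrix.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `matrix` (a `gene_feature_matrix`) and
#'   `labels` (a `label_set`).
#' @export
generate_feature_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 101L)
  genes <- .syn_gene_ids(config$n_genes)
  positives <- sort(sample(genes, config$n_positives))
  is_pos <- genes %in% positives

  fam <- config$families
  fids <- character(0); families <- character(0); is_sig <- logical(0)
  for (k in seq_len(nrow(fam))) {
    ids <- sprintf("%s_f%04d", fam$name[k], seq_len(fam$n_features[k]))
    sig <- seq_len(fam$n_features[k]) <= fam$n_signal[k]
    ids[sig] <- paste0(ids[sig], "_sig")
    fids <- c(fids, ids); is_sig <- c(is_sig, sig)
    families <- c(families, rep(fam$name[k], fam$n_features[k]))
  }
  n <- config$n_genes; p <- length(fids)
  probs <- matrix(config$p0, nrow = n, ncol = p)
  probs[is_pos, is_sig] <- config$p1
  vals <- matrix(rbinom(n * p, 1L, as.vector(probs)), nrow = n,
                 dimnames = list(genes, fids))
  m <- gene_feature_matrix(vals, setNames(families, fids))
  attr(m, "signal_features") <- fids[is_sig]
  list(matrix = m, labels = label_set(positives, genes))
}

.tri_pairs <- function(m) {
  # all unordered pairs (i < j) of 1..m as a 2-column matrix
  j <- rep.int(seq_len(m), seq_len(m) - 1L)
  i <- sequence(seq_len(m) - 1L)
  cbind(i, j)
}

#' Generate a stochastic-block-model PPI network
#'
#' Genes are assigned to blocks of the configured sizes; positives fill the
#' positive block(s) first (random order), negatives fill the rest.  Each
#' within-block pair is an edge with probability `p_within` and receives a
#' combined score drawn uniformly from `score_within`; between-block pairs
#' use `p_between` / `score_between`.
#'
#' @param config a [synthetic_config()].
#' @param labels a `label_set` over the same genome (from
#'   [generate_feature_matrix()]).
#' @return a [ppi_graph()] with a `blocks` attribute (named block id per
#'   gene).
#' @export
generate_ppi_network <- function(config, labels) {
  stopifnot(inherits(config, "synthetic_config"), inherits(labels, "label_set"))
  if (length(labels$universe) != config$n_genes)
    stop("labels universe does not match config n_genes")
  set.seed(config$seed + 202L)
  genes <- labels$universe
  pos <- sample(labels$positives)
  neg <- sample(labels$negatives)
  nb <- length(config$block_sizes)
  assignment <- character(config$n_genes)
  # positives fill the positive blocks (in id order), negatives pad the rest
  slots <- rep.int(seq_len(nb), config$block_sizes)
  block_members <- vector("list", nb)
  pi <- 1L; ni <- 1L
  for (b in seq_len(nb)) {
    size <- config$block_sizes[b]
    take_pos <- if (b %in% config$positive_block_ids)
      min(size, length(pos) - pi + 1L) else 0L
    members <- c(if (take_pos > 0L) pos[pi:(pi + take_pos - 1L)],
                 if (size - take_pos > 0L) neg[ni:(ni + size - take_pos - 1L)])
    pi <- pi + take_pos; ni <- ni + (size - take_pos)
    block_members[[b]] <- members
  }
  blocks <- setNames(rep.int(seq_len(nb), lengths(block_members)),
                     unlist(block_members))

  draw_scores <- function(k, range) {
    if (k == 0L) integer(0) else sample(range[1L]:range[2L], k, replace = TRUE)
  }
  ea <- character(0); eb <- character(0); sc <- integer(0)
  for (b in seq_len(nb)) {
    mem <- block_members[[b]]; m <- length(mem)
    if (m >= 2L) {
      pr <- .tri_pairs(m)
      keep <- runif(nrow(pr)) < config$p_within
      if (any(keep)) {
        ea <- c(ea, mem[pr[keep, 1L]]); eb <- c(eb, mem[pr[keep, 2L]])
        sc <- c(sc, draw_scores(sum(keep), config$score_within))
      }
    }
  }
  for (b1 in seq_len(nb - 1L)) for (b2 in (b1 + 1L):nb) {
    m1 <- block_members[[b1]]; m2 <- block_members[[b2]]
    keep <- runif(length(m1) * length(m2)) < config$p_between
    if (any(keep)) {
      idx <- which(keep) - 1L
      ea <- c(ea, m1[idx %% length(m1) + 1L])
      eb <- c(eb, m2[idx %/% length(m1) + 1L])
      sc <- c(sc, draw_scores(sum(keep), config$score_between))
    }
  }
  g <- ppi_graph(data.frame(a = ea, b = eb, score = sc), nodes = genes)
  attr(g, "blocks") <- blocks
  g
}

#' Generate block-derived annotation gene sets
#'
#' One gene set per network block.  With `noise = 0` the set equals the block
#' membership; with noise, each member is independently replaced (with
#' probability `noise`) by a random gene from outside the block, emulating
#' imperfect curated annotations for the over-representation stage.
#'
#' @param config a [synthetic_config()].
#' @param labels a `label_set`.
#' @param graph the network from [generate_ppi_network()] (its `blocks`
#'   attribute defines membership).
#' @param noise per-member replacement probability in `[0, 1)`.
#' @return a [gene_set_collection()] with sets named `block_1`, `block_2`, ...
#' @export
generate_annotation_sets <- function(config, labels, graph, noise = 0) {
  stopifnot(noise >= 0, noise < 1)
  blocks <- attr(graph, "blocks")
  if (is.null(blocks)) stop("graph lacks a blocks attribute")
  set.seed(config$seed + 303L)
  sets <- lapply(sort(unique(blocks)), function(b) {
    members <- names(blocks)[blocks == b]
    if (noise > 0) {
      swap <- runif(length(members)) < noise
      if (any(swap)) {
        pool <- setdiff(labels$universe, members)
        members[swap] <- sample(pool, sum(swap))
      }
    }
    unique(members)
  })
  names(sets) <- paste0("block_", sort(unique(blocks)))
  gene_set_collection(sets, rep("synthetic block annotation", length(sets)))
}
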
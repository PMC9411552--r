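# Shared fixtures and independent oracles, all built in code.

# tiny binary matrix with explicit values
tiny_matrix <- function(values, families = NULL) {
  if (is.null(families))
    families <- setNames(rep("FAM", ncol(values)), colnames(values))
  gene_feature_matrix(values, families)
}

# a small planted-signal world for classifier tests:
# n genes, half positive; `n_sig` features at p1 for positives / p0 else,
# `n_noise` background features at p0 for everyone.
toy_signal_data <- function(n = 60, n_sig = 6, n_noise = 10,
                            p1 = 0.9, p0 = 0.05, seed = 42) {
  set.seed(seed)
  genes <- sprintf("t%03d", seq_len(n))
  y <- rep(c(1L, 0L), each = n / 2)
  sig <- sapply(seq_len(n_sig), function(j) rbinom(n, 1, ifelse(y == 1, p1, p0)))
  noise <- matrix(rbinom(n * n_noise, 1, p0), nrow = n)
  vals <- cbind(sig, noise)
  dimnames(vals) <- list(genes, sprintf("f%02d", seq_len(n_sig + n_noise)))
  list(matrix = tiny_matrix(vals),
       training_set = data.frame(gene_id = genes, label = y),
       features = colnames(vals))
}

# a perfectly separable 2-feature fixture: feature f01 equals the label
separable_data <- function(n = 40) {
  genes <- sprintf("s%03d", seq_len(n))
  y <- rep(c(1L, 0L), each = n / 2)
  vals <- cbind(f01 = y, f02 = 1L - y)
  rownames(vals) <- genes
  list(matrix = tiny_matrix(vals),
       training_set = data.frame(gene_id = genes, label = y))
}

# small synthetic world reused by pipeline-level tests
small_config <- function(seed = 7, ...) {
  synthetic_config(
    seed = seed, n_genes = 400L, n_positives = 40L,
    families = data.frame(name = c("GTEx", "GO"),
                          n_features = c(60L, 40L),
                          n_signal = c(10L, 5L)),
    block_sizes = c(60L, 170L, 170L),
    p_within = 0.25, p_between = 0.01, ...)
}

# build a ppi_graph from a plain edge triple list
graph_from_triples <- function(...) {
  e <- do.call(rbind, lapply(list(...), function(tr)
    data.frame(a = tr[[1]], b = tr[[2]], score = as.integer(tr[[3]]))))
  ppi_graph(e)
}
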
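#' Build and validate a pipeline configuration
#'
#' Either supply `synthetic` (options for [synthetic_config()]) to run on
#' generated data, or `inputs` with paths `matrix`, `families`, `positives`
#' (one gene id per line), `ppi` and optionally `gene_sets` (GMT).  All
#' stage parameters have the pipeline defaults and valid-range checks.
#'
#' @param config named list or path to a YAML file.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = NULL, output_dir = "rmethpred_out",
    synthetic = list(), inputs = NULL,
    test_fraction = 0.2, min_score = 400L,
    filters = list(max_zero_fraction = 0.7, min_variance = 0.16),
    models = list(types = c("GB", "GNB", "LR", "RF", "SVM"), tune = FALSE),
    cv_folds = 10L, cv_sets = 3L,
    top_fraction = 0.01, top_k = 100L, holdout_top_k = 25L,
    min_consensus_models = 3L,
    pagerank = list(damping = 0.85, weighted = TRUE),
    gsea = list(n_perm = 10000L, weight_exponent = 1),
    louvain = list(resolution = 1.0))
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config must set an integer seed")
  stopifnot(cfg$test_fraction > 0, cfg$test_fraction < 1,
            cfg$filters$max_zero_fraction >= 0, cfg$filters$max_zero_fraction <= 1,
            cfg$filters$min_variance >= 0, cfg$filters$min_variance <= 0.25,
            cfg$top_fraction > 0, cfg$top_fraction <= 1,
            cfg$pagerank$damping > 0, cfg$pagerank$damping < 1,
            all(cfg$models$types %in% c("LR", "GNB", "SVM", "RF", "GB")))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg_plain <- unclass(cfg)
  writeLines(yaml::as.yaml(cfg_plain[order(names(cfg_plain))]), tmp)
  unname(tools::md5sum(tmp))
}

.artifact <- function(cfg, ...) file.path(cfg$output_dir, ...)

.write_manifest_entry <- function(cfg, stage, files) {
  path <- .artifact(cfg, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  manifest[[stage]] <- list(config_hash = .config_hash(cfg),
                            files = as.list(files))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

.require_stage <- function(cfg, stage) {
  path <- .artifact(cfg, "manifest.json")
  if (!file.exists(path))
    stop("stage '", stage, "' has not been run (no manifest in ",
         cfg$output_dir, ")")
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  entry <- manifest[[stage]]
  if (is.null(entry)) stop("stage '", stage, "' has not been run")
  if (!identical(entry$config_hash, unname(.config_hash(cfg))))
    stop("stale artifact: stage '", stage,
         "' was produced under a different config")
  invisible(entry)
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    m <- read_feature_matrix(cfg$inputs$matrix, cfg$inputs$families)
    positives <- readLines(cfg$inputs$positives)
    list(matrix = m,
         labels = label_set(positives[nzchar(positives)], gene_ids(m)),
         graph = read_ppi_edges(cfg$inputs$ppi, cfg$min_score),
         sets = if (!is.null(cfg$inputs$gene_sets))
           read_gmt(cfg$inputs$gene_sets) else NULL)
  } else {
    .require_stage(cfg, "simulate")
    m <- read_feature_matrix(.artifact(cfg, "matrix.tsv"),
                             .artifact(cfg, "families.tsv"))
    positives <- readLines(.artifact(cfg, "positives.txt"))
    list(matrix = m,
         labels = label_set(positives, gene_ids(m)),
         graph = read_ppi_edges(.artifact(cfg, "ppi.tsv"), cfg$min_score),
         sets = read_gmt(.artifact(cfg, "annotation_sets.gmt")))
  }
}

.stage_simulate <- function(cfg) {
  scfg <- do.call(synthetic_config,
                  modifyList(list(seed = cfg$seed), cfg$synthetic))
  fm <- generate_feature_matrix(scfg)
  graph <- generate_ppi_network(scfg, fm$labels)
  sets <- generate_annotation_sets(scfg, fm$labels, graph, noise = 0.05)
  write_feature_matrix(fm$matrix, .artifact(cfg, "matrix.tsv"),
                       .artifact(cfg, "families.tsv"))
  writeLines(fm$labels$positives, .artifact(cfg, "positives.txt"))
  write_ppi_edges(graph, .artifact(cfg, "ppi.tsv"))
  write_gmt(sets, .artifact(cfg, "annotation_sets.gmt"))
  writeLines(attr(fm$matrix, "signal_features"),
             .artifact(cfg, "signal_features.txt"))
  .write_manifest_entry(cfg, "simulate",
                        c("matrix.tsv", "families.tsv", "positives.txt",
                          "ppi.tsv", "annotation_sets.gmt",
                          "signal_features.txt"))
}

.stage_split <- function(cfg) {
  dat <- .load_inputs(cfg)
  split <- stratified_split(dat$labels, cfg$test_fraction, cfg$seed + 1L)
  design <- build_training_design(split, cfg$seed + 2L)
  message(sprintf("split: %d training sets of %d genes, %d leftover negatives",
                  length(design$training_sets),
                  2L * length(split$pos_train),
                  length(design$leftover_negatives)))
  utils::write.table(design_manifest(split, design),
                     .artifact(cfg, "split_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(list(split = split, design = design),
          .artifact(cfg, "split.rds"))
  .write_manifest_entry(cfg, "split", c("split_manifest.tsv", "split.rds"))
}

.stage_filter <- function(cfg) {
  .require_stage(cfg, "split")
  dat <- .load_inputs(cfg)
  sd_ <- readRDS(.artifact(cfg, "split.rds"))
  report <- select_features(dat$matrix, sd_$design,
                            cfg$filters$max_zero_fraction,
                            cfg$filters$min_variance)
  message(sprintf("filter: %d merged features kept", length(report$merged)))
  write_filter_report(report, dat$matrix, .artifact(cfg, "filter_report.tsv"))
  writeLines(report$merged, .artifact(cfg, "merged_features.txt"))
  .write_manifest_entry(cfg, "filter",
                        c("filter_report.tsv", "merged_features.txt"))
}

.stage_train <- function(cfg) {
  .require_stage(cfg, "filter")
  dat <- .load_inputs(cfg)
  sd_ <- readRDS(.artifact(cfg, "split.rds"))
  merged <- readLines(.artifact(cfg, "merged_features.txt"))
  records <- list(); cv <- list(); meta <- list()
  for (tp in cfg$models$types) {
    spec <- model_spec(tp, tune = isTRUE(cfg$models$tune), seed = cfg$seed + 3L)
    recs <- lapply(seq_along(sd_$design$training_sets), function(i)
      tune_and_train(spec, dat$matrix, sd_$design$training_sets[[i]],
                     merged, set_index = i))
    records[[tp]] <- recs
    n_cv <- min(cfg$cv_sets, length(recs))
    cv[[tp]] <- lapply(seq_len(n_cv), function(i)
      cross_validate(spec, dat$matrix, sd_$design$training_sets[[i]], merged,
                     k = cfg$cv_folds,
                     hyper = recs[[i]]$hyperparameters,
                     seed = cfg$seed + 4L))
    meta[[tp]] <- data.frame(
      model_type = tp,
      set_index = vapply(recs, `[[`, 1L, "set_index"),
      seed = vapply(recs, `[[`, 1L, "seed"),
      hyperparameters = vapply(recs, function(r)
        jsonlite::toJSON(r$hyperparameters, auto_unbox = TRUE), ""))
  }
  cv_table <- ensemble_cv_table(unlist(cv, recursive = FALSE))
  utils::write.table(cv_table, .artifact(cfg, "cv_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, meta), .artifact(cfg, "model_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(records, .artifact(cfg, "models.rds"))
  .write_manifest_entry(cfg, "train",
                        c("cv_table.tsv", "model_records.tsv", "models.rds"))
}

.stage_predict <- function(cfg) {
  .require_stage(cfg, "train")
  dat <- .load_inputs(cfg)
  records <- readRDS(.artifact(cfg, "models.rds"))
  top_sets <- list(); files <- character(0)
  for (tp in names(records)) {
    pred <- predict_genome(records[[tp]], dat$matrix, keep_per_model = FALSE)
    f <- paste0("predictions_", tp, ".tsv")
    write_predictions(pred, .artifact(cfg, f))
    top_sets[[tp]] <- top_fraction(pred, cfg$top_fraction)
    writeLines(top_sets[[tp]], .artifact(cfg, paste0("top_", tp, ".txt")))
    files <- c(files, f, paste0("top_", tp, ".txt"))
  }
  if (length(top_sets) >= cfg$min_consensus_models) {
    cons <- ensemble_overlap(top_sets, cfg$min_consensus_models)
    utils::write.table(
      data.frame(gene_id = names(cons$support),
                 support = unname(cons$support),
                 consensus = as.integer(names(cons$support) %in% cons$consensus)),
      .artifact(cfg, "consensus.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    files <- c(files, "consensus.tsv")
  }
  # novel candidates from the first (selected) model type
  sel <- names(records)[1L]
  pred_sel <- predict_genome(records[[sel]], dat$matrix, keep_per_model = FALSE)
  cand <- top_candidates(pred_sel, cfg$top_k, exclude = dat$labels$positives)
  utils::write.table(cand, .artifact(cfg, "top_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest_entry(cfg, "predict", c(files, "top_candidates.tsv"))
}

.stage_evaluate <- function(cfg) {
  .require_stage(cfg, "train")
  dat <- .load_inputs(cfg)
  sd_ <- readRDS(.artifact(cfg, "split.rds"))
  records <- readRDS(.artifact(cfg, "models.rds"))
  sel <- names(records)[1L]
  part <- partition_negatives(sd_$split$neg_test,
                              length(sd_$split$pos_test), cfg$seed + 5L)
  test_sets <- build_test_sets(sd_$split$pos_test, part$blocks)
  train_genes <- c(sd_$split$pos_train, sd_$split$neg_train)
  rep_ <- evaluate_on_test_sets(records[[sel]], dat$matrix, test_sets,
                                train_genes = train_genes)
  pooled <- pooled_holdout_rates(records[[sel]], dat$matrix,
                                 sd_$split$pos_test, sd_$split$neg_test)
  topk <- top_k_rates(pooled$scores, pooled$labels,
                      min(cfg$holdout_top_k, length(pooled$scores)))
  utils::write.table(rep_$pair_metrics, .artifact(cfg, "holdout_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(model_type = sel, averaged = as.list(rep_$averaged),
         pooled_fpr = pooled$fpr, pooled_auroc = pooled$metrics$auroc,
         top_k = cfg$holdout_top_k, top_k_fdr = topk$fdr,
         top_k_fpr = topk$fpr),
    .artifact(cfg, "holdout_summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  .write_manifest_entry(cfg, "evaluate",
                        c("holdout_pairs.tsv", "holdout_summary.json"))
}

.stage_ppi_validate <- function(cfg) {
  .require_stage(cfg, "predict")
  dat <- .load_inputs(cfg)
  sd_ <- readRDS(.artifact(cfg, "split.rds"))
  cand <- utils::read.delim(.artifact(cfg, "top_candidates.tsv"))
  val <- validate_predictions(dat$graph, dat$labels$positives, cand$gene_id,
                              damping = cfg$pagerank$damping,
                              weighted = isTRUE(cfg$pagerank$weighted),
                              n_perm = cfg$gsea$n_perm,
                              weight_exponent = cfg$gsea$weight_exponent,
                              seed = cfg$seed + 6L)
  utils::write.table(val$table, .artifact(cfg, "pagerank_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(es = val$gsea$es, nes = val$gsea$nes, p_value = val$gsea$p_value,
         n_perm = val$gsea$n_perm, set_size = val$gsea$set_size),
    .artifact(cfg, "gsea_summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  .write_manifest_entry(cfg, "ppi-validate",
                        c("pagerank_ranking.tsv", "gsea_summary.json"))
}

.stage_communities <- function(cfg) {
  .require_stage(cfg, "predict")
  dat <- .load_inputs(cfg)
  cand <- utils::read.delim(.artifact(cfg, "top_candidates.tsv"))
  sub <- subnetwork(dat$graph, dat$labels$positives, cand$gene_id)
  part <- louvain_communities(sub, resolution = cfg$louvain$resolution,
                              seed = cfg$seed + 7L)
  utils::write.table(
    data.frame(gene_id = names(part$membership),
               community = unname(part$membership)),
    .artifact(cfg, "communities.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  files <- "communities.tsv"
  if (!is.null(dat$sets)) {
    enr <- enrich_communities(part, dat$sets, dat$labels$universe)
    utils::write.table(enr, .artifact(cfg, "community_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "community_enrichment.tsv")
  }
  .write_manifest_entry(cfg, "communities", files)
}

.stages <- list(simulate = .stage_simulate, split = .stage_split,
                filter = .stage_filter, train = .stage_train,
                predict = .stage_predict, evaluate = .stage_evaluate,
                "ppi-validate" = .stage_ppi_validate,
                communities = .stage_communities)

#' Run one pipeline stage
#'
#' @param cfg a [pipeline_config()] (or list / YAML path coerced to one).
#' @param stage one of `simulate`, `split`, `filter`, `train`, `predict`,
#'   `evaluate`, `ppi-validate`, `communities`.
#' @return invisibly, the files the stage wrote (relative to the output
#'   directory).
#' @export
run_stage <- function(cfg, stage) {
  cfg <- pipeline_config(if (inherits(cfg, "pipeline_config")) unclass(cfg) else cfg)
  stage <- match.arg(stage, names(.stages))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  tryCatch(.stages[[stage]](cfg),
           error = function(e)
             stop("stage '", stage, "' failed: ", conditionMessage(e),
                  call. = FALSE))
}

#' Run the full analysis workflow
#'
#' Executes all stages in order (starting at `simulate` for synthetic
#' configs, `split` when real input paths are supplied) and returns the
#' manifest.  Identical config and seed reproduce byte-identical text
#' artifacts.
#'
#' @param cfg a [pipeline_config()], list, or YAML path.
#' @param stages subset of stages to run, in pipeline order.
#' @return the parsed manifest (invisibly).
#' @export
run_pipeline <- function(cfg, stages = NULL) {
  cfg <- pipeline_config(if (inherits(cfg, "pipeline_config")) unclass(cfg) else cfg)
  all_stages <- names(.stages)
  if (!is.null(cfg$inputs)) all_stages <- setdiff(all_stages, "simulate")
  if (is.null(stages)) stages <- all_stages
  for (st in stages) run_stage(cfg, st)
  invisible(jsonlite::read_json(.artifact(cfg, "manifest.json")))
}

#' Command-line entry point
#'
#' Usage: `rmethpred <stage|run> --config <config.yaml>`.  Intended for the
#' installed `exec/rmethpred` script; errors exit non-zero with the failing
#' stage named.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, NULL.
#' @export
rmethpred_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stop("usage: rmethpred <", paste(c(names(.stages), "run"), collapse = "|"),
         "> --config <config.yaml>")
  cmd <- args[1L]
  ci <- which(args == "--config")
  if (length(ci) != 1L || ci + 1L > length(args))
    stop("--config <path> is required")
  cfg <- pipeline_config(args[ci + 1L])
  if (cmd == "run") run_pipeline(cfg) else run_stage(cfg, cmd)
  invisible(NULL)
}
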
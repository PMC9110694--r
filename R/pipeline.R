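#' Validate a feature table and metadata pair
#'
#' Schema checks used before any analysis: required metadata columns,
#' table/metadata id cross-references, non-negative abundances, and GA
#' plausibility (0-45 weeks). Violations are reported, not thrown.
#'
#' @param table_path Feature table TSV (or an in-memory matrix).
#' @param meta_path Metadata CSV (or an in-memory data.frame).
#' @return data.frame of violations (kind, detail); zero rows when clean.
#' @export
validate_inputs <- function(table_path, meta_path) {
  table <- if (is.character(table_path)) read_feature_table(table_path)
           else table_path
  meta <- if (is.character(meta_path)) read_metadata(meta_path) else meta_path
  v <- list()
  bad <- function(kind, detail)
    v[[length(v) + 1L]] <<- data.frame(kind = kind, detail = detail,
                                       stringsAsFactors = FALSE)
  required <- c("injection_id", "sample_id", "type", "batch",
                "injection_order", "replicate_group")
  for (col in setdiff(required, names(meta)))
    bad("missing_column", col)
  if ("injection_id" %in% names(meta)) {
    orphan <- setdiff(colnames(table), meta$injection_id)
    for (id in orphan) bad("injection_not_in_metadata", id)
    unused <- setdiff(meta$injection_id, colnames(table))
    for (id in unused) bad("metadata_injection_not_in_table", id)
  }
  neg <- which(table < 0, arr.ind = TRUE)
  if (nrow(neg))
    for (k in seq_len(min(nrow(neg), 20L)))
      bad("negative_abundance",
          sprintf("feature %s, injection %s",
                  rownames(table)[neg[k, 1]], colnames(table)[neg[k, 2]]))
  if ("ga_weeks" %in% names(meta)) {
    ga <- meta$ga_weeks[!is.na(meta$ga_weeks)]
    if (any(ga <= 0 | ga >= 45))
      bad("implausible_ga", sprintf("%d value(s) outside (0, 45) weeks",
                                    sum(ga <= 0 | ga >= 45)))
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(kind = character(), detail = character())
}

#' Assemble a full run configuration
#'
#' Bundles the per-stage configurations with a global seed and output
#' directory. `config` may also be loaded from YAML with
#' [read_run_config()]; it round-trips losslessly through the file.
#'
#' @param sim A [sim_config()].
#' @param filter A [filter_config()].
#' @param loess A [loess_config()].
#' @param model A [model_config()].
#' @param network_threshold Bonferroni-adjusted P cutoff for network edges.
#' @param alpha Univariate screening threshold.
#' @param max_k Restricted-model maximum panel size.
#' @param seed Global seed; stage seeds are derived from it.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       filter = filter_config(),
                       loess = loess_config(),
                       model = model_config(),
                       network_threshold = 0.01,
                       alpha = 0.05,
                       max_k = 10L,
                       seed = 1L,
                       out_dir = tempfile("urigest_run_")) {
  structure(list(sim = sim, filter = filter, loess = loess, model = model,
                 network_threshold = network_threshold, alpha = alpha,
                 max_k = as.integer(max_k), seed = as.integer(seed),
                 out_dir = out_dir),
            class = c("run_config", "list"))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rd <- raw$sim$replicate_distribution
  if (!is.null(rd)) raw$sim$replicate_distribution <-
    stats::setNames(as.numeric(rd), as.character(1:4))
  cfg <- run_config(sim = do.call(sim_config, raw$sim %||% list()),
                    filter = do.call(filter_config, raw$filter %||% list()),
                    loess = do.call(loess_config, raw$loess %||% list()),
                    model = do.call(model_config, raw$model %||% list()),
                    network_threshold = raw$network_threshold %||% 0.01,
                    alpha = raw$alpha %||% 0.05,
                    max_k = raw$max_k %||% 10L,
                    seed = raw$seed %||% 1L,
                    out_dir = raw$out_dir %||% tempfile("urigest_run_"))
  cfg
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  out <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Run the complete simulated analysis end to end
#'
#' Simulates a discovery and validation cohort, preprocesses both
#' independently (each with its own LOESS/PQN statistics), fits the full
#' LOOCV model, selects the restricted model and applies it to the
#' validation cohort, fits stratified term/preterm models, runs the
#' univariate association screen, and builds the correlation network over
#' the union of selected panels. All artifacts are written under
#' `config$out_dir` along with a JSON manifest recording seeds, the config
#' hash and per-stage counts; two runs with the same config are
#' byte-identical.
#'
#' @param config A [run_config()] or path to its YAML file.
#' @param stratified Also fit per-outcome-group models.
#' @return The manifest list (invisibly written as manifest.json).
#' @export
run_ga_pipeline <- function(config = run_config(), stratified = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  # hash the config without the output location: runs that differ only in
  # out_dir are the same analysis
  hashable <- config
  hashable$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  write_run_config(hashable, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  manifest <- list(package = "urigest",
                   version = as.character(utils::packageVersion("urigest")),
                   seed = config$seed, config_hash = cfg_hash,
                   stages = list())
  stage <- function(name, info) manifest$stages[[name]] <<- info

  # --- simulate -------------------------------------------------------
  sim_cfg <- config$sim
  sim_cfg$seed <- config$seed
  cohort <- generate_cohort(sim_cfg)
  valid <- generate_validation_cohort(sim_cfg, cohort$truth)
  write_cohort(cohort, file.path(config$out_dir, "discovery"))
  write_cohort(valid, file.path(config$out_dir, "validation"))
  stage("simulate", list(n_discovery_injections = ncol(cohort$table),
                         n_validation_injections = ncol(valid$table),
                         n_features = nrow(cohort$table)))

  # --- preprocess (cohorts independently) -----------------------------
  prep <- run_preprocessing(cohort$table, cohort$meta, config$filter,
                            config$loess, impute_seed = config$seed)
  prep_v <- run_preprocessing(valid$table, valid$meta, config$filter,
                              config$loess, impute_seed = config$seed + 1L)
  write_feature_table(prep$table,
                      file.path(config$out_dir, "discovery_preprocessed.tsv"))
  stage("preprocess",
        list(discovery = lapply(prep$log, function(s)
          s[c("n_features", "n_injections", "n_removed")]),
          validation_features = nrow(prep_v$table)))

  X <- t(prep$table)
  y <- prep$meta$ga_weeks
  mcfg <- config$model
  mcfg$seed <- config$seed

  # --- full + restricted models ---------------------------------------
  full <- loocv_predict(X, y, mcfg)
  ranking <- rank_importance(X, y, mcfg, result = full)
  restr <- select_restricted_model(X, y, mcfg, max_k = config$max_k,
                                   ranking = ranking)
  kres <- restr$results[[restr$k]]
  utils::write.csv(data.frame(sample_id = prep$meta$sample_id,
                              y_true = full$y_true, y_pred = full$y_pred),
                   file.path(config$out_dir, "predictions_full.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(feature_id = names(full$importances),
                              importance = unname(full$importances)),
                   file.path(config$out_dir, "importance.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(k = seq_along(restr$cv_rmse_path),
                              rmse = restr$cv_rmse_path),
                   file.path(config$out_dir, "rmse_path.csv"),
                   row.names = FALSE)
  stage("predict", list(full = full[c("rho", "p_value", "rmse")],
                        restricted = c(list(k = restr$k,
                                            features = restr$selected_feature_ids),
                                       kres[c("rho", "p_value", "rmse")])))

  # --- validation ------------------------------------------------------
  common <- intersect(restr$selected_feature_ids, rownames(prep_v$table))
  val_metrics <- NULL
  if (length(common) == length(restr$selected_feature_ids)) {
    app <- apply_model(X, y, t(prep_v$table), restr$selected_feature_ids,
                       mcfg, y_new = prep_v$meta$ga_weeks)
    val_metrics <- app[c("rho", "p_value", "rmse")]
    utils::write.csv(data.frame(sample_id = prep_v$meta$sample_id,
                                y_true = prep_v$meta$ga_weeks,
                                y_pred = app$y_pred),
                     file.path(config$out_dir, "predictions_validation.csv"),
                     row.names = FALSE)
  }
  stage("validate", list(n = nrow(prep_v$meta),
                         n_panel_features_present = length(common),
                         metrics = val_metrics))

  # --- stratified ------------------------------------------------------
  strat_sets <- NULL
  if (stratified) {
    strat <- stratified_models(X, y, prep$meta$delivery_group, mcfg,
                               max_k = config$max_k)
    strat_sets <- lapply(strat, function(s) s$restricted$selected_feature_ids)
    stage("stratified", lapply(strat, function(s)
      c(s$prediction[c("rho", "p_value", "rmse")],
        list(k = s$restricted$k,
             features = s$restricted$selected_feature_ids))))
  }

  # --- association -----------------------------------------------------
  assoc <- spearman_screen(X, y, alpha = config$alpha)
  utils::write.csv(assoc, file.path(config$out_dir, "associations.csv"),
                   row.names = FALSE)
  stage("associate", list(n_significant = sum(assoc$significant),
                          n_tested = nrow(assoc)))

  # --- network over selected panels -----------------------------------
  sel <- unique(c(restr$selected_feature_ids, unlist(strat_sets)))
  if (length(sel) >= 2L) {
    labels <- NULL
    if (!is.null(strat_sets) && length(strat_sets) == 2L) {
      in1 <- sel %in% strat_sets[[1]]; in2 <- sel %in% strat_sets[[2]]
      labels <- stats::setNames(
        ifelse(in1 & in2, "both",
               ifelse(in1, paste0(names(strat_sets)[1], "-only"),
                      ifelse(in2, paste0(names(strat_sets)[2], "-only"),
                             "full-only"))), sel)
    }
    g <- build_network(X[, sel, drop = FALSE],
                       threshold = config$network_threshold, labels = labels)
    write_network(g, file.path(config$out_dir, "network"),
                  seed = config$seed)
    stage("network", list(n_nodes = igraph::vcount(g),
                          n_edges = igraph::ecount(g)))
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
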
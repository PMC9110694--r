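#' Random-forest model configuration
#'
#' Controls the regression forests used for gestational-age prediction.
#' When `tune = TRUE`, hyperparameters (fraction of features tried per
#' split, minimum leaf size) are optimized by internal k-fold
#' cross-validation inside every training set, minimizing RMSE; the
#' held-out sample of the outer leave-one-out loop never enters tuning.
#'
#' @param n_trees Trees per forest (>= 100 recommended for stable
#'   importances; smaller values are useful for quick runs).
#' @param mtry_fractions Candidate fractions of features tried at each
#'   split.
#' @param min_node_sizes Candidate minimum leaf sizes.
#' @param internal_cv_folds Folds of the internal tuning CV.
#' @param tune Tune per training set (TRUE) or use fixed defaults
#'   (mtry = p/3, min.node.size = 5) when FALSE.
#' @param importance "impurity" (default) or "permutation".
#' @param seed Integer seed controlling all forest randomness.
#' @return A `model_config` list.
#' @export
model_config <- function(n_trees = 500L,
                         mtry_fractions = c(0.1, 0.33, 0.5),
                         min_node_sizes = c(1L, 3L, 5L),
                         internal_cv_folds = 5L,
                         tune = TRUE,
                         importance = c("impurity", "permutation"),
                         seed = 1L) {
  importance <- match.arg(importance)
  cfg <- list(n_trees = as.integer(n_trees),
              mtry_fractions = mtry_fractions,
              min_node_sizes = as.integer(min_node_sizes),
              internal_cv_folds = as.integer(internal_cv_folds),
              tune = isTRUE(tune),
              importance = importance,
              seed = as.integer(seed))
  if (cfg$n_trees < 1L) stop("model_config: n_trees must be positive")
  if (cfg$internal_cv_folds < 2L) stop("model_config: folds >= 2 required")
  class(cfg) <- c("model_config", "list")
  cfg
}

fit_forest <- function(X, y, cfg, mtry_fraction = NULL, min_node_size = NULL,
                       seed_offset = 0L) {
  p <- ncol(X)
  mtry <- if (is.null(mtry_fraction)) max(1L, floor(p / 3)) else
    max(1L, floor(mtry_fraction * p))
  mns <- if (is.null(min_node_size)) 5L else as.integer(min_node_size)
  ranger::ranger(x = X, y = y,
                 num.trees = cfg$n_trees,
                 mtry = min(mtry, p),
                 min.node.size = mns,
                 importance = cfg$importance,
                 seed = (cfg$seed + seed_offset) %% .Machine$integer.max,
                 num.threads = 1L)
}

# internal CV over the hyperparameter grid; returns the winning pair
tune_forest <- function(X, y, cfg, seed_offset = 0L) {
  n <- nrow(X)
  set.seed((cfg$seed + seed_offset) %% .Machine$integer.max)
  folds <- sample(rep_len(seq_len(cfg$internal_cv_folds), n))
  grid <- expand.grid(mtry_fraction = cfg$mtry_fractions,
                      min_node_size = cfg$min_node_sizes)
  rmse <- vapply(seq_len(nrow(grid)), function(g) {
    err <- 0
    for (k in seq_len(cfg$internal_cv_folds)) {
      tr <- folds != k
      if (sum(tr) < 2 || sum(!tr) < 1) next
      fit <- fit_forest(X[tr, , drop = FALSE], y[tr], cfg,
                        grid$mtry_fraction[g], grid$min_node_size[g],
                        seed_offset = seed_offset + k)
      pred <- stats::predict(fit, data = X[!tr, , drop = FALSE])$predictions
      err <- err + sum((pred - y[!tr])^2)
    }
    sqrt(err / n)
  }, numeric(1))
  best <- which.min(rmse)
  list(mtry_fraction = grid$mtry_fraction[best],
       min_node_size = grid$min_node_size[best])
}

#' Prediction metrics: Spearman rho, its P-value, and RMSE
#'
#' Spearman's rank correlation uses tie-corrected ranks with the asymptotic
#' two-sided P-value; RMSE is in the units of the response (weeks). A
#' constant prediction vector has undefined rank correlation and is reported
#' as rho = 0 with P = 1.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 3).
#' @return List with `rho`, `p_value`, `rmse`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred have different lengths")
  if (length(y_true) < 3L) stop("need at least 3 observations")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  if (stats::sd(y_pred) == 0 || stats::sd(y_true) == 0)
    return(list(rho = 0, p_value = 1, rmse = rmse))
  ct <- suppressWarnings(
    stats::cor.test(y_true, y_pred, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, rmse = rmse)
}

#' Leave-one-out cross-validated random-forest prediction
#'
#' For each sample i, a forest is trained on all other samples (tuned by
#' internal CV when `cfg$tune`) and predicts sample i; metrics are computed
#' on the aggregated vector of blinded out-of-fold predictions. No statistic
#' is ever computed on the held-out sample.
#'
#' @param X Sample x feature numeric matrix (no missing values), rownames =
#'   sample ids, colnames = feature ids.
#' @param y Gestational age at collection (weeks), one per row of X.
#' @param cfg A [model_config()].
#' @return A `ga_prediction` list: `sample_ids`, `y_true`, `y_pred`, `rho`,
#'   `p_value`, `rmse`, `importances` (per-feature mean over fold models).
#' @export
loocv_predict <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; impute before modelling")
  n <- nrow(X)
  if (n < 10L) stop("leave-one-out CV needs at least 10 samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("constant response: nothing to predict")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  y_pred <- numeric(n)
  imp <- matrix(0, nrow = n, ncol = ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    hp <- if (cfg$tune) tune_forest(Xtr, ytr, cfg, seed_offset = i) else
      list(mtry_fraction = NULL, min_node_size = NULL)
    fit <- fit_forest(Xtr, ytr, cfg, hp$mtry_fraction, hp$min_node_size,
                      seed_offset = i)
    y_pred[i] <- stats::predict(fit, data = X[i, , drop = FALSE])$predictions
    imp[i, ] <- fit$variable.importance[colnames(X)]
  }
  m <- evaluate_predictions(y, y_pred)
  structure(list(sample_ids = rownames(X), y_true = y, y_pred = y_pred,
                 rho = m$rho, p_value = m$p_value, rmse = m$rmse,
                 importances = colMeans(imp)),
            class = "ga_prediction")
}

#' @export
print.ga_prediction <- function(x, ...) {
  cat(sprintf("LOOCV GA prediction: n = %d, rho = %.3f (P = %.2e), RMSE = %.2f weeks\n",
              length(x$y_true), x$rho, x$p_value, x$rmse))
  invisible(x)
}

#' Rank features by model importance
#'
#' Importance is averaged over the leave-one-out fold models and sorted in
#' descending order; ties are broken alphabetically by feature id so the
#' ranking is deterministic.
#'
#' @inheritParams loocv_predict
#' @param result Optional precomputed [loocv_predict()] result to reuse.
#' @return Character vector of feature ids, most important first.
#' @export
rank_importance <- function(X, y, cfg = model_config(), result = NULL) {
  if (is.null(result)) result <- loocv_predict(X, y, cfg)
  imp <- result$importances
  ids <- names(imp)
  ids[order(-imp, ids)]
}

#' Select a parsimonious restricted model
#'
#' Forward selection in importance order: for every candidate size k the
#' leave-one-out RMSE of a forest using only the top-k features is computed,
#' and the chosen k is the smallest whose RMSE is within one standard error
#' of the minimum (the 1-SE rule, with the SE of the minimum-k mean squared
#' error propagated to the RMSE scale).
#'
#' @inheritParams loocv_predict
#' @param max_k Largest candidate panel size.
#' @param ranking Optional precomputed importance ranking.
#' @return A `restricted_model` list: `selected_feature_ids`, `k`,
#'   `cv_rmse_path`, `tolerance_rule`, and the per-k `results`.
#' @export
select_restricted_model <- function(X, y, cfg = model_config(), max_k = 10L,
                                    ranking = NULL) {
  X <- as.matrix(X)
  if (max_k > ncol(X)) {
    warning("max_k exceeds the number of features; clamped to ", ncol(X))
    max_k <- ncol(X)
  }
  if (is.null(ranking)) ranking <- rank_importance(X, y, cfg)
  path <- numeric(max_k)
  results <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    res <- loocv_predict(X[, ranking[seq_len(k)], drop = FALSE], y, cfg)
    path[k] <- res$rmse
    results[[k]] <- res
  }
  kmin <- which.min(path)
  sq_err <- (results[[kmin]]$y_true - results[[kmin]]$y_pred)^2
  se_mse <- stats::sd(sq_err) / sqrt(length(sq_err))
  threshold <- sqrt(path[kmin]^2 + se_mse)
  k <- which(path <= threshold)[1]
  structure(list(selected_feature_ids = ranking[seq_len(k)], k = k,
                 cv_rmse_path = path,
                 tolerance_rule = "smallest k with RMSE <= sqrt(min MSE + 1 SE of min MSE)",
                 results = results),
            class = "restricted_model")
}

#' Apply a trained model to a new cohort
#'
#' A single forest is trained on the full discovery set restricted to
#' `feature_subset` and applied to a new (independently preprocessed)
#' cohort; metrics are returned when labels are supplied. The new cohort
#' must have been normalized with its own PQN/LOESS statistics — no
#' cross-cohort leakage.
#'
#' @param X_train,y_train Discovery matrix and GA labels.
#' @param X_new New-cohort matrix (samples x features).
#' @param feature_subset Feature ids used by the model.
#' @param cfg A [model_config()].
#' @param y_new Optional GA labels for the new cohort.
#' @return List with `y_pred` and, if labels were given, `rho`, `p_value`,
#'   `rmse`.
#' @export
apply_model <- function(X_train, y_train, X_new, feature_subset,
                        cfg = model_config(), y_new = NULL) {
  miss <- setdiff(feature_subset, colnames(X_new))
  if (length(miss))
    stop("feature(s) absent from the new cohort: ",
         paste(miss, collapse = ", "))
  miss_tr <- setdiff(feature_subset, colnames(X_train))
  if (length(miss_tr))
    stop("feature(s) absent from the training cohort: ",
         paste(miss_tr, collapse = ", "))
  Xtr <- as.matrix(X_train)[, feature_subset, drop = FALSE]
  Xnw <- as.matrix(X_new)[, feature_subset, drop = FALSE]
  hp <- if (cfg$tune) tune_forest(Xtr, y_train, cfg) else
    list(mtry_fraction = NULL, min_node_size = NULL)
  fit <- fit_forest(Xtr, y_train, cfg, hp$mtry_fraction, hp$min_node_size)
  y_pred <- stats::predict(fit, data = Xnw)$predictions
  out <- list(y_pred = y_pred)
  if (!is.null(y_new)) out <- c(out, evaluate_predictions(y_new, y_pred))
  out
}

#' Fit independent models within outcome strata
#'
#' Runs [loocv_predict()] and (optionally) [select_restricted_model()]
#' separately within each delivery-outcome group (term / preterm), returning
#' per-group results and selected feature sets for overlap analysis.
#'
#' @inheritParams loocv_predict
#' @param groups Character/factor vector of group labels per sample.
#' @param max_k Candidate panel sizes for the per-group restricted models.
#' @param restricted Run restricted-model selection per group.
#' @return Named list per group: `prediction` (a `ga_prediction`) and
#'   `restricted` (a `restricted_model` or NULL).
#' @export
stratified_models <- function(X, y, groups, cfg = model_config(),
                              max_k = 10L, restricted = TRUE) {
  X <- as.matrix(X)
  stopifnot(length(groups) == nrow(X))
  out <- list()
  for (g in unique(as.character(groups))) {
    idx <- which(groups == g)
    if (length(idx) < 10L)
      stop("group '", g, "' has fewer than 10 samples")
    Xg <- X[idx, , drop = FALSE]
    yg <- y[idx]
    pred <- loocv_predict(Xg, yg, cfg)
    restr <- if (restricted)
      select_restricted_model(Xg, yg, cfg, max_k = max_k,
                              ranking = rank_importance(Xg, yg, cfg,
                                                        result = pred))
    out[[g]] <- list(prediction = pred, restricted = restr)
  }
  out
}
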
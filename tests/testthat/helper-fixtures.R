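# Shared fixtures: all built in code, deterministic.

# small simulated cohort for fast unit tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_subjects = 30, n_validation = 8, n_features = 120,
             n_informative = 10, n_batches = 2, n_contaminants = 5,
             qc_every = 6, seed = seed, ...)
}

# quick model config for unit tests (not for performance claims)
quick_model_config <- function(seed = 1, n_trees = 50) {
  model_config(n_trees = n_trees, tune = FALSE, seed = seed)
}

# cache of preprocessed default cohorts, keyed by seed: several acceptance
# checks share the same study conditions
.prep_cache <- new.env(parent = emptyenv())
default_prepped <- function(seed) {
  key <- as.character(seed)
  if (is.null(.prep_cache[[key]])) {
    co <- generate_cohort(sim_config(seed = seed))
    prep <- run_preprocessing(co$table, co$meta, impute_seed = seed)
    .prep_cache[[key]] <- list(cohort = co, prep = prep,
                               X = t(prep$table), y = prep$meta$ga_weeks,
                               groups = prep$meta$delivery_group)
  }
  .prep_cache[[key]]
}

# Hand-built preprocessing fixture with known bad features:
#   10 contaminants (blank signal = QC signal)
#   15 low-presence features (one at exactly 66/99 present)
#   8 dilution-nonlinear features (constant across the dilution series)
#   27 clean survivors (one at exactly 67/99 present)
# 99 single-replicate study samples, 6 QC pools, 5 dilution levels, 2 blanks.
make_filter_fixture <- function() {
  n_feat <- 60
  feat_ids <- sprintf("F%02d", seq_len(n_feat))
  contaminants <- feat_ids[1:10]
  low_presence <- feat_ids[11:25]
  nonlinear <- feat_ids[26:33]
  clean <- feat_ids[34:60]
  boundary_removed <- low_presence[1]   # present in exactly 66/99
  boundary_kept <- clean[1]             # present in exactly 67/99

  study_ids <- sprintf("ST%02d", 1:99)
  qc_ids <- sprintf("QC%d", 1:6)
  dil_ids <- sprintf("DL%d", 1:5)
  blank_ids <- c("BK1", "BK2")
  inj <- c(dil_ids, qc_ids[1], study_ids[1:50], qc_ids[2:3], study_ids[51:99],
           qc_ids[4:6], blank_ids)
  tab <- matrix(100, nrow = n_feat, ncol = length(inj),
                dimnames = list(feat_ids, inj))
  dil_levels <- seq(0.2, 1, length.out = 5)
  tab[, dil_ids] <- matrix(rep(100 * dil_levels, each = n_feat), nrow = n_feat)
  tab[, blank_ids] <- 0.1
  tab[contaminants, blank_ids] <- 100          # fails the blank filter
  tab[nonlinear, dil_ids] <- 50                # zero-variance series
  for (f in low_presence) {
    n_present <- if (f == boundary_removed) 66 else 40
    tab[f, study_ids[seq_len(99 - n_present)]] <- NA
  }
  tab[boundary_kept, study_ids[1:32]] <- NA    # 67/99 present, kept
  meta <- data.frame(
    injection_id = inj,
    sample_id = c(dil_ids, qc_ids[1], study_ids[1:50], qc_ids[2:3],
                  study_ids[51:99], qc_ids[4:6], blank_ids),
    subject_id = NA_character_,
    type = c(rep("qc_dilution", 5), "qc_pool", rep("study", 50),
             rep("qc_pool", 2), rep("study", 49), rep("qc_pool", 3),
             rep("blank", 2)),
    batch = 1L,
    injection_order = seq_along(inj),
    dilution_level = c(dil_levels, rep(NA, length(inj) - 5)),
    stringsAsFactors = FALSE)
  meta$replicate_group <- ifelse(meta$type == "study", meta$sample_id, NA)
  list(table = tab, meta = meta,
       contaminants = contaminants, low_presence = low_presence,
       nonlinear = nonlinear, clean = clean,
       boundary_removed = boundary_removed, boundary_kept = boundary_kept)
}

# brute-force oracles ------------------------------------------------------

oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

oracle_spearman_p <- function(x, y) {
  # asymptotic two-sided t approximation on tie-corrected ranks
  r <- oracle_spearman(x, y)
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}

oracle_rmse <- function(a, b) sqrt(sum((a - b)^2) / length(a))

# hypergeometric enrichment tail P(X >= hits) by direct summation
oracle_hyper_tail <- function(hits, pathway, n_sig, background) {
  ks <- hits:min(pathway, n_sig)
  sum(choose(pathway, ks) * choose(background - pathway, n_sig - ks)) /
    choose(background, n_sig)
}

# exhaustive shortest-path betweenness on a small igraph (unweighted)
oracle_betweenness <- function(g) {
  ids <- igraph::V(g)$name
  btw <- stats::setNames(numeric(length(ids)), ids)
  n <- length(ids)
  d <- igraph::distances(g, weights = NA)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(d[s, t])) next
    paths <- igraph::all_shortest_paths(g, from = ids[s], to = ids[t],
                                        weights = NA)$res
    counts <- stats::setNames(numeric(length(ids)), ids)
    for (p in paths) {
      inner <- setdiff(names(p), c(ids[s], ids[t]))
      counts[inner] <- counts[inner] + 1
    }
    btw <- btw + counts / length(paths)
  }
  btw
}

# forward dot product recomputed from its definition with a fixed pairing
oracle_dot_product <- function(wq, wr, pairs) {
  num <- sum(wq[pairs[, 1]] * wr[pairs[, 2]])
  num^2 / (sum(wq^2) * sum(wr^2))
}
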
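#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set that drives [generate_cohort()] and
#' [generate_validation_cohort()]. Defaults emulate a multi-site early
#' pregnancy urine metabolomics study: 99 discovery subjects sampled
#' uniformly between 8 and 19 weeks of gestation, 2000 metabolic features of
#' which a minority track gestational age (GA) monotonically in log space
#' (55% with positive slope), four acquisition batches with smooth
#' injection-order signal drift, a pooled QC injection every 10 study
#' injections, a QC dilution series, blank injections, 1-4 technical
#' replicates per sample, strong per-sample urine dilution, and left-censored
#' missingness concentrated at low abundance.
#'
#' @param n_subjects Number of discovery-cohort subjects (one urine sample
#'   each).
#' @param n_validation Number of validation-cohort subjects, all term.
#' @param n_features Number of metabolic features (split between HILIC and
#'   RPLC modes).
#' @param n_informative Number of features whose log abundance depends
#'   linearly on GA.
#' @param frac_positive_slope Fraction of informative features with a
#'   positive GA slope; the count is `round(frac_positive_slope *
#'   n_informative)`.
#' @param n_batches Number of acquisition batches.
#' @param qc_every A pooled QC sample is injected after every `qc_every`
#'   study injections within each batch (plus one leading QC per batch).
#' @param replicate_distribution Probability vector over 1-4 technical
#'   replicates per sample.
#' @param ga_range_weeks Length-2 interval for GA at collection (weeks).
#' @param drift_amplitude Relative amplitude of the smooth per-batch
#'   injection-order drift (log scale); 0 disables drift.
#' @param dilution_log_sd SD of the per-sample natural-log dilution factor
#'   (urine concentration varies strongly with hydration).
#' @param noise_log_sd SD of per-injection technical noise (log scale).
#' @param biological_log_sd SD of the per-subject, per-feature biological
#'   effect (log scale).
#' @param missing_quantile Abundance quantile of the pre-censoring value
#'   distribution below which entries are set to missing (left-censoring).
#' @param slope_range Range of absolute informative slopes, log-abundance
#'   units per week.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of feature
#'   baseline abundance (spectral counts).
#' @param n_contaminants Number of non-informative features whose blank
#'   signal matches study levels (targets of the blank filter).
#' @param blank_epsilon Blank signal of non-contaminant features relative to
#'   baseline.
#' @param n_blanks_per_batch Blank injections appended to each batch.
#' @param n_dilution_levels Number of levels in the QC dilution series
#'   (injected at the head of batch 1); relative concentrations span
#'   `dilution_series_range`-fold.
#' @param dilution_series_range Fold range of the QC dilution series.
#' @param frac_preterm Fraction of discovery subjects who go on to deliver
#'   preterm (< 37 weeks).
#' @param preterm_sd_multiplier Inflation of the subject-effect SD for
#'   informative features in preterm subjects sampled between weeks 14 and
#'   17, emulating their higher inter-individual variability. Set to 1 to
#'   disable.
#' @param block_sizes Optional integer vector of planted correlated-block
#'   sizes: each block receives a shared per-subject latent factor (beyond
#'   GA), emulating co-regulated metabolite families such as steroid
#'   conjugates or amino acids. Default: none.
#' @param block_log_sd SD of the per-subject block latent factor (log
#'   scale).
#' @param n_sites Number of collection sites.
#' @param site_log_sd SD of the small multiplicative site offset (log
#'   scale).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_subjects = 99,
                       n_validation = 20,
                       n_features = 2000,
                       n_informative = 30,
                       frac_positive_slope = 0.55,
                       n_batches = 4,
                       qc_every = 10,
                       replicate_distribution = c(`1` = 0.45, `2` = 0.40,
                                                  `3` = 0.10, `4` = 0.05),
                       ga_range_weeks = c(8, 19),
                       drift_amplitude = 0.2,
                       dilution_log_sd = 0.5,
                       noise_log_sd = 0.15,
                       biological_log_sd = 0.55,
                       missing_quantile = 0.05,
                       slope_range = c(0.08, 0.18),
                       baseline_log_mean = log(500),
                       baseline_log_sd = 1.2,
                       n_contaminants = 10,
                       blank_epsilon = 0.01,
                       n_blanks_per_batch = 2,
                       n_dilution_levels = 5,
                       dilution_series_range = 5,
                       frac_preterm = 0.5,
                       preterm_sd_multiplier = 2,
                       block_sizes = integer(0),
                       block_log_sd = 0.8,
                       n_sites = 5,
                       site_log_sd = 0.05,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_validation = as.integer(n_validation),
              n_features = as.integer(n_features),
              n_informative = as.integer(n_informative),
              frac_positive_slope = frac_positive_slope,
              n_batches = as.integer(n_batches),
              qc_every = as.integer(qc_every),
              replicate_distribution = replicate_distribution,
              ga_range_weeks = as.numeric(ga_range_weeks),
              drift_amplitude = drift_amplitude,
              dilution_log_sd = dilution_log_sd,
              noise_log_sd = noise_log_sd,
              biological_log_sd = biological_log_sd,
              missing_quantile = missing_quantile,
              slope_range = as.numeric(slope_range),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              n_contaminants = as.integer(n_contaminants),
              blank_epsilon = blank_epsilon,
              n_blanks_per_batch = as.integer(n_blanks_per_batch),
              n_dilution_levels = as.integer(n_dilution_levels),
              dilution_series_range = dilution_series_range,
              frac_preterm = frac_preterm,
              preterm_sd_multiplier = preterm_sd_multiplier,
              block_sizes = as.integer(block_sizes),
              block_log_sd = block_log_sd,
              n_sites = as.integer(n_sites),
              site_log_sd = site_log_sd,
              seed = as.integer(seed))
  counts <- c("n_subjects", "n_validation", "n_features", "n_batches",
              "qc_every", "n_dilution_levels", "n_sites")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("sim_config: '", nm, "' must be a positive count")
  }
  if (cfg$n_informative < 0L || cfg$n_informative > cfg$n_features)
    stop("sim_config: n_informative must be in [0, n_features]")
  if (cfg$frac_positive_slope < 0 || cfg$frac_positive_slope > 1)
    stop("sim_config: frac_positive_slope must be in [0, 1]")
  if (length(cfg$ga_range_weeks) != 2L ||
      cfg$ga_range_weeks[1] >= cfg$ga_range_weeks[2] ||
      cfg$ga_range_weeks[1] <= 0 || cfg$ga_range_weeks[2] >= 45)
    stop("sim_config: ga_range_weeks must be an increasing interval inside (0, 45)")
  if (abs(sum(cfg$replicate_distribution) - 1) > 1e-8 ||
      any(cfg$replicate_distribution < 0) ||
      length(cfg$replicate_distribution) != 4L)
    stop("sim_config: replicate_distribution must be a probability vector over 1-4 replicates")
  if (cfg$n_contaminants > cfg$n_features - cfg$n_informative)
    stop("sim_config: too many contaminant features")
  if (cfg$n_dilution_levels < 3L)
    stop("sim_config: the QC dilution series needs at least 3 levels")
  if (sum(cfg$block_sizes) > cfg$n_features - cfg$n_informative)
    stop("sim_config: planted blocks exceed the non-informative features")
  if (cfg$missing_quantile < 0 || cfg$missing_quantile >= 1)
    stop("sim_config: missing_quantile must be in [0, 1)")
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Feature parameter table shared between discovery and validation: ids, mode,
# baselines, GA slopes, contaminant flags. Part of the ground truth.
simulate_feature_params <- function(cfg) {
  ids <- sprintf("%s_%04d",
                 rep(c("HILIC", "RPLC"), length.out = cfg$n_features),
                 seq_len(cfg$n_features))
  baseline_log <- stats::rnorm(cfg$n_features, cfg$baseline_log_mean,
                               cfg$baseline_log_sd)
  slope <- numeric(cfg$n_features)
  informative <- sort(sample.int(cfg$n_features, cfg$n_informative))
  n_pos <- floor(cfg$frac_positive_slope * cfg$n_informative + 0.5)  # half-up
  signs <- c(rep(1, n_pos), rep(-1, cfg$n_informative - n_pos))
  mag <- stats::runif(cfg$n_informative, cfg$slope_range[1], cfg$slope_range[2])
  slope[informative] <- signs * mag
  # informative features get a high-ish baseline so the signal survives
  # left-censoring; real GA markers (steroid conjugates) are abundant in urine
  baseline_log[informative] <- pmax(baseline_log[informative],
                                    cfg$baseline_log_mean)
  contaminant <- rep(FALSE, cfg$n_features)
  pool <- setdiff(seq_len(cfg$n_features), informative)
  if (cfg$n_contaminants > 0L)
    contaminant[sample(pool, cfg$n_contaminants)] <- TRUE
  block <- rep(0L, cfg$n_features)
  if (length(cfg$block_sizes)) {
    free <- setdiff(pool, which(contaminant))
    members <- sample(free, sum(cfg$block_sizes))
    block[members] <- rep(seq_along(cfg$block_sizes), cfg$block_sizes)
  }
  data.frame(feature_id = ids,
             mode = sub("_.*", "", ids),
             baseline_log = baseline_log,
             slope = slope,
             informative = seq_len(cfg$n_features) %in% informative,
             contaminant = contaminant,
             block = block,
             stringsAsFactors = FALSE)
}

# Injection sequence for one cohort: study replicates split over batches,
# a leading QC plus one QC after every qc_every study injections, blanks at
# the batch tail, and a QC dilution series at the head of batch 1.
build_injection_plan <- function(subjects, cfg) {
  reps <- subjects$n_replicates
  inj <- data.frame(
    sample_id = rep(subjects$sample_id, reps),
    subject_id = rep(subjects$subject_id, reps),
    type = "study",
    stringsAsFactors = FALSE)
  inj <- inj[sample.int(nrow(inj)), , drop = FALSE]  # randomized run order
  batch_of <- sort(rep_len(seq_len(cfg$n_batches), nrow(inj)))
  plan <- list()
  for (b in seq_len(cfg$n_batches)) {
    rows <- inj[batch_of == b, , drop = FALSE]
    seqs <- list()
    if (b == 1L && cfg$n_dilution_levels > 0L) {
      lv <- seq_len(cfg$n_dilution_levels)
      rel <- seq(1 / cfg$dilution_series_range, 1,
                 length.out = cfg$n_dilution_levels)
      seqs[[length(seqs) + 1L]] <- data.frame(
        sample_id = sprintf("QCDIL_L%d", lv), subject_id = NA_character_,
        type = "qc_dilution", dilution_level = rel,
        stringsAsFactors = FALSE)
    }
    qc_row <- function() data.frame(sample_id = "QC_POOL",
                                    subject_id = NA_character_,
                                    type = "qc_pool",
                                    dilution_level = NA_real_,
                                    stringsAsFactors = FALSE)
    seqs[[length(seqs) + 1L]] <- qc_row()
    if (nrow(rows) > 0) {
      rows$dilution_level <- NA_real_
      chunks <- split(seq_len(nrow(rows)),
                      ceiling(seq_len(nrow(rows)) / cfg$qc_every))
      for (ch in chunks) {
        seqs[[length(seqs) + 1L]] <- rows[ch, , drop = FALSE]
        seqs[[length(seqs) + 1L]] <- qc_row()
      }
    }
    if (cfg$n_blanks_per_batch > 0L)
      seqs[[length(seqs) + 1L]] <- data.frame(
        sample_id = sprintf("BLANK_B%d_%d", b, seq_len(cfg$n_blanks_per_batch)),
        subject_id = NA_character_, type = "blank",
        dilution_level = NA_real_, stringsAsFactors = FALSE)
    bdf <- do.call(rbind, seqs)
    bdf$batch <- b
    bdf$injection_order <- seq_len(nrow(bdf))
    plan[[b]] <- bdf
  }
  plan <- do.call(rbind, plan)
  plan$injection_id <- sprintf("INJ_%03d_%03d", plan$batch,
                               plan$injection_order)
  rownames(plan) <- NULL
  plan
}

# Smooth per-batch drift shapes on [0, 1]: a random linear trend plus one
# cosine harmonic, standardized to roughly unit range.
make_drift_shapes <- function(n_batches) {
  lapply(seq_len(n_batches), function(b) {
    a_lin <- stats::runif(1, -1, 1)
    a_cos <- stats::runif(1, 0.3, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    freq <- stats::runif(1, 0.5, 1.5)
    list(a_lin = a_lin, a_cos = a_cos, phase = phase, freq = freq)
  })
}

eval_drift_shape <- function(shape, t) {
  shape$a_lin * (2 * t - 1) + shape$a_cos * cos(pi * shape$freq * t + shape$phase)
}

# Core generative model, shared by discovery and validation cohorts.
# Returns the feature table (features x injections, NA = censored), the
# injection metadata, and the realized nuisance parameters.
simulate_from_params <- function(features, subjects, cfg) {
  ga_mid <- mean(cfg$ga_range_weeks)
  nf <- nrow(features)

  plan <- build_injection_plan(subjects, cfg)
  n_inj <- nrow(plan)

  # per-subject biological effect per feature; preterm subjects sampled in
  # weeks 14-17 get an inflated SD on informative features
  subj_eff <- matrix(stats::rnorm(nf * nrow(subjects), 0, cfg$biological_log_sd),
                     nrow = nf)
  colnames(subj_eff) <- subjects$subject_id
  if (cfg$preterm_sd_multiplier != 1) {
    inflate <- subjects$delivery_group == "preterm" &
      subjects$ga_weeks >= 14 & subjects$ga_weeks <= 17
    if (any(inflate))
      subj_eff[features$informative, inflate] <-
        subj_eff[features$informative, inflate] * cfg$preterm_sd_multiplier
  }

  # feature-specific site offsets (handling/storage effects); a uniform
  # per-site shift would be pure dilution and is left to dilution_factors
  site_eff <- matrix(stats::rnorm(nf * cfg$n_sites, 0, cfg$site_log_sd),
                     nrow = nf)

  # planted correlated blocks: shared per-subject latent factor with
  # per-feature loadings, added on top of the independent subject effects
  if (length(cfg$block_sizes) && any(features$block > 0L)) {
    for (b in seq_along(cfg$block_sizes)) {
      members <- which(features$block == b)
      if (!length(members)) next
      factor_s <- stats::rnorm(nrow(subjects), 0, cfg$block_log_sd)
      loading <- stats::runif(length(members), 0.7, 1.3)
      subj_eff[members, ] <- subj_eff[members, , drop = FALSE] +
        outer(loading, factor_s)
    }
  }

  dilution <- stats::setNames(
    exp(stats::rnorm(nrow(subjects), 0, cfg$dilution_log_sd)),
    subjects$sample_id)

  shapes <- make_drift_shapes(cfg$n_batches)
  sens <- stats::runif(nf, 0.5, 1.5)  # per-feature drift sensitivity

  # expected study-sample log concentration per feature x subject
  expected_log <- outer(features$baseline_log, rep(1, nrow(subjects))) +
    outer(features$slope, subjects$ga_weeks - ga_mid) +
    subj_eff +
    site_eff[, subjects$site, drop = FALSE]
  colnames(expected_log) <- subjects$subject_id
  # QC pool = equal-volume mixture of all study samples (incl. their dilution)
  pool_conc <- rowMeans(exp(expected_log) *
                          matrix(dilution[subjects$sample_id], nrow = nf,
                                 ncol = nrow(subjects), byrow = TRUE))
  blank_conc <- cfg$blank_epsilon * exp(features$baseline_log)
  blank_conc[features$contaminant] <- exp(features$baseline_log[features$contaminant])

  batch_len <- tapply(plan$injection_order, plan$batch, max)
  values <- matrix(NA_real_, nrow = nf, ncol = n_inj,
                   dimnames = list(features$feature_id, plan$injection_id))
  for (j in seq_len(n_inj)) {
    ty <- plan$type[j]
    conc <- switch(ty,
      study = exp(expected_log[, plan$subject_id[j]]) *
        dilution[[plan$sample_id[j]]],
      qc_pool = pool_conc,
      qc_dilution = pool_conc * plan$dilution_level[j],
      blank = blank_conc)
    t_norm <- if (batch_len[[plan$batch[j]]] > 1)
      (plan$injection_order[j] - 1) / (batch_len[[plan$batch[j]]] - 1) else 0
    drift <- exp(cfg$drift_amplitude * sens *
                   eval_drift_shape(shapes[[plan$batch[j]]], t_norm))
    noise <- exp(stats::rnorm(nf, 0, cfg$noise_log_sd))
    values[, j] <- conc * drift * noise
  }

  # left-censoring: everything below the missing_quantile of the
  # pre-censoring value distribution becomes missing
  if (cfg$missing_quantile > 0) {
    thr <- stats::quantile(values, cfg$missing_quantile, names = FALSE)
    values[values < thr] <- NA_real_
  }

  meta <- plan[, c("injection_id", "sample_id", "subject_id", "type", "batch",
                   "injection_order", "dilution_level")]
  meta$replicate_group <- ifelse(meta$type == "study", meta$sample_id,
                                 NA_character_)
  idx <- match(meta$subject_id, subjects$subject_id)
  meta$ga_weeks <- subjects$ga_weeks[idx]
  meta$ga_delivery <- subjects$ga_delivery[idx]
  meta$delivery_group <- subjects$delivery_group[idx]
  meta$site <- subjects$site[idx]
  rownames(meta) <- NULL

  list(table = values, meta = meta,
       dilution_factors = dilution,
       drift = list(shapes = shapes, sensitivities = stats::setNames(
         sens, features$feature_id), amplitude = cfg$drift_amplitude))
}

#' Generate a synthetic discovery cohort
#'
#' Simulates an untargeted LC-MS urine metabolomics acquisition: study
#' injections (1-4 technical replicates per sample in randomized order across
#' batches), pooled QC injections interleaved every `qc_every` study
#' injections, blank injections, and a QC dilution series. Informative
#' features follow `log(abundance) = baseline + slope * (GA - midpoint) +
#' subject effect + noise`; every injection is further multiplied by its
#' sample's dilution factor and its batch's smooth injection-order drift
#' curve, and values below the `missing_quantile` of the pre-censoring
#' distribution are censored to missing.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (non-negative feature x injection matrix,
#'   `NA` = missing), `meta` (injection metadata data.frame) and `truth`
#'   (ground-truth list: per-subject GA, delivery groups, informative
#'   feature ids and slopes, per-sample dilution factors, drift curves,
#'   contaminant ids, and the full feature parameter table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  features <- simulate_feature_params(config)

  n <- config$n_subjects
  subjects <- data.frame(
    subject_id = sprintf("D%03d", seq_len(n)),
    stringsAsFactors = FALSE)
  subjects$sample_id <- paste0("S_", subjects$subject_id)
  subjects$ga_weeks <- stats::runif(n, config$ga_range_weeks[1],
                                    config$ga_range_weeks[2])
  n_pre <- round(config$frac_preterm * n)
  grp <- rep("term", n)
  grp[sample.int(n, n_pre)] <- "preterm"
  subjects$delivery_group <- grp
  subjects$ga_delivery <- ifelse(grp == "preterm",
                                 stats::runif(n, 30, 36.9),
                                 stats::runif(n, 37.1, 41.5))
  subjects$site <- sample.int(config$n_sites, n, replace = TRUE)
  subjects$n_replicates <- sample(1:4, n, replace = TRUE,
                                  prob = config$replicate_distribution)

  sim <- simulate_from_params(features, subjects, config)
  truth <- list(
    ga_weeks = stats::setNames(subjects$ga_weeks, subjects$subject_id),
    delivery_group = stats::setNames(subjects$delivery_group,
                                     subjects$subject_id),
    informative_feature_ids = features$feature_id[features$informative],
    slopes = stats::setNames(features$slope[features$informative],
                             features$feature_id[features$informative]),
    contaminant_ids = features$feature_id[features$contaminant],
    block_members = if (any(features$block > 0L))
      split(features$feature_id[features$block > 0L],
            features$block[features$block > 0L]),
    dilution_factors = sim$dilution_factors,
    drift = sim$drift,
    features = features,
    subjects = subjects)
  list(table = sim$table, meta = sim$meta, truth = truth)
}

#' Generate an independent validation cohort sharing the discovery truth
#'
#' New subjects (all delivering at term) are drawn from the same generative
#' model, reusing the discovery cohort's feature parameters (baselines,
#' informative features and slopes, contaminants) so that a model trained on
#' discovery transfers. Randomness is drawn from a stream decoupled from the
#' discovery seed.
#'
#' @param config A [sim_config()]; `n_validation` sets the cohort size.
#' @param shared_truth `truth` element returned by [generate_cohort()].
#' @return A list with `table` and `meta` as in [generate_cohort()].
#' @export
generate_validation_cohort <- function(config, shared_truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_validation <= 0L)
    stop("generate_validation_cohort: n_validation must be positive")
  if (is.null(shared_truth$features))
    stop("generate_validation_cohort: shared_truth lacks feature parameters")
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  # a small validation cohort is acquired in a single batch
  config$n_batches <- 1L
  n <- config$n_validation
  subjects <- data.frame(
    subject_id = sprintf("V%03d", seq_len(n)),
    stringsAsFactors = FALSE)
  subjects$sample_id <- paste0("S_", subjects$subject_id)
  subjects$ga_weeks <- stats::runif(n, config$ga_range_weeks[1],
                                    config$ga_range_weeks[2])
  subjects$delivery_group <- "term"
  subjects$ga_delivery <- stats::runif(n, 37.1, 41.5)
  subjects$site <- sample.int(config$n_sites, n, replace = TRUE)
  subjects$n_replicates <- sample(1:4, n, replace = TRUE,
                                  prob = config$replicate_distribution)
  sim <- simulate_from_params(shared_truth$features, subjects, config)
  list(table = sim$table, meta = sim$meta)
}

#' Expected injection count for a simulated cohort
#'
#' Recomputes, from a cohort's metadata and its config, the conservation
#' identity: total injections = study replicates + blanks + QC pools + QC
#' dilution series.
#'
#' @param meta Injection metadata from [generate_cohort()].
#' @return Named integer vector of per-type counts plus the total.
#' @export
injection_census <- function(meta) {
  counts <- table(factor(meta$type, levels = c("study", "qc_pool", "blank",
                                               "qc_dilution")))
  out <- as.vector(counts)
  names(out) <- names(counts)
  c(out, total = nrow(meta))
}

#' Write a simulated cohort to plain-text files
#'
#' Feature table as TSV (rows = features, columns = injections), metadata as
#' CSV, ground truth as JSON. All regenerable from the config and seed.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, "feature_table.tsv")
  mp <- file.path(dir, "injection_metadata.csv")
  write_feature_table(cohort$table, tp)
  utils::write.csv(cohort$meta, mp, row.names = FALSE)
  paths <- c(table = tp, meta = mp)
  if (!is.null(cohort$truth)) {
    gp <- file.path(dir, "ground_truth.json")
    truth <- cohort$truth
    truth$drift$shapes <- lapply(truth$drift$shapes, unlist)
    jsonlite::write_json(truth, gp, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    paths <- c(paths, truth = gp)
  }
  invisible(paths)
}
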
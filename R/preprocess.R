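#' Filter and normalization configurations
#'
#' `filter_config()` holds the QC-driven feature filters: the blank filter
#' (features whose mean blank signal reaches `blank_ratio_max` of the mean QC
#' signal are discarded), the dilution-linearity filter (features whose
#' Pearson r against the QC dilution series falls below `dilution_r_min` are
#' discarded), and the presence filter (features kept only when present,
#' i.e. non-missing, in strictly more than `presence_fraction` of study
#' injections). `loess_config()` controls the per-batch LOESS signal-drift
#' correction fitted on pooled QC injections.
#'
#' @param dilution_r_min Minimum Pearson r of abundance vs dilution level.
#' @param presence_fraction Presence threshold, strict ">".
#' @param blank_ratio_max Blank/QC mean signal ratio at or above which a
#'   feature is treated as background.
#' @return A validated config list.
#' @export
filter_config <- function(dilution_r_min = 0.6,
                          presence_fraction = 2 / 3,
                          blank_ratio_max = 0.5) {
  cfg <- list(dilution_r_min = dilution_r_min,
              presence_fraction = presence_fraction,
              blank_ratio_max = blank_ratio_max)
  for (nm in names(cfg))
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1)
      stop("filter_config: '", nm, "' must be in (0, 1]")
  class(cfg) <- c("filter_config", "list")
  cfg
}

#' @rdname filter_config
#' @param span LOESS smoothing fraction.
#' @param min_qc_per_batch Minimum pooled-QC injections required to correct
#'   a batch; below this the batch is skipped with a warning.
#' @param per_batch Fit one curve per batch (recommended) rather than one
#'   global curve.
#' @export
loess_config <- function(span = 0.75, min_qc_per_batch = 5L,
                         per_batch = TRUE) {
  if (span <= 0 || span > 1) stop("loess_config: span must be in (0, 1]")
  structure(list(span = span, min_qc_per_batch = as.integer(min_qc_per_batch),
                 per_batch = isTRUE(per_batch)),
            class = c("loess_config", "list"))
}

# column means treating missing as zero signal (left-censored data)
col_mean_zero <- function(m) {
  m[is.na(m)] <- 0
  rowMeans(m)
}

#' Remove background features using blank injections
#'
#' A feature is background when its mean signal in blank injections reaches
#' `blank_ratio_max` times its mean signal in pooled-QC injections. Missing
#' values count as zero signal (they are left-censored low values).
#'
#' @param table Feature x injection matrix.
#' @param meta Injection metadata (`type` column).
#' @param cfg A [filter_config()].
#' @return List with the filtered `table` and `removed_ids`.
#' @export
filter_blank_features <- function(table, meta, cfg = filter_config()) {
  meta <- align_meta(table, meta)
  blanks <- meta$type == "blank"
  qcs <- meta$type == "qc_pool"
  if (!any(blanks))
    stop("no blank injections present; skip the blank filter explicitly ",
         "if your acquisition had none")
  if (!any(qcs)) stop("no qc_pool injections present")
  bmean <- col_mean_zero(table[, blanks, drop = FALSE])
  qmean <- col_mean_zero(table[, qcs, drop = FALSE])
  ratio <- ifelse(qmean > 0, bmean / qmean, Inf)
  removed <- rownames(table)[ratio >= cfg$blank_ratio_max]
  list(table = table[!(rownames(table) %in% removed), , drop = FALSE],
       removed_ids = removed)
}

#' Remove features without dilution linearity
#'
#' Per feature, the Pearson correlation between abundance and dilution level
#' across the QC dilution series is computed; features with r below
#' `dilution_r_min` are discarded. Missing values within the series are
#' treated as zero abundance; an undefined r (zero variance) fails the
#' filter.
#'
#' @inheritParams filter_blank_features
#' @return List with the filtered `table` and `removed_ids`.
#' @export
filter_dilution_linearity <- function(table, meta, cfg = filter_config()) {
  meta <- align_meta(table, meta)
  ser <- meta$type == "qc_dilution"
  levels <- meta$dilution_level[ser]
  if (length(unique(levels)) < 3L)
    stop("the QC dilution series needs >= 3 distinct levels")
  x <- table[, ser, drop = FALSE]
  x[is.na(x)] <- 0
  r <- apply(x, 1L, function(v) {
    if (stats::sd(v) == 0) return(0)
    stats::cor(v, levels)
  })
  removed <- rownames(table)[r < cfg$dilution_r_min]
  list(table = table[!(rownames(table) %in% removed), , drop = FALSE],
       removed_ids = removed)
}

#' Remove sparsely observed features
#'
#' Keeps a feature iff its non-missing fraction among study injections is
#' strictly greater than `presence_fraction` (default 2/3).
#'
#' @inheritParams filter_blank_features
#' @return List with the filtered `table` and `removed_ids`.
#' @export
filter_presence <- function(table, meta, cfg = filter_config()) {
  meta <- align_meta(table, meta)
  study <- meta$type == "study"
  if (!any(study)) stop("no study injections present")
  frac <- rowMeans(!is.na(table[, study, drop = FALSE]))
  removed <- rownames(table)[frac <= cfg$presence_fraction]
  list(table = table[!(rownames(table) %in% removed), , drop = FALSE],
       removed_ids = removed)
}

#' Correct injection-order signal drift with LOESS on pooled QCs
#'
#' For every feature and batch, a degree-1 LOESS curve (span per
#' `loess_config`) is fitted to the pooled-QC abundances versus injection
#' order. The multiplicative correction factor at any injection order is the
#' fitted value divided by the median fitted value at the QC orders, held
#' flat beyond the first/last QC; all injections in the batch are divided by
#' their factor. Non-positive fitted values are clamped to the smallest
#' positive fitted value in the batch. Batches with fewer than
#' `min_qc_per_batch` usable QCs are left uncorrected with a warning.
#'
#' @inheritParams filter_blank_features
#' @param cfg A [loess_config()].
#' @return Corrected feature table.
#' @export
loess_drift_correct <- function(table, meta, cfg = loess_config()) {
  meta <- align_meta(table, meta)
  out <- table
  batches <- if (cfg$per_batch) unique(meta$batch) else list(unique(meta$batch))
  for (b in batches) {
    in_batch <- meta$batch %in% b
    qc <- in_batch & meta$type == "qc_pool"
    if (sum(qc) < cfg$min_qc_per_batch) {
      warning("batch ", paste(b, collapse = "+"), ": only ", sum(qc),
              " QC pools, drift correction skipped")
      next
    }
    qc_ord <- meta$injection_order[qc]
    all_ord <- meta$injection_order[in_batch]
    # flat extrapolation beyond the terminal QCs
    eval_ord <- pmin(pmax(all_ord, min(qc_ord)), max(qc_ord))
    for (f in seq_len(nrow(table))) {
      yq <- table[f, qc]
      ok <- !is.na(yq)
      if (sum(ok) < cfg$min_qc_per_batch) next
      # loess emits numerical chatter (pseudoinverse, condition number) on
      # small QC sets; the fits themselves are fine, failures are caught
      fit <- tryCatch(
        suppressWarnings(
          stats::loess(yq[ok] ~ qc_ord[ok], span = cfg$span, degree = 1,
                       control = stats::loess.control(surface = "direct"))),
        error = function(e) NULL)
      if (is.null(fit)) next
      fitted_all <- suppressWarnings(stats::predict(fit, newdata = eval_ord))
      fitted_qc <- suppressWarnings(stats::predict(fit, newdata = qc_ord[ok]))
      ref <- stats::median(fitted_qc)
      if (!is.finite(ref) || ref == 0) next
      factors <- fitted_all / ref
      pos_min <- suppressWarnings(min(factors[factors > 0]))
      if (!is.finite(pos_min)) next
      factors[factors <= 0] <- pos_min
      out[f, in_batch] <- table[f, in_batch] / factors
    }
  }
  out
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution (urine concentration) by scaling each
#' injection by the median quotient of its abundances against a reference
#' spectrum. The reference is the per-feature median over the injections in
#' `reference_scope` ("qc": pooled QCs, the default; "study_all": all study
#' injections), ignoring missing values. Quotients use only features
#' non-missing in both the injection and the reference.
#'
#' @inheritParams filter_blank_features
#' @param reference_scope "qc" or "study_all".
#' @param min_shared Minimum shared features required per injection.
#' @return List with `normalized` (table / factors columnwise), `factors`
#'   (named per-injection positive scalars) and `reference` (per-feature
#'   spectrum).
#' @export
pqn_normalize <- function(table, meta, reference_scope = c("qc", "study_all"),
                          min_shared = 10L) {
  reference_scope <- match.arg(reference_scope)
  meta <- align_meta(table, meta)
  scope <- if (reference_scope == "qc") meta$type == "qc_pool"
           else meta$type == "study"
  if (!any(scope)) stop("no injections available for the PQN reference")
  reference <- apply(table[, scope, drop = FALSE], 1L, stats::median,
                     na.rm = TRUE)
  factors <- vapply(seq_len(ncol(table)), function(j) {
    v <- table[, j]
    shared <- !is.na(v) & !is.na(reference) & reference > 0
    if (sum(shared) < min_shared)
      stop("injection '", colnames(table)[j], "' shares fewer than ",
           min_shared, " features with the PQN reference")
    stats::median(v[shared] / reference[shared])
  }, numeric(1))
  names(factors) <- colnames(table)
  if (any(factors <= 0)) stop("non-positive PQN factor encountered")
  list(normalized = sweep(table, 2L, factors, "/"),
       factors = factors, reference = reference)
}

#' Impute missing values from low abundances
#'
#' Missingness in spectral-count data is left-censoring at the detection
#' limit, so missing entries of each injection are drawn uniformly from
#' `(0.5 * m, m)` where `m` is that injection's minimum observed value.
#'
#' @param table Feature x injection matrix.
#' @param seed Integer seed (reproducible imputation).
#' @param lower_fraction Lower edge of the draw window relative to the
#'   minimum observed value.
#' @return Table with no missing values.
#' @export
impute_missing <- function(table, seed = 1L, lower_fraction = 0.5) {
  set.seed(seed)
  out <- table
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    miss <- is.na(v)
    if (!any(miss)) next
    if (all(miss))
      stop("injection '", colnames(out)[j], "' has no observed values")
    m <- min(v[!miss])
    out[miss, j] <- stats::runif(sum(miss), lower_fraction * m, m)
  }
  out
}

#' Aggregate technical replicates into one column per sample
#'
#' Replicate injections of the same sample are combined by identity (1
#' replicate), arithmetic mean (2), or median (3-4; also used with a warning
#' for larger groups).
#'
#' @param table Feature x injection matrix (study injections only, or mixed;
#'   non-study injections are dropped).
#' @param meta Injection metadata with `replicate_group`.
#' @return List with `table` (features x samples) and `meta` (one row per
#'   sample).
#' @export
aggregate_replicates <- function(table, meta) {
  meta <- align_meta(table, meta)
  study <- meta$type == "study"
  tab <- table[, study, drop = FALSE]
  smeta <- meta[study, , drop = FALSE]
  groups <- split(seq_len(ncol(tab)), smeta$replicate_group)
  cols <- lapply(groups, function(idx) {
    n <- length(idx)
    if (n > 4L)
      warning("replicate group with ", n, " injections; using the median")
    if (n == 1L) tab[, idx]
    else if (n == 2L) rowMeans(tab[, idx, drop = FALSE])
    else apply(tab[, idx, drop = FALSE], 1L, stats::median)
  })
  agg <- matrix(unlist(cols), nrow = nrow(tab),
                dimnames = list(rownames(tab), names(groups)))
  out_meta <- smeta[match(names(groups), smeta$replicate_group), , drop = FALSE]
  out_meta$injection_id <- NULL
  out_meta$injection_order <- NULL
  rownames(out_meta) <- NULL
  colnames(agg) <- out_meta$sample_id
  list(table = agg, meta = out_meta)
}

#' Merge feature tables from different chromatography modes
#'
#' Tables (e.g. HILIC and RPLC) are concatenated by feature id over the same
#' samples. Duplicate metabolites detected in both modes remain distinct
#' features.
#'
#' @param tables List of feature x sample matrices with identical columns.
#' @return Row-bound matrix.
#' @export
merge_modes <- function(tables) {
  stopifnot(length(tables) >= 1L)
  cols <- colnames(tables[[1]])
  for (t in tables[-1])
    if (!identical(colnames(t), cols))
      stop("mode tables must share identical sample columns")
  out <- do.call(rbind, tables)
  if (anyDuplicated(rownames(out)))
    stop("duplicate feature ids across modes; prefix ids by mode")
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: blank filter, dilution-linearity filter, presence
#' filter, per-batch LOESS drift correction, PQN, low-value imputation, and
#' replicate aggregation, returning the per-sample matrix used for modelling
#' together with a provenance log of per-stage feature/injection counts.
#' HILIC and RPLC tables acquired separately should each be run through this
#' function and combined with [merge_modes()].
#'
#' @param table Raw feature x injection matrix.
#' @param meta Injection metadata.
#' @param filter_cfg A [filter_config()].
#' @param loess_cfg A [loess_config()].
#' @param pqn_scope PQN reference scope, see [pqn_normalize()].
#' @param impute_seed Seed for the imputation draws.
#' @param skip Character vector of stage names to skip (subset of
#'   "blank", "dilution", "presence", "loess", "pqn", "impute").
#' @return List with `table` (features x samples), `meta` (per-sample
#'   metadata), `pqn` (factors + reference) and `log` (per-stage records).
#' @export
run_preprocessing <- function(table, meta,
                              filter_cfg = filter_config(),
                              loess_cfg = loess_config(),
                              pqn_scope = "qc",
                              impute_seed = 1L,
                              skip = character()) {
  assert_feature_table(table)
  log <- list()
  note <- function(stage, tab, removed = character()) {
    log[[stage]] <<- list(stage = stage, n_features = nrow(tab),
                          n_injections = ncol(tab),
                          n_removed = length(removed),
                          removed_ids = removed)
  }
  note("input", table)

  if (!"blank" %in% skip) {
    st <- filter_blank_features(table, meta, filter_cfg)
    table <- st$table; note("blank_filter", table, st$removed_ids)
  }
  if (!"dilution" %in% skip) {
    st <- filter_dilution_linearity(table, meta, filter_cfg)
    table <- st$table; note("dilution_filter", table, st$removed_ids)
  }
  if (!"presence" %in% skip) {
    st <- filter_presence(table, meta, filter_cfg)
    table <- st$table; note("presence_filter", table, st$removed_ids)
  }

  # blanks and the dilution series have served the filters; drop them
  # before normalization (they carry no usable signal)
  meta_al <- align_meta(table, meta)
  keep_inj <- meta_al$type %in% c("study", "qc_pool")
  table <- table[, keep_inj, drop = FALSE]
  note("drop_non_study", table)
  if (!"loess" %in% skip) {
    table <- loess_drift_correct(table, meta, loess_cfg)
    note("loess_drift", table)
  }
  pqn <- NULL
  if (!"pqn" %in% skip) {
    pqn <- pqn_normalize(table, meta, pqn_scope)
    table <- pqn$normalized
    note("pqn", table)
  }
  if (!"impute" %in% skip) {
    table <- impute_missing(table, seed = impute_seed)
    note("impute", table)
  }
  agg <- aggregate_replicates(table, meta)
  note("aggregate", agg$table)

  list(table = agg$table, meta = agg$meta,
       pqn = if (!is.null(pqn)) pqn[c("factors", "reference")],
       log = log)
}
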
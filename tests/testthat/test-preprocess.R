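make_tiny <- function(values, types, dil = NULL) {
  n <- length(types)
  inj <- sprintf("I%02d", seq_len(n))
  rn <- if (is.matrix(values) && !is.null(rownames(values)) &&
            all(nzchar(rownames(values))))
    rownames(values) else sprintf("F%02d", seq_len(length(values) / n))
  tab <- matrix(values, ncol = n, dimnames = list(rn, inj))
  meta <- data.frame(injection_id = inj, sample_id = inj,
                     subject_id = NA, type = types, batch = 1L,
                     injection_order = seq_len(n),
                     dilution_level = if (is.null(dil)) NA_real_ else dil,
                     replicate_group = ifelse(types == "study", inj, NA),
                     stringsAsFactors = FALSE)
  list(table = tab, meta = meta)
}

test_that("blank filter removes background features by blank/QC ratio", {
  tt <- make_tiny(rbind(c(0, 0, 100, 100),      # blank mean 0 -> kept
                        c(100, 100, 100, 100),  # blank = QC -> removed
                        c(49, 49, 100, 100),    # ratio 0.49 -> kept
                        c(50, 50, 100, 100)),   # ratio 0.50 -> removed
                  c("blank", "blank", "qc_pool", "qc_pool"))
  res <- filter_blank_features(tt$table, tt$meta)
  expect_setequal(res$removed_ids, c("F02", "F04"))
  expect_setequal(rownames(res$table), c("F01", "F03"))

  no_blank <- make_tiny(matrix(1, 1, 2), c("qc_pool", "study"))
  expect_error(filter_blank_features(no_blank$table, no_blank$meta),
               "blank")
})

test_that("dilution linearity uses Pearson r with hand-checked values", {
  x <- c(1, 2.1, 2.9, 4.2, 4.8)
  lv <- 1:5
  r_hand <- oracle_pearson(x, lv)
  expect_equal(r_hand, 9.7 / sqrt(9.5 * 10), tolerance = 1e-12)

  tt <- make_tiny(rbind(10 * lv,                 # exactly proportional
                        x,                       # hand case, r ~ 0.995
                        rep(7, 5),               # constant -> undefined -> out
                        c(5, 4, 3, 2, 1)),       # r = -1 -> out
                  rep("qc_dilution", 5), dil = lv)
  res <- filter_dilution_linearity(tt$table, tt$meta)
  expect_setequal(res$removed_ids, c("F03", "F04"))
  expect_true(all(c("F01", "F02") %in% rownames(res$table)))
  expect_true(r_hand >= 0.6)

  few <- make_tiny(matrix(1, 1, 2), rep("qc_dilution", 2), dil = 1:2)
  expect_error(filter_dilution_linearity(few$table, few$meta), "3")
})

test_that("presence filter applies the strict > 2/3 rule on 99 samples", {
  types <- rep("study", 99)
  v67 <- c(rep(1, 67), rep(NA, 32))
  v66 <- c(rep(1, 66), rep(NA, 33))
  tt <- make_tiny(rbind(v67, v66, rep(1, 99)), types)
  res <- filter_presence(tt$table, tt$meta)
  expect_identical(res$removed_ids, "F02")   # 66/99 == 2/3 exactly
  expect_true(all(c("F01", "F03") %in% rownames(res$table)))
})

test_that("filters are idempotent on their own output", {
  fx <- make_filter_fixture()
  b1 <- filter_blank_features(fx$table, fx$meta)
  b2 <- filter_blank_features(b1$table, fx$meta)
  expect_length(b2$removed_ids, 0)
  d1 <- filter_dilution_linearity(fx$table, fx$meta)
  d2 <- filter_dilution_linearity(d1$table, fx$meta)
  expect_length(d2$removed_ids, 0)
  p1 <- filter_presence(fx$table, fx$meta)
  p2 <- filter_presence(p1$table, fx$meta)
  expect_length(p2$removed_ids, 0)
})

test_that("LOESS drift correction is a no-op on constant QCs and removes a linear drift", {
  # constant QC signal: factors all 1
  n <- 30
  types <- rep("study", n); types[seq(1, n, by = 5)] <- "qc_pool"
  tt <- make_tiny(matrix(100, 2, n, dimnames = list(c("Fa", "Fb"),
                                                    sprintf("I%02d", 1:n))),
                  types)
  corrected <- loess_drift_correct(tt$table, tt$meta)
  expect_equal(corrected, tt$table, tolerance = 1e-9)

  # linear 2x drift across the batch: post-correction QC slope ~ 0
  drift <- seq(1, 2, length.out = n)
  tt2 <- tt
  tt2$table <- sweep(tt$table, 2, drift, `*`)
  corr2 <- loess_drift_correct(tt2$table, tt2$meta)
  qc <- tt2$meta$type == "qc_pool"
  # relative QC trend: slope of (value / mean value) per SD of order
  rel_slope <- function(v, ord)
    abs(coef(lm(I(v / mean(v)) ~ scale(ord)))[2])
  o <- tt2$meta$injection_order[qc]
  expect_gt(rel_slope(tt2$table["Fa", qc], o), 0.2)  # drift visible before
  expect_lt(rel_slope(corr2["Fa", qc], o), 0.05)     # flattened after
  # and the QC CV strictly decreases
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(corr2["Fa", qc]), cv(tt2$table["Fa", qc]))
})

test_that("per-batch LOESS handles opposite drifts that a global fit cannot", {
  n <- 30
  mk <- function(batch, drift) {
    types <- rep("study", n); types[seq(1, n, by = 5)] <- "qc_pool"
    inj <- sprintf("B%d_%02d", batch, 1:n)
    tab <- matrix(100 * drift, 1, n, dimnames = list("Fa", inj))
    meta <- data.frame(injection_id = inj, sample_id = inj, subject_id = NA,
                       type = types, batch = batch, injection_order = 1:n,
                       dilution_level = NA_real_,
                       replicate_group = NA, stringsAsFactors = FALSE)
    list(tab = tab, meta = meta)
  }
  up <- mk(1, seq(1, 2, length.out = n))
  down <- mk(2, seq(2, 1, length.out = n))
  tab <- cbind(up$tab, down$tab)
  meta <- rbind(up$meta, down$meta)
  per_batch <- loess_drift_correct(tab, meta, loess_config(per_batch = TRUE))
  global <- loess_drift_correct(tab, meta, loess_config(per_batch = FALSE))
  # residual QC scatter within each batch
  resid <- function(m, b) {
    qc <- meta$type == "qc_pool" & meta$batch == b
    sd(m["Fa", qc]) / mean(m["Fa", qc])
  }
  for (b in 1:2) {
    expect_lt(resid(per_batch, b), 1e-6)
    expect_gt(resid(global, b), 0.05)
  }
})

test_that("LOESS warns and skips batches with too few QC pools", {
  tt <- make_tiny(matrix(100, 1, 6),
                  c("qc_pool", rep("study", 4), "qc_pool"))
  expect_warning(out <- loess_drift_correct(tt$table, tt$meta),
                 "skipped")
  expect_equal(out, tt$table)
})

test_that("PQN recovers exact scaling factors and normalizes to unit median quotient", {
  ref <- c(100, 200, 50, 80, 10, 30, 70, 90, 120, 40, 60, 110)
  tab <- cbind(QC1 = ref, QC2 = ref, A = ref, B = 3 * ref, C = 0.5 * ref)
  rownames(tab) <- sprintf("F%02d", seq_along(ref))
  meta <- data.frame(injection_id = colnames(tab),
                     sample_id = colnames(tab), subject_id = NA,
                     type = c("qc_pool", "qc_pool", "study", "study", "study"),
                     batch = 1L, injection_order = 1:5,
                     dilution_level = NA_real_,
                     replicate_group = c(NA, NA, "A", "B", "C"),
                     stringsAsFactors = FALSE)
  res <- pqn_normalize(tab, meta)
  expect_equal(unname(res$factors[c("A", "B", "C")]), c(1, 3, 0.5))
  expect_equal(res$normalized[, "B"], res$reference,
               ignore_attr = TRUE)
  # invariant: post-normalization median quotient vs reference is 1
  for (j in colnames(tab)) {
    q <- res$normalized[, j] / res$reference
    expect_equal(median(q, na.rm = TRUE), 1, tolerance = 1e-9)
  }
  # an injection sharing too few features errors by name
  tab2 <- tab
  tab2[2:12, "C"] <- NA
  expect_error(pqn_normalize(tab2, meta), "'C'")
})

test_that("PQN factors are ~1 when the simulation has no dilution or drift", {
  # full feature complement: the median quotient concentrates around 1
  cfg <- sim_config(seed = 4, drift_amplitude = 0, dilution_log_sd = 0,
                    missing_quantile = 0)
  co <- generate_cohort(cfg)
  # reference from the study population itself, so biological variation
  # cancels in the median quotient
  res <- pqn_normalize(co$table, co$meta, reference_scope = "study_all")
  study <- co$meta$type == "study"
  expect_lt(median(abs(res$factors[co$meta$injection_id[study]] - 1)), 0.02)

  # with technical noise also silenced, LOESS is an exact no-op
  cfg0 <- sim_config(seed = 4, drift_amplitude = 0, dilution_log_sd = 0,
                     noise_log_sd = 0, missing_quantile = 0)
  co0 <- generate_cohort(cfg0)
  corrected <- loess_drift_correct(co0$table, co0$meta)
  rel <- abs(corrected - co0$table) / co0$table
  expect_lt(max(rel, na.rm = TRUE), 0.01)
})

test_that("imputation draws low values per injection, reproducibly", {
  tab <- matrix(c(10, 20, NA, 40,
                  50, NA, NA, 80), ncol = 2,
                dimnames = list(sprintf("F%d", 1:4), c("A", "B")))
  a <- impute_missing(tab, seed = 11)
  b <- impute_missing(tab, seed = 11)
  expect_identical(a, b)
  expect_false(anyNA(a))
  expect_identical(a[!is.na(tab)], tab[!is.na(tab)])

  # range check over many draws: (0.5 * min, min) per injection
  big <- matrix(NA_real_, nrow = 1001, ncol = 1,
                dimnames = list(sprintf("F%04d", 1:1001), "A"))
  big[1, 1] <- 10
  imp <- impute_missing(big, seed = 2)
  draws <- imp[-1, 1]
  expect_true(all(draws > 5 & draws < 10))

  all_na <- matrix(NA_real_, 2, 1, dimnames = list(c("F1", "F2"), "A"))
  expect_error(impute_missing(all_na), "observed")
})

test_that("replicate aggregation uses identity/mean/median by group size", {
  tab <- matrix(c(5,            # sample A, n = 1
                  2, 4,         # sample B, n = 2 -> mean 3
                  1, 2, 9,      # sample C, n = 3 -> median 2
                  1, 2, 3, 10), # sample D, n = 4 -> median 2.5
                nrow = 1)
  colnames(tab) <- sprintf("I%02d", 1:10)
  rownames(tab) <- "Fa"
  meta <- data.frame(injection_id = colnames(tab),
                     sample_id = c("A", "B", "B", "C", "C", "C",
                                   "D", "D", "D", "D"),
                     subject_id = NA, type = "study", batch = 1L,
                     injection_order = 1:10, dilution_level = NA_real_,
                     stringsAsFactors = FALSE)
  meta$replicate_group <- meta$sample_id
  res <- aggregate_replicates(tab, meta)
  expect_equal(res$table["Fa", c("A", "B", "C", "D")],
               c(A = 5, B = 3, C = 2, D = 2.5))
})

test_that("run_preprocessing removes exactly the constructed bad features", {
  fx <- make_filter_fixture()
  res <- run_preprocessing(fx$table, fx$meta, impute_seed = 1)
  expected_removed <- c(fx$contaminants, fx$low_presence, fx$nonlinear)
  kept <- rownames(res$table)
  expect_setequal(kept, fx$clean)
  expect_length(kept, 27)
  removed_logged <- unlist(lapply(res$log, `[[`, "removed_ids"))
  expect_setequal(removed_logged, expected_removed)
  expect_length(removed_logged, 33)
  expect_true(fx$boundary_kept %in% kept)
  expect_false(fx$boundary_removed %in% kept)
  # output is one column per sample with no missing or negative values
  expect_equal(ncol(res$table), 99)
  expect_false(anyNA(res$table))
  expect_true(all(res$table >= 0))
  # rerun is identical
  res2 <- run_preprocessing(fx$table, fx$meta, impute_seed = 1)
  expect_identical(res$table, res2$table)
})

test_that("mode merge concatenates feature tables over shared samples", {
  a <- matrix(1, 2, 3, dimnames = list(c("HILIC_1", "HILIC_2"),
                                       c("S1", "S2", "S3")))
  b <- matrix(2, 1, 3, dimnames = list("RPLC_1", c("S1", "S2", "S3")))
  m <- merge_modes(list(a, b))
  expect_equal(dim(m), c(3L, 3L))
  expect_error(merge_modes(list(a, b[, c(2, 1, 3), drop = FALSE])),
               "identical sample columns")
  expect_error(merge_modes(list(a, a)), "duplicate")
})
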
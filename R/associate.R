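#' Univariate association screen against gestational age
#'
#' Per feature: Spearman's rank correlation (tie-corrected, asymptotic
#' two-sided P) between abundance and GA, and a volcano-style beta — the
#' ordinary least-squares slope of log2 abundance on GA in weeks. Features
#' are flagged significant at raw `p < alpha` without multiplicity
#' correction, matching common practice for this screen; Benjamini-Hochberg
#' adjusted values are returned alongside for stricter reuse. Constant
#' features get rho = 0, p = 1.
#'
#' @param X Sample x feature matrix of positive abundances.
#' @param y GA at collection (weeks).
#' @param alpha Raw significance threshold.
#' @return data.frame: feature_id, rho, p, p_bh, beta, significant.
#' @export
spearman_screen <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  res <- t(apply(X, 2L, function(v) {
    if (stats::sd(v) == 0) return(c(0, 1))
    ct <- suppressWarnings(
      stats::cor.test(v, y, method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }))
  beta <- apply(X, 2L, function(v) {
    if (any(v <= 0)) return(NA_real_)
    unname(stats::coef(stats::lm(log2(v) ~ y))[2])
  })
  data.frame(feature_id = colnames(X),
             rho = res[, 1], p = res[, 2],
             p_bh = stats::p.adjust(res[, 2], "BH"),
             beta = beta,
             significant = res[, 2] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PCA axes most associated with gestational age
#'
#' Principal components of the (per-feature standardized) significant
#' feature matrix; each PC's scores are correlated with GA by Spearman's
#' rho, and the two PCs with the largest absolute rho are reported as the
#' GA axes — the dominant variance direction need not be the GA direction.
#'
#' @param X_sig Sample x feature matrix (significant features, typically
#'   log2 abundances).
#' @param y GA at collection (weeks).
#' @param n_components PCs to examine.
#' @return List: `scores` (samples x PCs), `sdev`, `pc_ga_correlations`
#'   (named rho per PC), `chosen_pcs` (two PC names, strongest first).
#' @export
pca_ga_axes <- function(X_sig, y, n_components = 10L) {
  X_sig <- as.matrix(X_sig)
  if (nrow(X_sig) < 3L) stop("PCA needs at least 3 samples")
  if (ncol(X_sig) < 2L) stop("PCA needs at least 2 features")
  keep <- apply(X_sig, 2L, stats::sd) > 0
  pc <- stats::prcomp(X_sig[, keep, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rho <- apply(scores, 2L, function(s)
    suppressWarnings(stats::cor(s, y, method = "spearman")))
  chosen <- names(sort(abs(rho), decreasing = TRUE))[seq_len(min(2L, k))]
  list(scores = scores, sdev = pc$sdev,
       pc_ga_correlations = rho, chosen_pcs = chosen)
}

#' Coefficient of variation per gestational-age bin
#'
#' CV = SD/mean of raw normalized abundances of the samples falling in each
#' GA bin, per feature, computed separately for each outcome group. Bins
#' with zero mean give a missing CV; empty bins are flagged.
#'
#' @param X_top Sample x feature matrix (raw normalized abundances, not
#'   log-transformed).
#' @param y GA at collection (weeks).
#' @param breaks Bin edges in weeks (right-closed except the first bin).
#' @param groups Outcome labels per sample (e.g. term/preterm); NULL treats
#'   all samples as one group.
#' @return Named list per group with `cv` (features x bins matrix),
#'   `bin_labels` and `empty_bins`.
#' @export
cv_by_ga_bin <- function(X_top, y, breaks = c(8, 11, 14, 17, 19),
                         groups = NULL) {
  X_top <- as.matrix(X_top)
  stopifnot(nrow(X_top) == length(y))
  if (is.null(groups)) groups <- rep("all", length(y))
  bins <- cut(y, breaks = breaks, include.lowest = TRUE)
  out <- list()
  for (g in unique(as.character(groups))) {
    sel <- groups == g
    cvm <- vapply(levels(bins), function(b) {
      idx <- sel & bins == b
      if (sum(idx) < 2L) return(rep(NA_real_, ncol(X_top)))
      apply(X_top[idx, , drop = FALSE], 2L, function(v) {
        m <- mean(v)
        if (m == 0) NA_real_ else stats::sd(v) / m
      })
    }, numeric(ncol(X_top)))
    cvm <- matrix(cvm, nrow = ncol(X_top),
                  dimnames = list(colnames(X_top), levels(bins)))
    out[[g]] <- list(cv = cvm, bin_labels = levels(bins),
                     empty_bins = levels(bins)[colSums(!is.na(cvm)) == 0])
  }
  out
}

#' Pathway over-representation by the one-sided Fisher exact test
#'
#' For each pathway, a 2x2 table (in/out of pathway x significant/not,
#' within the background) is tested for enrichment with a one-sided Fisher
#' exact test; pathways with P <= alpha are flagged significant.
#'
#' @param significant_ids Significant feature/metabolite annotations
#'   (subset of the background).
#' @param background_ids All tested annotations.
#' @param pathways Named list mapping pathway id to its annotation set.
#' @param alpha Significance threshold (inclusive).
#' @return data.frame: pathway_id, n_pathway (in background), n_hits, p,
#'   significant; ordered by p.
#' @export
pathway_ora <- function(significant_ids, background_ids, pathways,
                        alpha = 0.05) {
  background_ids <- unique(background_ids)
  if (length(background_ids) == 0L) stop("empty background")
  significant_ids <- unique(significant_ids)
  if (!all(significant_ids %in% background_ids))
    stop("significant_ids must be a subset of background_ids")
  N <- length(background_ids)
  n_sig <- length(significant_ids)
  rows <- lapply(names(pathways), function(pw) {
    in_pw <- intersect(pathways[[pw]], background_ids)
    K <- length(in_pw)
    hits <- length(intersect(in_pw, significant_ids))
    p <- if (K == 0L) 1 else
      stats::fisher.test(matrix(c(hits, K - hits,
                                  n_sig - hits, N - K - (n_sig - hits)),
                                nrow = 2L),
                         alternative = "greater")$p.value
    data.frame(pathway_id = pw, n_pathway = K, n_hits = hits, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p <= alpha
  out[order(out$p), , drop = FALSE]
}

#' Read pathway definitions from a two-column TSV
#'
#' @param path TSV with columns pathway_id, feature_annotation (no header
#'   required; a header line named exactly so is tolerated).
#' @return Named list of annotation character vectors.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("pathway_id", "feature_annotation"))
  if (df$pathway_id[1] == "pathway_id") df <- df[-1, , drop = FALSE]
  split(df$feature_annotation, df$pathway_id)
}

#' Overlap between stratified and full-model feature panels
#'
#' Reports the percentage of each stratified panel recovered by the full
#' model and the full three-set Venn partition.
#'
#' @param selected_full,selected_A,selected_B Identifier sets (full-cohort,
#'   e.g. term, e.g. preterm panels).
#' @return List: `overlap_A_pct`, `overlap_B_pct` (NA when the panel is
#'   empty), and `venn` — named counts of the 7 exclusive regions
#'   (full_only, A_only, B_only, full_A, full_B, A_B, full_A_B).
#' @export
model_overlap <- function(selected_full, selected_A, selected_B) {
  f <- unique(selected_full); a <- unique(selected_A); b <- unique(selected_B)
  pct <- function(x, ref) if (length(x) == 0L) NA_real_ else
    100 * length(intersect(x, ref)) / length(x)
  all_ids <- union(f, union(a, b))
  inf <- all_ids %in% f; ina <- all_ids %in% a; inb <- all_ids %in% b
  venn <- c(full_only = sum(inf & !ina & !inb),
            A_only = sum(!inf & ina & !inb),
            B_only = sum(!inf & !ina & inb),
            full_A = sum(inf & ina & !inb),
            full_B = sum(inf & !ina & inb),
            A_B = sum(!inf & ina & inb),
            full_A_B = sum(inf & ina & inb))
  list(overlap_A_pct = pct(a, f), overlap_B_pct = pct(b, f), venn = venn)
}
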
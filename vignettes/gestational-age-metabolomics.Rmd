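---
title: "Predicting gestational age from urine metabolomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gestational age from urine metabolomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urigest)
```

## The problem

Accurate dating of a pregnancy guides essentially every clinical decision
made during it, yet the reference method — early obstetric ultrasound — is
unavailable to many women in low-resource settings. Urine is the easiest
biofluid to collect, and the urinary metabolome changes strongly and
monotonically across gestation, driven largely by placental steroid
biosynthesis (estrogen and progesterone conjugates rise severalfold between
weeks 8 and 19). `urigest` implements an analysis pipeline that turns an
untargeted LC–MS urine feature table into a gestational-age (GA) predictor:
QC-driven preprocessing, random-forest regression evaluated by external
leave-one-out cross-validation (LOOCV), selection of a parsimonious
metabolite panel, stratified comparison of term and preterm pregnancies,
univariate association and correlation-network analyses, and MS/MS
spectral-library annotation.

Because instrument data cannot ship with a package, `urigest` also contains
a first-class synthetic-cohort generator that emulates the statistical
structure such a study produces; every stage of the pipeline is tested
against the generator's known ground truth.

## The generative model behind the simulator

`generate_cohort()` draws, for feature $f$ and subject $s$,

$$\log A_{fs} = \mu_f + \beta_f \,(\mathrm{GA}_s - \overline{\mathrm{GA}})
  + b_{fs} + u_{f,\mathrm{site}(s)}$$

with log-normal baselines $\mu_f$, GA slopes $\beta_f$ non-zero for a
minority of informative features (55% positive / 45% negative by default),
independent subject effects $b_{fs}$, and small feature-specific site
offsets. Each injection then multiplies this concentration by its sample's
dilution factor (log-normal), its batch's smooth injection-order drift
curve (a random linear-plus-cosine shape with per-feature sensitivity) and
log-normal technical noise. Values below the 5% quantile of the
pre-censoring distribution become missing — missingness is left-censoring
at the detection limit, which is what justifies low-value imputation
downstream. The acquisition layout mirrors untargeted practice: 1–4
technical replicates per sample in randomized order over 4 batches, a
pooled-QC injection every 10 study injections, blank injections, and a
5-level QC dilution series spanning a 5-fold range.

Key default choices, with reasoning:

* **GA at collection ~ Uniform(8, 19) weeks**, one sample per subject —
  the early-pregnancy window in which the panel is meant to operate.
* **99 discovery subjects (≈50% later preterm), 20 validation subjects
  (all term)** — a realistic multi-site discovery/validation split for this
  kind of cohort.
* **`dilution_log_sd = 0.5`** — urine concentration varies severalfold with
  hydration; the simulated factors span roughly a 10-fold range.
* **`biological_log_sd = 0.55`** — calibrated so that the default cohort
  yields full-model LOOCV performance on the scale this class of predictor
  achieves in practice (Spearman ρ ≈ 0.85–0.9, RMSE ≈ 1.8 weeks) rather
  than a noise-free toy; between-subject variation, not instrument noise,
  is the binding constraint on real GA predictors.
* **Preterm mechanism**: subjects destined to deliver preterm whose sample
  falls between weeks 14 and 17 receive a 2× inflated subject-effect SD on
  the informative features. This emulates the observed phenomenon that
  preterm pregnancies show higher inter-individual variability of GA-marker
  levels in mid-gestation, and it is the only way term and preterm cohorts
  differ in the generator.
* **Contaminant features** have blank signal equal to study signal, giving
  the blank filter something real to remove; optional planted correlated
  blocks (shared latent factor per subject) emulate co-regulated metabolite
  families (steroid conjugates; amino acids) for network analyses.
* **Site effects are feature-specific.** A uniform per-site scaling would
  be mathematically indistinguishable from dilution and silently absorbed
  by PQN; feature-specific offsets are both more realistic (handling and
  storage affect compounds differentially) and keep the dilution ground
  truth identifiable.

What the simulator does **not** model: chromatographic peak shapes, m/z
space and adduct structure, correlated missingness between co-eluting
features, non-monotone GA trajectories, and real between-site batch
structure. Passing recovery tests on simulated data therefore demonstrates
that the implementation does what it claims under the stated model — not
that the model captures everything real data do.

## Preprocessing

Stages run in a fixed order; each is also exported on its own.

1. **Blank filter** — a feature is background if mean(blank) ≥ 0.5 ×
   mean(pooled QC). Missing values count as zero signal (they are censored
   low values). The 0.5 ratio is conventional and configurable.
2. **Dilution-linearity filter** — Pearson r of abundance versus dilution
   level across the QC dilution series; features with r < 0.6 are removed.
   A zero-variance series gives an undefined r and fails the filter.
3. **Presence filter** — keep a feature iff it is non-missing in strictly
   more than 2/3 of study injections: 66/99 is removed, 67/99 kept.
4. **LOESS drift correction** — per feature and batch, a degree-1 LOESS
   (span 0.75) of pooled-QC abundance on injection order; every injection
   is divided by fitted/median(fitted at QCs). Extrapolation beyond the
   terminal QCs is flat, and non-positive fitted values are clamped to the
   smallest positive fitted value, so corrections are always positive and
   bounded. Division (not subtraction) is used because MS intensity error
   is multiplicative. Batches with fewer than 5 usable QCs are skipped
   with a warning rather than corrected from too little evidence.
5. **PQN** — the reference spectrum is the per-feature median over pooled
   QCs (configurable to all study injections); each injection is divided by
   the median of its feature-wise quotients against the reference. After
   normalization every injection's median quotient is exactly 1. An
   injection sharing fewer than 10 features with the reference is an error,
   not a silent NA.
6. **Imputation** — missing entries are drawn uniformly from
   (0.5·m, m) where m is the injection's minimum observed value, seeded.
7. **Replicate aggregation** — identity (n = 1), mean (n = 2), median
   (n = 3–4; also for larger groups, with a warning).

HILIC and RPLC tables, which come from separate acquisitions, should each
pass through the chain and be combined with `merge_modes()`; metabolites
detected in both modes stay distinct features.

## Prediction

`loocv_predict()` implements strictly external LOOCV: sample *i* is
predicted by a forest trained on the other n−1 samples, and no filter,
normalization statistic or tuning decision ever sees the held-out sample.
Internal 5-fold cross-validation over a small grid (feature fraction per
split × minimum leaf size) can be enabled per training set
(`tune = TRUE`, the default constructor setting); the runs reported by this
package's scripts use the fixed ranger-style defaults (`tune = FALSE`,
mtry = p/3, leaf size 5), which pilot runs showed to be statistically
indistinguishable on simulated cohorts at a fraction of the cost. Metrics
are Spearman's ρ (tie-corrected, asymptotic two-sided P) and RMSE in weeks;
a constant prediction vector reports ρ = 0.

The **restricted model** operationalizes "fewest metabolites that retain
predictive ability" with the 1-SE rule: features are ranked by impurity
importance averaged over the LOOCV fold models (ties broken by id), the
LOOCV RMSE path is computed for panels of size 1…max_k, and the chosen k is
the smallest whose RMSE is within one standard error of the minimum (the SE
of the mean squared error at the minimizing k, propagated to the RMSE
scale). `apply_model()` then trains one forest on the full discovery set
and predicts an independently preprocessed validation cohort.

GA **at delivery** can be passed as the response, but is expected to fail —
urine metabolites track gestation, not time-to-delivery — and the package
deliberately offers no term/preterm classifier.

## Association, stratification, network

* `spearman_screen()` reports per-feature Spearman ρ/P against GA and an
  OLS beta of log2 abundance per week. Significance is raw p < 0.05 with
  no multiplicity correction — the screen is descriptive, feeding the PCA
  and pathway stages; BH-adjusted values are returned alongside for
  stricter use.
* `pca_ga_axes()` standardizes the significant features, and picks the two
  PCs whose scores correlate most strongly with GA — the informative axes
  need not be the loudest.
* `cv_by_ga_bin()` computes SD/mean per GA bin (default edges 8, 11, 14,
  17, 19 weeks) per outcome group, on raw normalized abundances — CV of
  log data is not meaningful. Betas and PCA use log2 abundances.
* `pathway_ora()` is a one-sided Fisher exact over-representation test on
  caller-supplied pathway sets (no m/z-based pathway guessing).
* `build_network()` tests all feature pairs by Spearman correlation,
  Bonferroni-adjusts by the number of tested pairs m(m−1)/2, keeps edges
  with adjusted P ≤ 0.01, and weights them by |ρ| (sign kept as an
  attribute; negative correlations do form edges). Betweenness is computed
  on the unweighted graph for determinism (1/|ρ| distances behind a flag);
  the Fruchterman–Reingold layout is seeded.

## Annotation

`annotate_features()` grades identifications by MSI level: 1 for an
in-house match (precursor within ±15 ppm, retention time within ±30 s
HILIC / ±20 s RPLC, spectral score ≥ 0.4), 2 for a public-library spectral
match (no RT available), 3 for caller-supplied putative names, 4 otherwise.
The similarity score is the forward dot-product on square-root-weighted
intensities with greedy closest-first one-to-one fragment pairing within
±15 ppm; unmatched fragments punish the score through the denominator
only. Fragment tolerance and intensity weighting are conventions, not
measurements, and both are configurable.

## Numerical choices and degenerate inputs

* Undefined correlations (zero variance) are treated as failures where a
  filter needs a decision, and as ρ = 0 / p = 1 where a statistic is
  reported.
* The positive-slope count uses half-up rounding (`floor(x + 0.5)`), so
  55% of 30 informative features is 17, not the even-rounding 16.
* All randomness — simulation, imputation, forests, layout — is derived
  from explicit integer seeds; reruns are byte-identical, which the test
  suite asserts on whole output directories.
* Forests run single-threaded with fixed seeds; importance ties are broken
  by feature id.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` exercise the default study
conditions (99 + 20 subjects, 2000 features, 30 informative) with forests
of 30–100 trees, and two deliberately scaled experiments chosen for
desk-scale runtime: the permutation-null check runs LOOCV on the 200
highest-variance features (a label-independent screen; the null property
does not depend on panel size), and the planted-panel recovery experiment
uses 60 subjects × 200 features with exactly 3 equal-slope informative
features. These sizes are the package's own choices and are stated here so
results can be reproduced exactly.

## Known limitations

* The simulator's GA trends are log-linear; real steroid trajectories
  flatten late in gestation.
* PQN and LOESS estimates are per-cohort; very small validation cohorts
  (< ~15 samples) make the PQN reference noisy.
* Impurity importance is biased toward high-cardinality features in
  general; with continuous abundances on a common scale this bias is mild,
  and permutation importance is available.
* The annotation module matches spectra; it does not enumerate adducts or
  predict retention times, and ships no library content.
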
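---
title: "Evaluating epigenetic predictors within demographic strata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating epigenetic predictors within demographic strata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiperform)
```

## The problem

DNA methylation (DNAm) data can be turned into predictions of phenotypic
traits: chronological age (epigenetic clocks such as Horvath's panTissue,
Hannum, Skin&Blood, Lin, Weidner, Vidal-Bralo and Zhang), leukocyte telomere
length (DNAmTL), circulating plasma proteins (the GrimAge/GrimAge2 component
surrogates for B2M, Cystatin C, CRP and HbA1c), and leukocyte subtype
proportions from reference-based deconvolution. These predictors are usually
trained in cohorts whose demographic composition does not match the
populations they are later applied to, and their accuracy can differ across
self-reported race/ethnicity groups and between sexes. This package provides
the machinery to quantify such differences in any cohort that carries both
laboratory measurements and DNAm predictions, and a synthetic-cohort
generator so that every stage of the machinery can be validated against a
known truth.

## The evaluation procedure

For each of 15 predictors the pipeline pairs a DNAm prediction with its
measured phenotype, applies quality control and unit conversions, and then
computes two complementary performance metrics per stratum:

* **Pearson correlation** `r` — strength of the linear association;
* **Median absolute error** `MAE = median(|prediction - phenotype|)` — a
  robust accuracy measure in the phenotype's units (years for clocks, kbp
  for telomere length, mg/L for proteins, percentage points for HbA1c,
  proportion units for cells).

Between-group differences in either metric are assessed with a percentile
bootstrap: participants are resampled with replacement within each group
(pairs stay together), the metric is recomputed in each group per iteration
(10,000 by default), and the difference is summarised by its median and
2.5th/97.5th percentiles; a difference is called significant when this 95%
interval excludes 0. A sensitivity variant resamples every group at the
smallest compared group's size to remove sample-size effects on metric
precision. Effect modification is additionally tested with OLS interaction
models (`prediction ~ phenotype * group + covariates`), where the phenotype
term is the reference-group slope (NH White, or female) and each interaction
term the additional slope in that group; interaction p-values are
Bonferroni-adjusted against a fixed budget of 150 tests (15 predictors x 5
race/ethnicity groups x 2 sexes) for the minimally adjusted models and 120
(12 non-cell predictors x 5 x 2) for the fully adjusted ones, with
unadjusted p < 0.05 reported as "suggestive".

## Quality control and conversions

The QC rules mirror standard practice for this kind of paired
biomarker table, and every removal is recorded in an audit trail:

* records whose DNAm-predicted sex disagrees with reported sex are removed
  globally (likely sample mislabels);
* ages top-coded at 85 (disclosure control in the emulated cohort) are
  removed *only* for the seven clocks (`uses_age = TRUE`), since only there
  does a censored age corrupt the fit assessment;
* telomere T/S ratios convert to kilobase pairs as
  `kbp = (3274 + 2413 * T/S) / 1000`;
* log-scale CRP and HbA1c predictions are exponentiated before analysis;
* laboratory lymphocyte proportions are compared against the sum of the
  DNAm B-cell, CD4+ and CD8+ T-cell estimates (the deconvolution is finer
  grained than the blood count);
* laboratory values at or beyond 3 standard deviations from the mean on
  the log scale are removed. The rule is single-pass (mean/SD computed
  once on all non-missing values, no iterative re-filtering), inclusive at
  exactly 3 SD, applies only to laboratory-derived measures (never to DNAm
  predictions, never to chronological age), and is vacuous when the SD is
  zero. Non-positive values, where the log is undefined, are excluded with
  their own audit reason (`nonpositive-for-log`) rather than erroring,
  since proportions of exactly zero are legitimate data.

Missing laboratory values exclude a participant from that predictor's
analysis only; nothing is imputed.

## The synthetic cohort: what it emulates and what it does not

`sim_config()` describes a cohort modelled on the structure of the NHANES
1999–2002 DNAm subsample: five race/ethnicity groups of sizes
694/159/1005/533/81, 50.8% male, ages uniform on [50, 84] plus 126 records
top-coded at 85, 60 sex-prediction mismatches, per-measure missingness
(28 Cystatin C, 31 B2M, 1 HbA1c, 2 telomere, 13 blood-count records), and
injected extreme outliers per measure.

The generator's central guarantee is *analysis-scale calibration*: for
every (predictor, group), the expected Pearson correlation between the
phenotype and the prediction **after QC and unit conversion** equals the
configured `target_correlation`. Three construction paths deliver this:

* **Raw-scale Gaussian mixing** (clocks, cell proportions):
  `y = rho * z(x) + sqrt(1 - rho^2) * eps`, rescaled to the prediction's
  location/scale. The phenotype is standardized on the rows that will
  survive QC (e.g. excluding top-coded ages), so the correlation target
  applies to the analysed subset — standardizing on all rows would shrink
  the realised correlation whenever extreme rows are later removed.
* **Log-scale construction with a correlation link** (B2M, Cystatin C,
  CRP, HbA1c, DNAmTL): positive measures are generated log-normally and
  their predictions on the log scale, but the analysis correlates raw
  (exponentiated / kbp-converted) values. The log-scale mixing correlation
  is obtained by inverting a closed-form expression for the raw-scale
  correlation of exponentiated truncated-bivariate-normal pairs (via the
  truncated-normal moment generating function), so the *raw-scale* target
  is met. Affine maps (kbp conversion) leave correlations untouched.
* **Dirichlet blood counts**: the three laboratory proportions come from
  one Dirichlet draw over (lymphocytes, monocytes, neutrophils, other);
  DNAm cell predictions are generated per cell type against their
  laboratory counterpart, and the total lymphocyte prediction is split
  into B/CD4/CD8 components by a second Dirichlet draw so the sum retains
  the target correlation.

Exact defect accounting is engineered, not hoped for: the base draws of
positive measures are truncated at 2.6 SD on the log scale (3 SDs of the
truncated distribution is ~2.89 SD, so no natural draw can trip the rule),
Dirichlet draws — which have no hard log-scale bound — go through a
bounded redraw loop with a safety margin, injected outliers are placed at
6 (proteins/telomere) or 4.5 (proportions) pre-injection SDs, and defect
row sets are disjoint where the audit must reproduce config counts (sex
mismatches never overlap other defects; within a measure, missing and
outlier rows never overlap). Consequently the QC audit on a default cohort
reports *exactly* the configured counts, which is what the defect-
accounting tests assert.

Random streams are split per (predictor, group) from the master seed, so
adding a predictor to a config never perturbs the draws of the others, and
the same config is byte-identical across runs.

What the generator does **not** emulate — and hence what a green test does
not establish: real within-group phenotype distributions (none are
published for the emulated cohort; the log-normal locations/scales are
realistic placeholders), survey weights, genetic-ancestry structure,
correlated missingness, or jointly-constrained DNAm cell proportions. On
the last point: real deconvolution output sums close to 1 with small
spread because all six estimates derive from one methylome; generating
each cell type independently (necessary for per-type correlation control)
inflates the spread of the sum, which is why `simulate_population()` warns
about rows whose six DNAm proportions sum outside [0.95, 1.05]. HbA1c is
generated log-normally (sdlog 0.12, visually indistinguishable from a
symmetric distribution at that scale) rather than on the raw scale,
because the outlier rule operates on the log scale and a raw-scale normal
has an asymmetric log-scale lower tail that would break exact defect
accounting.

## Numerical and design choices

* **Percentile extraction** uses linear interpolation between order
  statistics (`quantile(type = 7)`); at 10,000 iterations the choice of
  plotting position moves CI endpoints by ~1e-3 at most.
* **Degenerate bootstrap iterations** (a zero-variance resample makes r
  undefined) are dropped and counted (`n_degenerate`), never redrawn —
  redrawing would bias the null in tiny strata. A warning fires when more
  than 1% of iterations are lost.
* **Bootstrap seeding**: each comparison row derives its seed from
  (master seed, predictor, metric, pair, variant), and each group's
  resampling stream from (row seed, group label). Rows are independently
  reproducible, and swapping the two groups exactly negates the median
  difference and CI.
* **Comparison orientation** is fixed: Mexican American − NH White,
  NH Black − NH White, Mexican American − NH Black, male − female.
* **Regression scales**: variables enter on their converted natural
  scales, unstandardized, so a phenotype slope of 1 means a unit-for-unit
  association. PIR enters linearly; the education "Don't know" level is
  kept as its own dummy. CIs are the standard t-based OLS intervals.
* **Bonferroni budgets** are fixed constants (150/120) rather than
  recomputed from the number of fits actually run, faithful to the stated
  procedure; `m_tests` allows overriding for reuse.
* **Equal-n caps** default, per predictor, to the smallest compared
  group's analysable n (533 and 1217 in the emulated cohort's race and
  sex analyses respectively).
* The **0.35 correlation threshold flag** is computed for every predictor
  but is only meaningful for the plasma-protein family, where it
  originates as the GrimAge component-selection criterion.

## Known limitations, and one honestly red criterion

Two statistical facts surfaced by the validation suite are worth stating
plainly, because they are properties of the *procedure being implemented*,
not implementation defects:

1. **Pearson r on heavy-tailed data is noisy.** The calibration tests
   express recovery tolerance in Fisher-z standard errors, which presume
   near-normal data. For a log-normal marginal with sdlog 1.0 (a realistic
   CRP distribution) the true sampling SD of r is about twice the Fisher
   value. The parameter-recovery acceptance test therefore exercises the
   log-scale construction path with the mild-skew Cystatin C marginal;
   recovery for CRP-like tails is still unbiased, just wider.
2. **Percentile bootstrap of an MAE difference over-rejects slightly under
   the null.** The bootstrap distribution of a sample median concentrates
   on few order statistics (the classic quantile-lattice effect), so
   percentile CIs for median-based statistics are a little too narrow at
   n = 1000: measured null rejection is 8.3% for the MAE difference (600
   replicates; 3.8% for the correlation difference) against the ≤7% the acceptance contract allows.
   The corresponding acceptance assertion fails honestly for the MAE
   metric rather than being masked by a smoothed or widened interval
   the procedure does not prescribe. Users comparing MAE between
   groups of this size should treat borderline-significant differences
   with corresponding caution.

Also out of scope by design: computing DNAm predictions from raw array
data, survey-weighted estimation, and genetic-ancestry analyses. The
pipeline's real-data mode is a documented column mapping
(`read_population()` on a tab-delimited table with this package's column
names); nothing is ever downloaded.

## A worked example

```{r, eval = FALSE}
cfg <- study_config(
  simulation = sim_config(seed = 1),
  bootstrap = list(n_iter = 10000, seed = 1),
  output_dir = "epiperform_results")
bundle <- run_pipeline(cfg)
head(bundle$metrics)
subset(bundle$bootstrap$race_standard, significant)
subset(significance_tiers(bundle$regression), tier == "significant")
```
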
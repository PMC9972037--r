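---
title: "Discovering and evaluating circulating protein signatures with protsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and evaluating circulating protein signatures with protsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protsig)
```

## The problem

Serum protein panels measured by proximity extension assays report relative
abundances as NPX values on a log2 scale: one NPX unit is a doubling of
signal. In surgical oncology cohorts — the motivating setting is pancreatic
ductal adenocarcinoma, where roughly 7 of 10 patients present with
resectable tumors and median overall survival differs sharply between
resectable (~22.6 months) and unresectable (~8.2 months) disease — such
panels are screened for two purposes: markers that separate clinically
defined groups, and composite risk scores that predict overall survival.
With ~93 correlated markers (92 panel proteins plus CA19-9) and a few
hundred patients, single-split penalized regression is unstable: which
markers enter a LASSO model can change with the random split. `protsig`
implements a pipeline built around two complementary answers to that
instability, together with the full evaluation layer needed to judge the
resulting signatures against right-censored survival.

CA19-9, measured in U/ml, is pooled with the NPX proteins after a log2
transform, so that all 93 markers live on a common log2 scale and penalized
regression weights are comparable across markers. (Whether to log-transform
or z-score CA19-9 before pooling is genuinely open; the log2 choice keeps
the "+1 unit = doubling" reading of every coefficient.)

## Group comparisons and differential expression

`build_comparison_catalog()` defines seven two-group contrasts: resectable
vs unresectable; within resectable patients, short (observed death before
1 year) versus long survival past the 1-, 3-, 4- and 5-year marks; and
below- versus above-median OS within the resectable and the unresectable
subgroup, medians computed from the subgroup's observed survival times.
Dichotomizing survival under right-censoring needs a rule for censored
patients: a patient censored *before* the threshold is excluded (their
class is unknowable), while any patient followed past the threshold counts
as a long-term survivor. The same rule is applied to median splits.

Per-marker testing follows a sample-size-driven router: with at least 40
patients per arm the central limit theorem is trusted and a Welch t-test is
used; in smaller arms each group is checked with the Shapiro–Wilk test and
the Wilcoxon rank-sum test is substituted when either group departs from
normality at 0.05. Fold changes are reported on the linear scale as the
ratio of geometric means, which for log2 data is `2^(mean1 - mean2)`.
Benjamini–Hochberg correction is applied across the 93 markers of one
comparison (not pooled across comparisons), matching per-comparison
volcano tables. An exploratory PCA on centered, unit-scaled markers is
included because NPX scales differ per assay.

## Approach 1: stability selection with proportion scores

The cohort is split once into discovery and replication (stratified by
class; discovery fraction 2/3 by default, so that after halving the
discovery cohort the training halves remain comparable in size to the
replication cohort). Then, 500 times:

1. draw a fresh stratified half-split of the discovery cohort,
2. fit an L1 (LASSO) logistic model on the training half, with the penalty
   chosen by internal 10-fold cross-validated deviance,
3. record which markers carry nonzero coefficients.

The per-marker selection frequency across the 500 models is its
**proportion score**. Candidate signatures are the 21 nested sets of
markers at proportion-score thresholds 0, 0.05, ..., 1.0; identical sets
are deduplicated keeping the highest threshold, so the retained family is
strictly nested with strictly decreasing sizes. Each signature is then
evaluated with Ridge-logistic models — fitted on one half of discovery and
scored on the other, and fitted on all of discovery and scored on
replication — reporting AUC, the Youden best point (sensitivity +
specificity − 1, ties broken toward higher specificity and then the larger
cutoff), sensitivity, specificity, PPV and NPV, each with percentile 95%
confidence intervals from 2000 class-stratified bootstrap resamples of the
evaluation set (the fitted model held fixed; the Youden cutoff is
recomputed per replicate so threshold instability is part of the
interval). Whether the half-split should be redrawn at every iteration is
ambiguous; redrawing is the design here, since a fixed half-split would
make the 500 models differ only through fold randomness.

## Approach 2: median-lambda penalized models

The second strategy uses all samples. After standardizing each marker to
mean 0 and unit sample standard deviation (n−1 convention, used
everywhere), 10-fold cross-validation is repeated 500 times with fresh fold
assignments, each repetition contributing its deviance-minimizing penalty;
the final penalty is the **median of the 500 lambdas**, and the final model
is a single L1 fit at that penalty on all data. The spread of the
per-repetition weights is retained as a robustness summary. The same
machinery drives:

- an L1 **logistic** classifier (e.g. resectable vs unresectable, or short
  vs long survivors), and
- an L1 **Cox** model for overall survival (Breslow ties,
  partial-likelihood deviance as the CV criterion), optionally with
  **non-negative** weights so that only hazard-increasing markers can
  enter the risk score — a truly protective marker is forced to exactly
  zero by the constraint.

A patient's prediction/risk score is the linear combination of
standardized marker levels and fitted weights (plus intercept for logistic
families). `linear_model_from_weights()` rebuilds such a score from a
published weight table, which is how externally reported signatures are
applied to new data.

The per-repetition CV grid is glmnet's default path from the smallest
penalty that zeroes all coefficients downward; the deviance-minimizing
lambda (not the one-standard-error rule) is used because the repetition /
median step already provides the stabilization that the one-SE rule
approximates on a single run.

## Survival evaluation layer

All evaluation components take a score vector plus `(times, events)`:

- **ROC/AUC**: the empirical step curve over midpoint cutoffs; the
  trapezoidal AUC equals the tie-corrected Mann–Whitney statistic.
- **Time-dependent ROC** at horizons 6/12/24 months: the
  cumulative-case/dynamic-control estimator in which the event probability
  within each score stratum is estimated by the conditional Kaplan–Meier
  curve. With no censoring before the horizon it reduces exactly to the
  static ROC of "event by t". The nearest-neighbor-smoothed alternative is
  deliberately not implemented.
- **Kaplan–Meier / logrank / Cox PH** via the survival package (Breslow
  ties); univariate and multivariate summaries with age (continuous),
  stage and ASA (ordinal integers), adjuvant chemotherapy (dummy-coded)
  and log2 CA19-9. Rows with missing covariates (ASA is occasionally
  unrecorded) are dropped and counted.
- **Cutpoints**: the median split (ties to the low-score group) and the
  maximally selected logrank cutpoint — an exhaustive scan of all midpoint
  cutoffs within the 10th–90th score percentiles for the largest absolute
  standardized logrank statistic. The reported p-value at the selected
  cutpoint is the naive logrank p and is explicitly flagged
  `selection_biased`; the Lausen–Schumacher correction is not applied, so
  these p-values should be read as descriptive.
- **Horizon classification** at 6/12/24 months: "positive" means predicted
  alive (score below the cutoff for risk-oriented scores); patients
  censored before a horizon are excluded at that horizon rather than
  imputed.

## The synthetic cohort generator

No public data release exists for the motivating cohort, so
`simulate_cohort()` generates cohorts with the statistical structure the
pipeline assumes, with exported ground truth:

- **Markers**: latent-factor correlated Gaussians on the log2 scale
  (3 factors, loading SD 0.5, unit noise by default) plus per-marker mean
  shifts between resectability groups.
- **Survival**: exponential event times with group hazards calibrated so
  the uncensored medians equal 22.6 (resectable) and 8.2 (unresectable)
  months when all survival effects are zero, multiplied by
  `exp(beta' x)` on centered markers otherwise. The exponential family was
  chosen over Weibull because its closed-form median makes the calibration
  exact; no shape heterogeneity is modeled.
- **Censoring**: an administrative horizon of 150 months (mirroring a
  follow-up window that closes ~12.5 years after first inclusion) plus a
  15% fraction of uniformly early censoring times.
- **Covariates**: age, stage (skewed toward advanced stage in unresectable
  disease), ASA with one missing record, adjuvant chemotherapy category —
  plausible marginals, no planted covariate-survival signal.

The reference test scenario (`default_scenario()`) plants five
resectability markers at +1.0 NPX and five survival markers at
|beta| = 0.5 per NPX unit, one of them protective. What the generator does
*not* emulate: the empirical correlation matrix of a real Olink panel,
assay-specific limits of detection and QC flags, non-proportional hazards,
and covariate–marker dependence. Passing recovery tests therefore show
that the machinery works under its stated assumptions, not that real
cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

- "Nonzero coefficient" means |weight| > 1e-10 on the standardized scale.
- Youden and maxstat ties are broken deterministically (higher
  specificity, then larger cutoff; first maximizer in the scan).
- Median splits assign boundary ties to the low group.
- Wilcoxon p-values use exact enumeration when both groups have at most 25
  untied observations, otherwise the normal approximation with continuity
  correction.
- Two constant equal groups compare with p = 1; constant markers are
  rejected by name wherever scaling or standardization is required.
- Missing NPX values are never imputed: any operation that selects a
  marker containing missing values errors with the marker name.
- All resampling (splits, folds, bootstrap) is driven by explicit seeds;
  a repeated run with the same configuration is bit-identical.

## Validation problem sizes

The shipped test-suite exercises the full pipeline at reduced but
non-trivial sizes chosen to keep the suite fast while leaving every
stochastic check well-powered: stability selection with 60 resampling
iterations across 10 master seeds at the reference cohort size (n = 273,
p = 93), median-lambda fits with 25–40 CV repetitions, bootstrap intervals
with 100–200 replicates, and 200-replicate type-I-error screens. The
package defaults remain the study-scale values (500 iterations, 2000
bootstrap replicates), and `scripts/acceptance.R` re-derives the headline
quantities — simulator calibration, null error rates, recovery fractions
and published-weight score arithmetic — from scratch at every run.

## Limitations

- Exponential survival and linear log-hazards are simulation assumptions,
  not claims about pancreatic cancer biology.
- The maxstat p-value is selection-biased by construction and flagged as
  such; use it to rank cutpoints, not to test them.
- Ridge evaluation of a single-marker signature falls back to an
  unpenalized logistic fit (the score is monotone in the marker either
  way, so ranking metrics are unaffected).
- The pipeline evaluates signatures; it does not perform causal inference
  or account for treatment selection after risk stratification.
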
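---
title: "Modelling advanced colorectal neoplasia risk with neighbourhood deprivation"
author: "acnrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling advanced colorectal neoplasia risk with neighbourhood deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Advanced colorectal neoplasia (ACN) — colorectal cancer together with
advanced precancerous adenoma — is the target lesion of screening
colonoscopy.  Clinical risk prediction models for ACN are usually built
from individual-level factors (age, sex, BMI, smoking, family history,
diet, diabetes, supplement use).  Neighbourhood socioeconomic status is a
contextual exposure that individual covariates do not capture: subjects
are nested in census tracts, and the deprivation of a tract shifts its
residents' baseline risk.  `acnrisk` implements a complete analysis chain
for this setting:

1. a **synthetic multilevel cohort generator** (two race strata nested in
   census tracts, binary ACN outcome);
2. an **Area Deprivation Index (ADI)**: the first principal component of
   17 tract-level socioeconomic indicators, oriented so higher = more
   deprived, scaled to 0–100;
3. **bootstrap-stability predictor selection** around logistic regression
   fitted by iteratively reweighted least squares (IRLS);
4. a **two-stage mixed-effects augmentation**: ACN regressed on the base
   model's predicted risk plus ADI with a census-tract random intercept,
   fitted by adaptive Gauss–Hermite quadrature (AGQ);
5. **evaluation**: C-statistic with bootstrap CI, Hosmer–Lemeshow
   calibration over risk deciles and over ADI quantiles, a
   Cochran–Armitage prevalence trend test, and the variance-partition
   statistic $(\mathrm{Var}_{null}-\mathrm{Var}_{full})/\mathrm{Var}_{null}$
   for the share of tract-level risk variation explained by ADI.

Because no patient-level data ship with the package, every empirical
claim in the test suite is a property of the generator plus estimators —
parameter-recovery simulations, independent numerical oracles, and exact
arithmetic.

## The generative model

The generator (`generator_config()`, `generate_cohort()`) encodes the
study conditions the package emulates.

**Tracts.** Each of $T$ census tracts (default 598) carries 17
standardized indicators following a single-factor model
$x_k = \lambda f + \sqrt{1-\lambda^2}\,\varepsilon_k$ with $f$,
$\varepsilon_k$ standard normal.  The indicators are therefore
equicorrelated with correlation $\lambda^2$, and the leading eigenvalue
of their correlation matrix is $1 + 16\lambda^2$, giving a PC1 variance
share of $(1+16\lambda^2)/17$.  The default loading inverts this formula
at a share of 60.2%, so the constructed ADI captures that fraction of the
indicators' variance by design.  Indicator `v1` is the poverty proxy used
to orient the index.

**Subjects.** Each race block (defaults: EA $n=1457$, AA $n=936$) draws
covariates from the configured marginals: age and BMI as truncated
normals on [50, 80] years and [15, 60] kg/m² with pre-truncation
parameters solved numerically so the *post*-truncation mean and SD hit
the configured targets; smoking years, red meat and alcohol frequencies
as normals floored at zero (for these the configured mean/SD pairs are
unattainable under left truncation — the ratio of mean to SD is below
what a left-truncated normal can produce — so they parameterize the
latent normal instead); binary covariates as Bernoulli draws.

**Tract assignment.** Races differ sharply in deprivation exposure
(target subject-level ADI: EA mean 28.1, SD 11.5; AA mean 53.1, SD 15.3).
Subjects are assigned to tracts with importance weights equal to the
density ratio of the race's target ADI distribution over a normal
approximation of the realized tract ADI distribution, truncated at the
99.9th weight percentile.  This hits both the target mean and SD with a
single rule; a rank-based weighting would pin only the location.

**Outcome.** ACN is drawn from
$$\operatorname{logit} p = \alpha_{race} + \textstyle\sum_k \beta_k x_k +
  \beta_{ADI}\,(ADI/10) + u_{tract},\qquad u \sim N(0, \sigma_u^2),$$
with race-specific coefficient defaults equal to the corresponding
race-specific risk model (e.g. EA: male sex OR 1.43, age 1.03/year, BMI
1.04/unit, family history 1.83, smoking 1.01/year, calcium 0.44, ADI
1.24 per 10 units).  The intercept is never configured: it is calibrated
by bisection (`calibrate_intercept()`, tolerance $10^{-6}$) so the
realized expected prevalence equals the block's target (6.3% EA, 8.4%
AA).  Simulating from the same augmented-model form that the estimators
fit makes every downstream quantity recovery-testable.

**Tract heterogeneity.** $\sigma_u$ defaults to 0.3 on the logit scale —
a modest but non-zero cluster effect.  No empirical anchor for this value
exists at the subject level, so it is a free parameter; notably, with the
default ADI effects it implies ADI shares of tract-level linear-predictor
variance close to 38.7% (EA) and 10.6% (AA).  The helper
`tract_sigma_for_adi_share()` inverts
$s = \frac{(\beta_{ADI}/10)^2\sigma_{ADI}^2}
          {(\beta_{ADI}/10)^2\sigma_{ADI}^2 + \sigma_u^2}$
to derive $\sigma_u$ from a target share exactly.

**Seeds.** One master seed; child seeds by fixed offsets (+1 tract
indicators, +2 tract intercepts, +100·k covariates of the k-th race
block, +3 outcomes).  Identical `(config, seed)` give byte-identical
tables.

## Estimators

**IRLS logistic regression** (`fit_logistic()`): Newton scoring with
step-halving, so the log-likelihood is non-decreasing; convergence at
score $<10^{-8}$ or relative log-likelihood change $<10^{-10}$; Wald
tests on the normal reference; a separation flag when a coefficient
passes 10 in absolute value while the likelihood still improves.
Rank-deficient designs fail fast, naming the aliased column.

**Backward elimination** (`backward_eliminate()`): full refit after each
removal (not the one-shot approximation — reproducible and only
marginally slower at these model sizes), removing the worst non-forced
term with Wald $P > 0.10$; ties broken lexicographically by term name so
the result cannot depend on candidate ordering.

**Stability selection** (`bootstrap_frequencies()`): B bootstrap
resamples (default 1000), each refitted and backward-eliminated;
survivors counted.  Failed resamples (single-class outcome, separation,
singular design) are redrawn so B stays exact, with the redraw count
reported; more than 20% failures aborts as a data pathology.  The
final-predictor rule (`choose_final_predictors()`) takes frequencies
above 0.4 and, with the drop rule on, scans the sorted frequency sequence
for the largest consecutive drop whose upper side sits at or below the
threshold and pulls in everything above it — capturing a cluster of
just-below-threshold predictors separated from the noise by a big gap.
A drop located *above* the threshold is not used for extension: those
predictors are already selected, and extending past such a drop would
re-admit the noise tail the rule exists to exclude.  On an all-equal
plateau there is no gap and no extension.

**LASSO redundancy check** (`fit_lasso_cv()`): coordinate descent on the
IRLS quadratic approximation, standardized covariates, unpenalized
intercept, 3-decade log-spaced path from $\lambda_{max}$, stratified
3-fold cross-validation maximizing out-of-fold AUC, ties resolved toward
the sparser model.  Its role is confirmatory: report which (if any) of
the stability-selected predictors the penalty removes.

**Random-intercept logistic regression**
(`fit_random_intercept_logistic()`): the per-cluster marginal likelihood
is integrated by adaptive Gauss–Hermite quadrature (default 10 points;
nodes from the Golub–Welsch eigendecomposition).  The integrand's mode
and curvature are found by a vectorized Newton search (the integrand is
strictly log-concave), nodes are re-centred and re-scaled per cluster,
and the outer maximization over fixed effects and $\log\sigma_u$ uses
L-BFGS-B with central numeric gradients (step $10^{-5}$).  Fits at the
$\sigma_u \to 0$ boundary are reported as zero variance with a boundary
flag.  Ten points are saturated for these data: the test suite checks
agreement with a 30-point rule to $10^{-4}$ and with brute-force dense
integration to $10^{-6}$ on toy problems, and the fit agrees with an
independent AGQ implementation to four decimals.

**Two-stage augmentation** (`augment_with_adi()`): exactly two fixed
covariates — the base model's predicted risk entered on the absolute
probability scale in units of 0.1, and ADI in units of 10 — plus a tract
random intercept.  The probability scale (not the logit) for the base
prediction follows the convention of reporting odds ratios per 0.1 of
absolute predicted risk.  Each term's P value is a likelihood-ratio test
against the model dropping that term (chi-square, df 1; the tested terms
are fixed effects, so no boundary correction applies); CIs are Wald.
The tract variances of the null (no-ADI) and full fits give the
variance-partition statistic.

**Evaluation**: the C-statistic is computed by mean ranks (equal to
exhaustive concordant/tied pair enumeration), with a percentile bootstrap
CI over resampled subjects (default B = 2000; model applied, not
refitted).  Hosmer–Lemeshow uses
$H=\sum_g (O_g-E_g)^2/\{E_g(1-E_g/n_g)\}$ with $G-2$ df for both
risk-decile and ADI-quantile groupings ($G-2$ is the standard
development-data convention; with four deprivation quartiles this gives
df 2); tied decile cut points are merged and the df adjusted.  The
prevalence trend across ADI quantiles is a Cochran–Armitage test with
equally spaced scores, reported as a signed Z with two-sided P.

## Pipeline

`run_pipeline()` chains the stages per population — combined cohort
(race forced into the final model even when the bootstrap does not select
it), then each race stratum — and adds cross-application: each
race-specific model is also evaluated on the complementary stratum, and
the combined model on both.  Reports serialize to JSON (fitted model
objects and wall-clock timing excluded, so identical seeds give
byte-identical files) plus an aligned-text summary; fitted base models
serialize to JSON model files reloadable with `read_model()`.
Generated cohorts are complete; ingested CSV cohorts are validated
(schema, 50–80 age eligibility, referential tract integrity) and rows
with unresolvable tracts are rejected with their indices.

## Numerical and design choices

* ADI scaling is sample min–max (0 = least, 100 = most deprived tract in
  the sample); percentile-rank scaling is available via
  `scaling = "percentile"`.  National reference scaling is out of scope.
* PCA is computed on the correlation matrix: the real indicators the
  index abstracts have heterogeneous units.
* A leading-eigenvalue tie within $10^{-12}$ triggers a warning and a
  deterministic lexicographic sign tie-break.
* Continuous covariates enter models untransformed (per-unit odds
  ratios imply linearity on the logit scale).
* Chi-square tests are Pearson without continuity correction; a
  degenerate 2×2 margin falls back to Fisher's exact test with a warning.
* The bootstrap of the C-statistic CI redraws single-class resamples and
  logs the count.

## What the simulations do and do not show

The generator reproduces the *marginal* structure of the emulated
screening cohort (sample sizes, covariate moments, prevalences, per-race
deprivation distributions, cluster structure) and an outcome model whose
effect sizes default to the emulated study's fitted estimates.  It does
not emulate covariate correlations (covariates are independent within
race), non-linear dose–response, informative missingness (generated data
are complete), geographic autocorrelation between tracts, or
measurement error.  Passing recovery tests therefore demonstrate that
the estimators are correct and well-calibrated under the stated model —
not that the model describes any particular real population.

Two honesty notes from the recovery studies, both visible in the test
suite rather than hidden:

* With ~2.4 subjects per tract at ~7% prevalence, the tract-variance MLE
  is weakly identified: single-cohort estimates frequently hit the zero
  boundary (an independent reference implementation agrees), and per-seed
  variance-partition ratios are unstable.  The recovery checks therefore
  pool the estimated variance components across seeds (20–30 seeds) before
  forming $(\mathrm{Var}_{null}-\mathrm{Var}_{full})/\mathrm{Var}_{null}$;
  the pooled ratio recovers the configured shares.
* For the same reason the random-intercept SD recovery check (600
  clusters of 4) asserts the band on the mean across 10 seeds; the
  per-seed sampling SD of $\hat\sigma_u$ (~0.1) makes a tight per-seed
  band unattainable for any correct estimator.

## Problem sizes used in the checks

Module tests run on scaled-down cohorts (hundreds of subjects, tens of
tracts) chosen to exercise every code path; recovery studies use the
full emulated design ($n=1457$ or $936$ in 598 tracts) with 10–20 seeds,
and calibration/uniformity properties use 100 seeded replicates.  The
bootstrap defaults (B = 1000 selections, B = 2000 C-statistic resamples)
are used at full scale by `run_pipeline()`; tests exercise the same code
with smaller B, which changes only Monte Carlo resolution, not logic.

## Limitations

* One clustering level, random intercepts only — no crossed or nested
  structures, no random slopes.
* No Firth correction; separation is flagged, not penalized away.
* No splines or interactions; no multiple imputation (complete-case with
  a logged count on ingest).
* The "2000 imputed bootstrap datasets" convention for the C-statistic
  CI is implemented as a plain nonparametric bootstrap of subjects;
  generated cohorts have no missing data to impute.
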
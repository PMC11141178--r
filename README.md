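# acnrisk

Race-stratified risk prediction of advanced colorectal neoplasia (ACN)
with neighbourhood socioeconomic deprivation.

## What this package is for

ACN — colorectal cancer plus advanced precancerous adenoma — is the
target lesion of screening colonoscopy. Risk prediction models built
from individual-level factors alone ignore a contextual exposure:
subjects live in census tracts, and neighbourhood deprivation shifts
tract-level baseline risk. `acnrisk` is for biostatisticians and
epidemiologists who want to

* build parsimonious logistic risk models with **bootstrap stability
  selection** (candidate screening at univariate P < 0.10, fast backward
  elimination at Wald P > 0.10 inside each of B bootstrap resamples,
  selection-frequency rule with a frequency-drop extension, LASSO
  redundancy check by 3-fold CV on AUC);
* construct an **Area Deprivation Index (ADI)** as the first principal
  component of 17 tract-level socioeconomic indicators, oriented so the
  poverty proxy loads positively and scaled to 0–100;
* quantify what deprivation adds to an existing risk model through a
  **two-stage mixed-effects augmentation**

  ```
  logit P(ACN) = a + b1 * (predicted risk / 0.1) + b2 * (ADI / 10) + u_tract,
  u_tract ~ N(0, s^2)
  ```

  fitted by 10-point adaptive Gauss–Hermite quadrature, with
  likelihood-ratio tests, odds ratios per 0.1 predicted risk and per 10
  ADI units, and the variance partition
  `(Var_null − Var_full) / Var_null` — the share of census-tract-level
  risk variation explained by ADI;
* evaluate models by C-statistic (bootstrap CI over 2000 resamples),
  Hosmer–Lemeshow calibration across risk deciles and across ADI
  quantiles, and a Cochran–Armitage prevalence trend test.

Because screening cohorts of this kind are not public, the package
ships a **synthetic multilevel cohort generator** whose defaults emulate
the study conditions it models: 598 census tracts, two race strata
(European-American n = 1457, African-American n = 936) with race-specific
covariate distributions, deprivation exposure (EA ADI mean 28.1 SD 11.5;
AA mean 53.1 SD 15.3), outcome prevalences (6.3% / 8.4%) and
race-specific effect sizes. All estimators are validated by
parameter-recovery simulation against this generator plus independent
numerical oracles.

## Worked example

```r
library(acnrisk)

## EA-like cohort: 1457 subjects in 598 tracts, race-specific effects
sim <- generate_cohort(ea_generator_config(seed = 11))
pd  <- sim$cohort
pd$sex_male <- as.numeric(pd$sex == "male")

## 1. stability selection over the candidate risk factors
vars <- c("sex_male", "age", "bmi", "family_history_fdr", "smoking_years",
          "diabetes", "calcium_use", "red_meat_per_week", "alcohol_per_week")
forced <- c("sex_male", "bmi", "alcohol_per_week", "smoking_years",
            "family_history_fdr", "red_meat_per_week")
cand <- screen_candidates(pd, variables = vars, forced = forced)
stab <- bootstrap_frequencies(pd, candidates = cand, B = 200, seed = 11)
print(stab)
#> Bootstrap stability selection: B = 200, alpha = 0.10
#>        calcium_use family_history_fdr                age                bmi 
#>              0.980              0.950              0.635              0.530 
#>   alcohol_per_week      smoking_years           sex_male  red_meat_per_week 
#>              0.390              0.305              0.280              0.240 
choose_final_predictors(stab)
#> [1] "age"                "bmi"                "family_history_fdr"
#> [4] "calcium_use"        "alcohol_per_week"

## 2. the race-specific risk model and its discrimination
fit <- fit_logistic(acn ~ sex_male + age + bmi + family_history_fdr +
                      smoking_years + calcium_use, pd)
ci <- c_statistic_ci(fit, pd, B = 2000, seed = 11)
round(c(C = ci$point, lo = ci$lower, hi = ci$upper), 3)
#>     C    lo    hi
#> 0.650 0.596 0.702

## 3. what does deprivation add?
pred <- predict(fit, pd)
aug <- augment_with_adi(pred, pd$adi, pd$acn, pd$tract_id)
print(aug)
#> Mixed-effects augmentation of base risk with ADI
#>   base predicted risk (per 0.1) OR 3.34 (95% CI 2.23 to 4.99), LRT P = 1.63e-08
#>   ADI (per 10 units)           OR 1.24 (95% CI 1.03 to 1.49), LRT P = 0.0223
#>   tract variance: null 0.3885, full 0.2858; ADI share 26.4%
```

The four strongest selection frequencies are true risk factors of the
generating model (calcium use, family history, age, BMI), while the
noise-level candidates sit far below the 0.4 rule; the drop rule pulls
in one borderline term (alcohol at 0.390) sitting just above a large
frequency gap. The C-statistic of 0.65 reflects the modest
discrimination individual risk factors achieve at 6% prevalence. In the
augmentation, the estimated ADI odds ratio per 10 units (1.24) lands on
the generator's true value, the likelihood-ratio test detects it
(P = 0.022), and ADI explains 26% of this realization's tract-level
variance — a quantity that is weakly identified per cohort, which is why
the acceptance script pools variance components across seeds.

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/acn-pipeline.R` with subcommands `simulate`, `adi`,
`evaluate` and `run` (full per-population pipeline: selection, fitting,
cross-race evaluation, ADI augmentation, calibration-by-deprivation
report). See the methods vignette (`vignettes/acn-risk-modelling.Rmd`)
for the model, its assumptions, and every numerical design choice.
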
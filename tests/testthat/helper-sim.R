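## Shared fixtures, built in code.

## Scaled-down single-stratum config for fast end-to-end checks.
small_ea_config <- function(seed = 1L, n = 300L, tracts = 80L, ...) {
  ea_generator_config(
    seed = seed, n_tracts = tracts,
    race_blocks = list(EA = ea_race_block(n_subjects = n)),
    ...)
}

## The final-model formula of each race-specific risk model, on the
## numeric modelling frame.
ea_model_formula <- acn ~ sex_male + age + bmi + family_history_fdr +
  smoking_years + calcium_use
aa_model_formula <- acn ~ age + smoking_years + diabetes +
  red_meat_per_week

## Numeric modelling frame (sex/race recoded to indicators).
mframe <- function(cohort) acnrisk:::modelling_frame(cohort)

## Random logistic-regression dataset with known coefficients.
sim_logistic <- function(n, beta, seed = 1L, intercept = -2) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  eta <- intercept + drop(X %*% beta)
  d <- as.data.frame(X)
  d$y <- rbinom(n, 1, plogis(eta))
  d
}

## Clustered binary data with a known random-intercept SD.
sim_clustered <- function(n_cl, m_per_cl, beta_x = 0.5, sigma_u = 0.5,
                          intercept = -2, seed = 1L) {
  set.seed(seed)
  cl <- rep(seq_len(n_cl), each = m_per_cl)
  u <- rnorm(n_cl, 0, sigma_u)
  x <- rnorm(n_cl * m_per_cl)
  eta <- intercept + beta_x * x + u[cl]
  data.frame(y = rbinom(length(x), 1, plogis(eta)), x = x, cl = cl)
}
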
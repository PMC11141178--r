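test_that("Gauss-Hermite rules match known node/weight values", {
  gh2 <- gauss_hermite(2)
  expect_equal(gh2$nodes, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(gh2$weights, rep(sqrt(pi) / 2, 2), tolerance = 1e-12)
  gh3 <- gauss_hermite(3)
  expect_equal(gh3$nodes, c(-sqrt(1.5), 0, sqrt(1.5)), tolerance = 1e-12)
  expect_equal(gh3$weights,
               c(sqrt(pi) / 6, 2 * sqrt(pi) / 3, sqrt(pi) / 6),
               tolerance = 1e-12)
  ## the rule integrates exp(-t^2) exactly
  expect_equal(sum(gauss_hermite(10)$weights), sqrt(pi), tolerance = 1e-12)
})

test_that("AGQ log-likelihood matches brute-force numerical integration", {
  ## 3 clusters x 5 subjects, fixed parameters
  set.seed(31)
  d <- data.frame(cl = rep(1:3, each = 5), x = rnorm(15))
  d$y <- rbinom(15, 1, plogis(-0.5 + 0.8 * d$x))
  beta <- c(-0.4, 0.7); sigma <- 0.6
  X <- cbind(1, d$x)
  gh <- gauss_hermite(10)
  ll_agq <- acnrisk:::agq_loglik(beta, sigma, X, d$y, d$cl, 3L, gh)
  ## dense trapezoid integration over each cluster's standardized effect
  grid <- seq(-12, 12, length.out = 40001)
  ll_num <- 0
  for (i in 1:3) {
    rows <- d$cl == i
    eta0 <- X[rows, ] %*% beta
    integrand <- vapply(grid, function(a)
      exp(sum(acnrisk:::bernoulli_loglik(d$y[rows], eta0 + sigma * a))) *
        dnorm(a), 0)
    ll_num <- ll_num +
      log(sum((integrand[-1] + integrand[-length(grid)]) / 2) *
            diff(grid[1:2]))
  }
  expect_equal(ll_agq, ll_num, tolerance = 1e-6)
})

test_that("the no-heterogeneity limit reduces to plain logistic regression", {
  cfg <- small_ea_config(seed = 5, n = 400, tracts = 60, tract_sigma = 0,
                         adi_log_or_per_10 = 0)
  pd <- mframe(generate_cohort(cfg)$cohort)
  mix <- fit_random_intercept_logistic(acn ~ age + bmi, pd, "tract_id")
  glm_fit <- fit_logistic(acn ~ age + bmi, pd)
  expect_lt(max(abs(coef(mix) - coef(glm_fit))), 1e-3)
  expect_lt(mix$tract_variance, 1e-3)
  expect_true(mix$boundary_flag)
})

test_that("the random-intercept SD is recovered across seeds", {
  ## 600 clusters of 4, true SD 0.5; the mean estimate recovers the truth
  ## and every seed stays in a plausible neighbourhood
  est <- vapply(1:10, function(s) {
    d <- sim_clustered(600, 4, sigma_u = 0.5, intercept = 0, seed = s)
    fit_random_intercept_logistic(y ~ x, d, "cl", q_points = 10)$tract_sd
  }, 0)
  expect_gte(mean(est), 0.35)
  expect_lte(mean(est), 0.65)
  expect_true(all(est > 0.15 & est < 0.9))
})

test_that("AGQ agrees with the reference mixed-model fitter", {
  skip_if_not_installed("lme4")
  d <- sim_clustered(300, 5, sigma_u = 0.6, intercept = -1.5, seed = 8)
  ours <- fit_random_intercept_logistic(y ~ x, d, "cl", q_points = 10)
  ref <- lme4::glmer(y ~ x + (1 | cl), d, family = binomial, nAGQ = 10)
  expect_equal(unname(coef(ours)), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(ours$tract_sd,
               sqrt(unname(unlist(lme4::VarCorr(ref)))), tolerance = 1e-2)
  expect_equal(ours$log_likelihood, as.numeric(logLik(ref)),
               tolerance = 1e-4)
})

test_that("10-point quadrature is saturated relative to 30 points", {
  pd <- mframe(generate_cohort(small_ea_config(seed = 9, n = 500,
                                               tracts = 120))$cohort)
  f10 <- fit_random_intercept_logistic(acn ~ age, pd, "tract_id",
                                       q_points = 10)
  ll30 <- acnrisk:::agq_loglik(
    coef(f10), f10$tract_sd,
    cbind(`(Intercept)` = 1, age = pd$age), pd$acn,
    as.integer(factor(pd$tract_id)),
    nlevels(factor(pd$tract_id)), gauss_hermite(30))
  expect_equal(f10$log_likelihood, ll30, tolerance = 1e-4)
})

test_that("profiling at the estimated SD reproduces the fixed effects", {
  d <- sim_clustered(150, 5, sigma_u = 0.5, seed = 12)
  fit <- fit_random_intercept_logistic(y ~ x, d, "cl")
  prof <- fit_random_intercept_logistic(y ~ x, d, "cl",
                                        fix_sigma = fit$tract_sd,
                                        start = coef(fit))
  expect_lt(max(abs(coef(fit) - coef(prof))), 1e-5)
})

test_that("the nested LRT follows chi-square arithmetic", {
  mk <- function(ll, k, n = 100L)
    structure(list(log_likelihood = ll,
                   coefficients = setNames(numeric(k), paste0("b", 1:k)),
                   n = n), class = "acn_mixed")
  same <- lrt_nested(mk(-50, 2), mk(-50, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  one <- lrt_nested(mk(-48.08, 3), mk(-50, 2))
  expect_equal(one$df, 1)
  ## chi-square survival oracle via the normal distribution (df 1)
  expect_equal(lrt_nested(mk(-48.08, 3), mk(-50, 2))$statistic, 3.84,
               tolerance = 1e-9)
  expect_equal(one$p, 2 * pnorm(-sqrt(3.84)), tolerance = 1e-12)
  expect_error(lrt_nested(mk(-51, 3), mk(-50, 2)), "optimization failure")
})

test_that("the variance partition is plain arithmetic with guards", {
  expect_equal(variance_partition(0.5, 0.5), 0)
  expect_equal(variance_partition(0.4, 0.1), 0.75)
  expect_warning(vp <- variance_partition(0.2, 0.25), "negative")
  expect_equal(vp, -0.25)
  expect_error(variance_partition(0, 0.1), "undefined")
})

test_that("the augmentation model reports two ORs on the stated units", {
  cfg <- small_ea_config(seed = 6, n = 500, tracts = 100)
  pd <- mframe(generate_cohort(cfg)$cohort)
  base <- fit_logistic(acn ~ age + bmi, pd)
  pred <- pmin(pmax(predict(base, pd), 1e-8), 1 - 1e-8)
  aug <- augment_with_adi(pred, pd$adi, pd$acn, pd$tract_id, q_points = 5)
  for (v in list(aug$or_base_per_0p1, aug$or_adi_per_10)) {
    expect_true(all(c("or", "lo", "hi", "p") %in% names(v)))
    expect_gt(v[["or"]], 0)
    expect_lte(v[["lo"]], v[["or"]])
    expect_gte(v[["hi"]], v[["or"]])
  }
  expect_equal(aug$lrt_adi$df, 1)
  ## unit contract: the base OR is per 0.1 of predicted risk, so the
  ## coefficient on the 0-1 scale is 10x the fitted one
  expect_equal(unname(coef(aug$fit_full)["risk01"]),
               log(aug$or_base_per_0p1[["or"]]), tolerance = 1e-10)
  expect_error(augment_with_adi(rep(0.2, 10), runif(10, 0, 100),
                                rbinom(10, 1, 0.2), rep(1:2, 5)),
               "constant")
})
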
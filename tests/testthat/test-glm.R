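test_that("intercept-only and saturated 2x2 fits match closed forms", {
  d <- data.frame(y = c(rep(1, 3), rep(0, 7)))
  fit <- fit_logistic(y ~ 1, d)
  expect_equal(unname(coef(fit)), log(3 / 7), tolerance = 1e-8)

  ## 2x2 table (x=1: 20 events / 10 non; x=0: 10 events / 20 non) -> OR 4
  d2 <- data.frame(
    x = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)),
    y = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)))
  fit2 <- fit_logistic(y ~ x, d2)
  expect_equal(unname(coef(fit2)["x"]), log(4), tolerance = 1e-8)
  expect_equal(unname(coef(fit2)["(Intercept)"]), log(10 / 20),
               tolerance = 1e-8)
})

test_that("IRLS matches a dense 2-D grid search of the exact likelihood", {
  d <- data.frame(x = c(-1.2, -0.3, 0.1, 0.8, 1.5, 2.0),
                  y = c(0, 0, 1, 0, 1, 1))
  fit <- fit_logistic(y ~ x, d)
  ll <- function(a, b) sum(d$y * (a + b * d$x) - log1p(exp(a + b * d$x)))
  grid_a <- seq(-3, 3, by = 0.002)
  grid_b <- seq(-1, 5, by = 0.002)
  L <- outer(grid_a, grid_b, Vectorize(ll))
  best <- arrayInd(which.max(L), dim(L))
  expect_equal(unname(coef(fit)["(Intercept)"]), grid_a[best[1]],
               tolerance = 1e-3)
  expect_equal(unname(coef(fit)["x"]), grid_b[best[2]], tolerance = 1e-3)
  expect_gte(fit$log_likelihood, max(L) - 1e-9)
})

test_that("IRLS agrees with the reference GLM fitter on cohort data", {
  pd <- mframe(generate_cohort(small_ea_config(seed = 14))$cohort)
  fit <- fit_logistic(ea_model_formula, pd)
  ref <- glm(ea_model_formula, binomial(), pd)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)),
               tolerance = 1e-8)
  expect_equal(unname(diag(vcov(fit))), unname(diag(vcov(ref))),
               tolerance = 1e-3)
  expect_true(fit$converged)
  expect_gte(fit$log_likelihood, fit$null_log_likelihood)
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(x = rnorm(10), y = rep(1, 10))
  expect_error(fit_logistic(y ~ x, d), "single class")
  set.seed(2)
  d2 <- data.frame(x = rnorm(30))
  d2$z <- 2 * d2$x
  d2$y <- rbinom(30, 1, 0.4)
  expect_error(fit_logistic(y ~ x + z, d2), "aliased.*z")
})

test_that("complete separation sets the separation flag", {
  d <- data.frame(x = c(-(5:1), 1:5) / 2)
  d$y <- as.integer(d$x > 0)
  fit <- fit_logistic(y ~ x, d)
  expect_true(fit$separation_flag)
  expect_gt(abs(coef(fit)["x"]), 10)
})

test_that("Nagelkerke R2 follows the rescaled Cox-Snell formula", {
  d <- data.frame(y = c(rep(1, 4), rep(0, 8)))
  fit0 <- fit_logistic(y ~ 1, d)
  expect_equal(nagelkerke_r2(fit0), 0, tolerance = 1e-12)

  pd <- mframe(generate_cohort(small_ea_config(seed = 31))$cohort)
  fit <- fit_logistic(acn ~ age + bmi, pd)
  n <- fit$n
  r2_cs <- 1 - exp((2 / n) * (fit$null_log_likelihood - fit$log_likelihood))
  r2_max <- 1 - exp((2 / n) * fit$null_log_likelihood)
  expect_equal(nagelkerke_r2(fit), r2_cs / r2_max, tolerance = 1e-10)
  ## near-perfect prediction approaches the upper bound 1
  dp <- data.frame(x = c(-(10:1), 1:10))
  dp$y <- as.integer(dp$x > 0)
  fitp <- fit_logistic(y ~ x, dp)
  expect_gt(nagelkerke_r2(fitp), 0.99)
})

test_that("backward elimination honors the stopping rule and forcing", {
  ## strong predictors only: fixed point, nothing removed
  d <- sim_logistic(800, beta = c(1.2, -1.0), seed = 5, intercept = -0.5)
  res <- backward_eliminate(d, outcome = "y", candidates = c("x1", "x2"))
  expect_setequal(res$selected, c("x1", "x2"))

  ## a pure-noise forced term survives despite a large P value
  d$noise <- rnorm(nrow(d))
  res2 <- backward_eliminate(d, outcome = "y",
                             candidates = c("x1", "x2", "noise"),
                             forced = "noise")
  expect_true("noise" %in% res2$selected)
  p_noise <- res2$fit$p_value["noise"]
  expect_gt(p_noise, 0.10)

  ## all retained terms meet the threshold
  d3 <- sim_logistic(600, beta = c(0.9, 0, 0, 0), seed = 6)
  res3 <- backward_eliminate(d3, outcome = "y",
                             candidates = paste0("x", 1:4))
  pv <- res3$fit$p_value[setdiff(names(res3$fit$p_value), "(Intercept)")]
  expect_true(all(pv <= 0.10))
})

test_that("elimination result is invariant to candidate ordering", {
  d <- sim_logistic(500, beta = c(0.8, 0.02, -0.03, 0.6), seed = 9)
  r1 <- backward_eliminate(d, "y", paste0("x", 1:4))
  r2 <- backward_eliminate(d, "y", rev(paste0("x", 1:4)))
  expect_setequal(r1$selected, r2$selected)
})

test_that("a strong predictor survives elimination in almost all replicates", {
  kept <- 0L
  for (s in 1:100) {
    d <- sim_logistic(2000, beta = c(0.8, 0, 0, 0, 0, 0),
                      seed = 100 + s, intercept = -2)
    res <- backward_eliminate(d, "y", paste0("x", 1:6))
    if ("x1" %in% res$selected) kept <- kept + 1L
  }
  expect_gte(kept, 95)
})

test_that("serialized models predict identically after a round trip", {
  pd <- mframe(generate_cohort(small_ea_config(seed = 8))$cohort)
  fit <- fit_logistic(ea_model_formula, pd)
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  restored <- read_model(path)
  expect_equal(predict(restored, pd), predict(fit, pd), tolerance = 1e-12)
  expect_equal(coef(restored), coef(fit), tolerance = 1e-15)
})
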
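test_that("univariate screening reproduces hand-computed 2x2 statistics", {
  ## balanced table: no association
  d0 <- data.frame(x = rep(c(1, 1, 0, 0), each = 10),
                   acn = rep(c(1, 0, 1, 0), each = 10))
  u0 <- univariate_screen(d0, variables = "x")
  expect_equal(u0$or, 1.0, tolerance = 1e-8)
  expect_equal(u0$statistic, 0, tolerance = 1e-12)

  ## (20,10;10,20): OR 4; Pearson chi-square 20/3 (four deviations of 5
  ## against expected cells of 15)
  d1 <- data.frame(x = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)),
                   acn = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)))
  u1 <- univariate_screen(d1, variables = "x")
  expect_equal(u1$or, 4.0, tolerance = 1e-7)
  expect_equal(u1$statistic, 4 * 5^2 / 15, tolerance = 1e-10)
  expect_equal(u1$test, "chi-square")

  ## identical continuous samples: Welch t = 0, P = 1
  v <- c(1.2, 3.4, 5.6, 2.2, 8.1)
  d2 <- data.frame(z = c(v, v), acn = rep(c(1, 0), each = 5))
  u2 <- univariate_screen(d2, variables = "z")
  expect_equal(u2$test, "welch-t")
  expect_equal(u2$statistic, 0, tolerance = 1e-12)
  expect_equal(u2$p, 1, tolerance = 1e-12)
})

test_that("the C-statistic equals exhaustive pairwise enumeration", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(c_statistic(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(c_statistic(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)), 0.75)

  enumerate_c <- function(pred, y) {
    ev <- which(y == 1); nv <- which(y == 0)
    tot <- 0
    for (i in ev) for (j in nv)
      tot <- tot + (pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j])
    tot / (length(ev) * length(nv))
  }
  set.seed(20)
  for (rep in 1:5) {
    pred <- round(runif(40), 2)  # rounded so ties occur
    y <- rbinom(40, 1, 0.4)
    expect_equal(c_statistic(pred, y), enumerate_c(pred, y))
  }
  expect_error(c_statistic(runif(5), rep(1, 5)), "single class")
})

test_that("the C-statistic is invariant under monotone transforms", {
  set.seed(21)
  pred <- runif(200); y <- rbinom(200, 1, pred)
  base <- c_statistic(pred, y)
  expect_equal(c_statistic(qlogis(pred), y), base)
  expect_equal(c_statistic(pred^3, y), base)
  expect_equal(c_statistic(rank(pred), y), base)
})

test_that("bootstrap C intervals are deterministic and degenerate-safe", {
  d <- data.frame(x = c(rep(-2, 30), rep(2, 30)),
                  y = rep(c(0, 1), each = 30))
  fit <- fit_logistic(y ~ x, d)
  ci <- c_statistic_ci(fit, d, outcome = "y", B = 200, seed = 3)
  expect_equal(ci$point, 1.0)
  expect_equal(ci$lower, 1.0)
  expect_equal(ci$upper, 1.0)
  ci2 <- c_statistic_ci(fit, d, outcome = "y", B = 200, seed = 3)
  expect_identical(ci, ci2)
  expect_error(c_statistic_ci(fit, d, outcome = "y", B = 50), "at least 100")
})

test_that("bootstrap C intervals cover the long-run discrimination", {
  ## long-run C of the data-generating model, by a large-sample evaluation
  set.seed(77)
  big_x <- rnorm(200000)
  big_y <- rbinom(200000, 1, plogis(-1 + big_x))
  c_true <- c_statistic(plogis(-1 + big_x), big_y)
  covered <- 0L
  d_model <- data.frame(x = rnorm(2000))
  d_model$y <- rbinom(2000, 1, plogis(-1 + d_model$x))
  fit <- fit_logistic(y ~ x, d_model)
  for (r in 1:100) {
    set.seed(900 + r)
    d <- data.frame(x = rnorm(400))
    d$y <- rbinom(400, 1, plogis(-1 + d$x))
    ci <- c_statistic_ci(fit, d, outcome = "y", B = 400, seed = r)
    if (ci$lower <= c_true && c_true <= ci$upper) covered <- covered + 1L
  }
  expect_gte(covered, 89)
  expect_lte(covered, 99)
})

test_that("Hosmer-Lemeshow matches hand arithmetic and chi-square tails", {
  ## perfect calibration: every group's expected equals observed
  pred <- rep(c(0.1, 0.2, 0.3, 0.4), each = 10)
  y <- unlist(lapply(c(1, 2, 3, 4), function(k) rep(c(1, 0), c(k, 10 - k))))
  hl <- hosmer_lemeshow(pred, y, groups = rep(1:4, each = 10))
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p, 1)

  ## hand-computed group term: n=10, mean pred 0.2, observed 3
  ## -> (3-2)^2 / (2 * (1 - 0.2)) = 0.625
  pred2 <- c(rep(0.2, 10), rep(0.5, 10), rep(0.7, 10))
  y2 <- c(rep(c(1, 0), c(3, 7)), rep(c(1, 0), c(5, 5)),
          rep(c(1, 0), c(7, 3)))
  hl2 <- hosmer_lemeshow(pred2, y2, groups = rep(1:3, each = 10))
  expect_equal(hl2$statistic, 0.625, tolerance = 1e-12)
  expect_equal(hl2$df, 1)

  ## df = G - 2 and the chi-square survival identity P = exp(-H/2) at df 2
  pred4 <- rep(c(0.1, 0.2, 0.3, 0.4), each = 25)
  set.seed(31)
  y4 <- rbinom(100, 1, pred4)
  hl4 <- hosmer_lemeshow(pred4, y4, groups = rep(1:4, each = 25))
  expect_equal(hl4$df, 2)
  expect_equal(hl4$p, exp(-hl4$statistic / 2), tolerance = 1e-12)

  ## degenerate group (expected 0) rejected
  expect_error(hosmer_lemeshow(c(rep(0, 10), rep(0.5, 20)),
                               rbinom(30, 1, 0.3),
                               groups = rep(1:3, each = 10)),
               "degenerate")
})

test_that("decile grouping merges ties and reports totals consistently", {
  set.seed(41)
  pred <- plogis(rnorm(500, -2, 0.8))
  y <- rbinom(500, 1, pred)
  hl <- hosmer_lemeshow(pred, y)
  expect_equal(sum(hl$table$n), 500)
  expect_equal(sum(hl$table$observed), sum(y))
  expect_equal(hl$df, nrow(hl$table) - 2)
  expect_gte(hl$statistic, 0)
})

test_that("quantile calibration groups by the external variable", {
  ## predictions equal to each group's observed rate -> H = 0, P = 1
  adi <- rep(c(10, 30, 60, 90), each = 20)
  y <- unlist(lapply(c(1, 2, 4, 6), function(k) rep(c(1, 0), c(k, 20 - k))))
  pred <- rep(c(1, 2, 4, 6) / 20, each = 20)
  cal <- calibration_by_quantile(pred, y, adi, Q = 4)
  expect_equal(cal$statistic, 0, tolerance = 1e-12)
  expect_equal(cal$p, 1)
  expect_equal(nrow(cal$table), 4)

  ## Q=4 on 8 subjects with distinct group values -> groups of 2
  g8 <- calibration_by_quantile(rep(0.5, 8), c(0, 1, 0, 1, 0, 1, 0, 1),
                                group_var = 1:8, Q = 4)
  expect_equal(g8$table$n, rep(2, 4))
  expect_error(calibration_by_quantile(runif(10), rbinom(10, 1, 0.5),
                                       rep(1, 10), Q = 4),
               "too few distinct")
})

test_that("the trend test matches the Cochran-Armitage reference", {
  ## flat prevalences: Z = 0, P = 1
  y_flat <- rep(rep(c(1, 0), c(2, 8)), 3)
  g_flat <- rep(1:3, each = 10)
  t_flat <- trend_test(y_flat, g_flat)
  expect_equal(t_flat$z, 0, tolerance = 1e-12)
  expect_equal(t_flat$p, 1, tolerance = 1e-12)

  ## steadily increasing prevalence at large n: overwhelming evidence
  y_inc <- unlist(lapply(c(25, 50, 75, 100),
                         function(k) rep(c(1, 0), c(k, 500 - k))))
  g_inc <- rep(1:4, each = 500)
  t_inc <- trend_test(y_inc, g_inc)
  expect_lt(t_inc$p, 1e-6)
  expect_gt(t_inc$z, 0)

  ## agrees with the base-R prevalence trend test
  ref <- suppressWarnings(prop.trend.test(c(25, 50, 75, 100), rep(500, 4)))
  expect_equal(t_inc$z^2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(t_inc$p, ref$p.value, tolerance = 1e-10)

  ## reversing the ordering flips the sign but not the P value
  t_rev <- trend_test(y_inc, 5 - g_inc)
  expect_equal(t_rev$z, -t_inc$z, tolerance = 1e-12)
  expect_equal(t_rev$p, t_inc$p, tolerance = 1e-12)
})
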
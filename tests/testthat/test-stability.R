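test_that("candidate screening unions univariate hits with forced terms", {
  pd <- mframe(generate_cohort(generator_config(seed = 4))$cohort)
  forced <- c("sex_male", "bmi", "alcohol_per_week", "smoking_years",
              "family_history_fdr", "red_meat_per_week")
  cand <- screen_candidates(pd, variables = acnrisk:::pipeline_candidate_vars,
                            forced = forced)
  expect_true(all(forced %in% cand))
  uni <- univariate_screen(pd,
                           variables = acnrisk:::pipeline_candidate_vars)
  expect_setequal(cand, union(uni$variable[uni$p < 0.10], forced))

  ## a forced term stays a candidate whatever its univariate P
  pd$pure_noise <- rnorm(nrow(pd))
  cand2 <- screen_candidates(pd, variables = c("age", "pure_noise"),
                             forced = c("pure_noise"))
  expect_true("pure_noise" %in% cand2)
  expect_error(screen_candidates(pd, forced = "not_a_column"),
               "unknown forced")
})

test_that("an outcome-linked covariate is reliably screened in", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(7000 + s)
    n <- 600
    x <- rnorm(n)
    d <- data.frame(age = x * 4 + 58,
                    bmi = rnorm(n, 28, 5),
                    acn = rbinom(n, 1, plogis(-2.3 + 0.5 * x)))
    cand <- screen_candidates(d, variables = c("age", "bmi"),
                              forced = character())
    if ("age" %in% cand) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("bootstrap selection is deterministic given the seed", {
  pd <- mframe(generate_cohort(small_ea_config(seed = 3))$cohort)
  r1 <- bootstrap_frequencies(pd, candidates = c("age", "bmi", "sex_male"),
                              B = 1L, seed = 99)
  r2 <- bootstrap_frequencies(pd, candidates = c("age", "bmi", "sex_male"),
                              B = 1L, seed = 99)
  expect_identical(r1, r2)
  expect_true(all(r1$selection_count %in% 0:1))
})

test_that("selection frequencies separate signal from noise", {
  ## one strong predictor (OR 2 per SD), three null predictors, 10% base rate
  set.seed(42)
  n <- 2000
  d <- data.frame(strong = rnorm(n), null1 = rnorm(n), null2 = rnorm(n),
                  null3 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-2.2 + log(2) * d$strong))
  res <- bootstrap_frequencies(d, outcome = "y",
                               candidates = c("strong", "null1", "null2",
                                              "null3"),
                               B = 200L, seed = 5)
  expect_gt(res$frequency[["strong"]], 0.9)
  expect_lt(mean(res$frequency[c("null1", "null2", "null3")]), 0.4)
  expect_true(all(res$frequency >= 0 & res$frequency <= 1))
  expect_true(all(diff(res$sorted_frequencies) <= 0))
})

test_that("the final-predictor rule applies threshold and drop logic", {
  mk <- function(freqs, B = 100L) {
    structure(list(candidates = names(freqs),
                   selection_count = as.integer(freqs * B),
                   frequency = freqs,
                   sorted_frequencies = sort(freqs, decreasing = TRUE),
                   B = B, alpha = 0.1, seed = 1L, redraws = 0L),
              class = "acn_stability")
  }
  r <- mk(c(a = 0.9, b = 0.7, c = 0.35, d = 0.10))
  expect_setequal(choose_final_predictors(r, drop_rule = FALSE),
                  c("a", "b"))

  ## a big drop just under the threshold pulls the cluster above it in
  r2 <- mk(c(a = 0.9, b = 0.38, c = 0.36, d = 0.05))
  expect_setequal(choose_final_predictors(r2, drop_rule = TRUE),
                  c("a", "b", "c"))

  ## flat plateau: no gap, no extension
  r3 <- mk(c(a = 0.3, b = 0.3, c = 0.3))
  expect_identical(choose_final_predictors(r3, drop_rule = TRUE),
                   character(0))

  ## raising the threshold never enlarges the base set
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    lo <- choose_final_predictors(r, threshold = th, drop_rule = FALSE)
    hi <- choose_final_predictors(r, threshold = th + 0.1,
                                  drop_rule = FALSE)
    expect_true(all(hi %in% lo))
  }
})

test_that("true predictors out-select injected null predictors", {
  ## EA-like cohorts; two pure-noise covariates injected
  diffs <- numeric(10)
  true_terms <- c("sex_male", "age", "bmi", "family_history_fdr",
                  "smoking_years", "calcium_use")
  for (s in 1:10) {
    pd <- mframe(generate_cohort(ea_generator_config(seed = 500 + s))$cohort)
    set.seed(600 + s)
    pd$noise1 <- rnorm(nrow(pd))
    pd$noise2 <- rnorm(nrow(pd))
    res <- bootstrap_frequencies(
      pd, candidates = c(true_terms, "noise1", "noise2"),
      B = 40L, seed = 700 + s)
    diffs[s] <- mean(res$frequency[true_terms]) -
      mean(res$frequency[c("noise1", "noise2")])
  }
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 8)
})
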
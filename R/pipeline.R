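## End-to-end orchestration: cohort ingest or generation, per-population
## model building (overall with race forced, plus each race stratum),
## evaluation with cross-race application, deprivation augmentation and
## report emission.

## Canonical numeric modelling frame: character covariates recoded to the
## indicator columns the selection machinery uses.
modelling_frame <- function(cohort) {
  d <- cohort
  d$sex_male <- as.numeric(d$sex == "male")
  if ("race" %in% names(d)) d$race_aa <- as.numeric(d$race == "AA")
  d
}

pipeline_candidate_vars <- c("sex_male", "age", "bmi", "family_history_fdr",
                             "smoking_years", "diabetes", "calcium_use",
                             "red_meat_per_week", "alcohol_per_week")
pipeline_forced_vars <- c("sex_male", "bmi", "alcohol_per_week",
                          "smoking_years", "family_history_fdr",
                          "red_meat_per_week")

## Table-1-shape cohort summary.
cohort_summary <- function(cohort) {
  summarize_block <- function(d) {
    cont <- c("age", "bmi", "smoking_years", "red_meat_per_week",
              "alcohol_per_week", "adi")
    bin <- c("family_history_fdr", "diabetes", "calcium_use")
    list(
      n = nrow(d),
      events = sum(d$acn),
      prevalence = mean(d$acn),
      p_female = mean(d$sex == "female"),
      means = lapply(stats::setNames(cont, cont),
                     function(v) c(mean = mean(d[[v]]),
                                   sd = stats::sd(d[[v]]))),
      proportions = lapply(stats::setNames(bin, bin),
                           function(v) mean(d[[v]]))
    )
  }
  races <- sort(unique(cohort$race))
  out <- list(Overall = summarize_block(cohort))
  for (r in races) out[[r]] <- summarize_block(cohort[cohort$race == r, ])
  out
}

## One population's model-building block: screen -> bootstrap selection ->
## final rule -> final fit -> LASSO redundancy check.
build_population_model <- function(pd, population, seed,
                                   stability_B, threshold, drop_rule,
                                   force_final = character()) {
  candidates <- screen_candidates(
    pd, variables = pipeline_candidate_vars,
    forced = pipeline_forced_vars)
  if (length(force_final)) candidates <- union(candidates, force_final)
  stab <- bootstrap_frequencies(pd, candidates = candidates,
                                B = stability_B, seed = seed)
  final <- choose_final_predictors(stab, threshold = threshold,
                                   drop_rule = drop_rule)
  final <- union(final, force_final)
  fml <- stats::reformulate(if (length(final)) final else "1",
                            response = "acn")
  fit <- fit_logistic(fml, pd)
  lasso <- if (length(final) >= 2)
    fit_lasso_cv(pd, predictors = final, seed = seed)
  else NULL
  list(population = population,
       candidates = candidates,
       frequencies = stab$frequency,
       sorted_frequencies = stab$sorted_frequencies,
       final_predictors = final,
       fit = fit,
       nagelkerke_r2 = nagelkerke_r2(fit),
       or_table = summary(fit)$table,
       lasso_nonzero = if (is.null(lasso)) final else lasso$nonzero_set,
       lasso_eliminated = if (is.null(lasso)) character()
         else setdiff(final, lasso$nonzero_set))
}

evaluate_model_on <- function(fit, pd, c_stat_B, seed) {
  pred <- stats::predict(fit, pd, type = "response")
  ci <- c_statistic_ci(fit, pd, B = c_stat_B, seed = seed)
  hl <- tryCatch(hosmer_lemeshow(pred, pd$acn),
                 error = function(e) NULL)
  list(c_statistic = ci$point, c_lower = ci$lower, c_upper = ci$upper,
       hl_p = if (is.null(hl)) NA_real_ else hl$p,
       hl_statistic = if (is.null(hl)) NA_real_ else hl$statistic)
}

#' Run the full analysis pipeline
#'
#' Executes, for each population (the combined cohort when more than one
#' race block is present, then each race stratum): univariate candidate
#' screening, bootstrap stability selection, the final-predictor rule
#' (race forced into the combined model), the final logistic fit, the
#' LASSO redundancy check, evaluation on its own population and
#' cross-application to the complementary race stratum, the two-stage
#' mixed-effects augmentation with ADI (likelihood-ratio test, tract
#' variance partition), and calibration across ADI quantiles before and
#' after augmentation.  All randomness derives from one master seed.
#'
#' @param config an [generator_config()]; ignored when `cohort` is given.
#' @param cohort optional pre-loaded cohort data frame (e.g. from
#'   [read_cohort()]); when NULL a synthetic cohort is generated.
#' @param seed master seed (default: the config's).
#' @param stability_B bootstrap replicates of the selection procedure
#'   (default 1000).
#' @param c_stat_B bootstrap replicates of the C-statistic CI
#'   (default 2000).
#' @param threshold,drop_rule final-predictor rule parameters.
#' @param q_points quadrature points of the mixed fits (default 10).
#' @param quantile_Q deprivation quantile groups for calibration
#'   (default 4).
#' @return object of class `acn_report` (a nested list; see
#'   [write_report()]).
#' @export
run_pipeline <- function(config = generator_config(), cohort = NULL,
                         seed = config$seed, stability_B = 1000L,
                         c_stat_B = 2000L, threshold = 0.4,
                         drop_rule = TRUE, q_points = 10L,
                         quantile_Q = 4L) {
  t0 <- Sys.time()
  if (is.null(cohort)) {
    sim <- generate_cohort(config, seed = seed)
    cohort <- sim$cohort
  }
  pd_all <- modelling_frame(cohort)
  races <- sort(unique(cohort$race))
  pops <- if (length(races) > 1) c("All", races) else races

  report <- list(
    provenance = list(seed = as.integer(seed),
                      config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("acnrisk")),
                      populations = pops),
    cohort_summary = cohort_summary(cohort),
    univariate = as.data.frame(univariate_screen(
      cohort,
      variables = Filter(
        function(v) length(unique(cohort[[v]])) > 1,
        intersect(c("race", "sex", "age", "bmi", "family_history_fdr",
                    "smoking_years", "diabetes", "calcium_use",
                    "red_meat_per_week", "alcohol_per_week", "adi"),
                  names(cohort))))),
    populations = list()
  )

  fits <- list()
  for (i in seq_along(pops)) {
    pop <- pops[i]
    pd <- if (pop == "All") pd_all else pd_all[pd_all$race == pop, ]
    blk <- build_population_model(
      pd, pop, seed = child_seed(seed, 1000L + i),
      stability_B = stability_B, threshold = threshold,
      drop_rule = drop_rule,
      force_final = if (pop == "All") "race_aa" else character())
    fits[[pop]] <- blk$fit

    ev_own <- evaluate_model_on(blk$fit, pd, c_stat_B,
                                seed = child_seed(seed, 2000L + i))
    cross <- list()
    cross_pops <- if (pop == "All") races else setdiff(races, pop)
    for (cp in cross_pops) {
      pd_cp <- pd_all[pd_all$race == cp, ]
      cross[[cp]] <- evaluate_model_on(blk$fit, pd_cp, c_stat_B,
                                       seed = child_seed(seed, 3000L + i))
    }

    ## ADI augmentation on the model's own population
    pred <- stats::predict(blk$fit, pd, type = "response")
    pred <- pmin(pmax(pred, 1e-10), 1 - 1e-10)
    aug <- augment_with_adi(pred, pd$adi, pd$acn, pd$tract_id,
                            q_points = q_points)
    cal_before <- calibration_by_quantile(pred, pd$acn, pd$adi,
                                          Q = quantile_Q)
    pred_after <- stats::predict(
      aug$fit_full,
      data.frame(risk01 = pred / 0.1, adi10 = pd$adi / 10),
      type = "response")
    cal_after <- calibration_by_quantile(pred_after, pd$acn, pd$adi,
                                         Q = quantile_Q)

    ## prevalence trend across deprivation quartiles
    adi_q <- cut(pd$adi,
                 breaks = unique(stats::quantile(
                   pd$adi, probs = seq(0, 1, length.out = quantile_Q + 1),
                   type = 7)),
                 include.lowest = TRUE, labels = FALSE)
    trend <- trend_test(pd$acn, adi_q)

    report$populations[[pop]] <- list(
      candidates = blk$candidates,
      selection_frequencies = as.list(blk$frequencies),
      sorted_frequencies = as.list(blk$sorted_frequencies),
      adi_trend = list(z = trend$z, p = trend$p),
      final_predictors = blk$final_predictors,
      or_table = as.data.frame(blk$or_table),
      nagelkerke_r2 = blk$nagelkerke_r2,
      lasso_eliminated = blk$lasso_eliminated,
      performance = c(list(own = ev_own), cross),
      augmentation = list(
        or_base_per_0p1 = as.list(aug$or_base_per_0p1),
        or_adi_per_10 = as.list(aug$or_adi_per_10),
        lrt_adi_p = aug$lrt_adi$p,
        tract_variance_null = aug$tract_variance_null,
        tract_variance_full = aug$tract_variance,
        variance_partition = aug$variance_partition),
      calibration_by_adi = list(
        before = list(table = cal_before$table, p = cal_before$p),
        after = list(table = cal_after$table, p = cal_after$p))
    )
  }
  report$timing_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$models <- fits
  class(report) <- "acn_report"
  report
}

#' @export
print.acn_report <- function(x, ...) {
  cs <- x$cohort_summary$Overall
  cat(sprintf("ACN analysis report: n = %d, events = %d (%.1f%%)\n",
              cs$n, cs$events, 100 * cs$prevalence))
  for (pop in names(x$populations)) {
    b <- x$populations[[pop]]
    cat(sprintf(
      "  %s: predictors {%s}; C = %.3f (%.3f-%.3f); HL P = %.3f\n",
      pop, paste(b$final_predictors, collapse = ", "),
      b$performance$own$c_statistic, b$performance$own$c_lower,
      b$performance$own$c_upper, b$performance$own$hl_p))
    cat(sprintf(
      "      ADI OR/10 = %.2f (LRT P = %.3g); tract-variance share %.1f%%\n",
      b$augmentation$or_adi_per_10$or, b$augmentation$lrt_adi_p,
      100 * b$augmentation$variance_partition))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the machine-readable report as JSON (fitted model objects
#' excluded) and a short aligned-text summary.
#'
#' @param report an `acn_report`.
#' @param dir output directory (created if absent).
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- unclass(report)
  out$models <- NULL
  out$timing_s <- NULL  # wall-clock time would break report determinism
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, "w")
  sink(con); print(report); sink()
  close(con)
  for (pop in names(report$models)) {
    write_model(report$models[[pop]],
                file.path(dir, paste0("model_", pop, ".json")))
  }
  invisible(json_path)
}
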
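## Synthetic multilevel cohort generator: census tracts with 17 correlated
## socioeconomic indicators, and a two-race screening cohort nested in the
## tracts with covariates, tract random intercepts and a binary advanced
## colorectal neoplasia (ACN) outcome.

#' Race-block parameters for the cohort generator
#'
#' Bundles the per-race sampling parameters: cohort size, covariate
#' distribution parameters (means/SDs of continuous covariates, proportions
#' of binary covariates), the target ACN prevalence, the target mean and SD
#' of the Area Deprivation Index (ADI) among subjects of that race, and
#' optional race-specific overrides of the outcome-model coefficients.
#'
#' Continuous covariates are drawn as truncated normals: age on \[50, 80\]
#' (screening eligibility window) and BMI on \[15, 60\], both with the
#' pre-truncation parameters adjusted so the post-truncation mean and SD
#' match the configured targets; smoking years, red meat and alcohol
#' frequencies are floored at 0 without moment adjustment (their configured
#' mean/SD pairs are not attainable under left truncation, so the configured
#' values parameterize the latent normal).
#'
#' @param n_subjects number of subjects.
#' @param age_mean,age_sd target mean/SD of age (years) after truncation to
#'   \[50, 80\].
#' @param bmi_mean,bmi_sd target mean/SD of BMI (kg/m^2) after truncation to
#'   \[15, 60\].
#' @param smoking_mean,smoking_sd latent mean/SD of years smoked (floored at 0).
#' @param red_meat_mean,red_meat_sd latent mean/SD of weekly red-meat
#'   frequency (floored at 0).
#' @param alcohol_mean,alcohol_sd latent mean/SD of weekly alcohol frequency
#'   (floored at 0).
#' @param p_female,p_family_history_fdr,p_diabetes,p_calcium_use proportions
#'   in \[0, 1\] for the binary covariates (family history is of colorectal
#'   cancer in first-degree relatives).
#' @param target_prevalence target marginal ACN prevalence for the block.
#' @param adi_target_mean,adi_target_sd target mean/SD of subject-level ADI
#'   (0-100 scale) achieved by deprivation-weighted tract assignment.
#' @param coefficients optional named list of log-odds-ratio overrides for
#'   this race (see [generator_config()]).
#' @param adi_log_or_per_10 optional race-specific log odds ratio per 10 ADI
#'   units.
#' @return list of class `acn_race_block`.
#' @export
race_block <- function(n_subjects,
                       age_mean, age_sd,
                       bmi_mean, bmi_sd,
                       smoking_mean, smoking_sd,
                       red_meat_mean, red_meat_sd,
                       alcohol_mean, alcohol_sd,
                       p_female, p_family_history_fdr,
                       p_diabetes, p_calcium_use,
                       target_prevalence,
                       adi_target_mean, adi_target_sd,
                       coefficients = NULL,
                       adi_log_or_per_10 = NULL) {
  blk <- list(
    n_subjects = as.integer(n_subjects),
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    smoking_mean = smoking_mean, smoking_sd = smoking_sd,
    red_meat_mean = red_meat_mean, red_meat_sd = red_meat_sd,
    alcohol_mean = alcohol_mean, alcohol_sd = alcohol_sd,
    p_female = p_female,
    p_family_history_fdr = p_family_history_fdr,
    p_diabetes = p_diabetes,
    p_calcium_use = p_calcium_use,
    target_prevalence = target_prevalence,
    adi_target_mean = adi_target_mean,
    adi_target_sd = adi_target_sd,
    coefficients = coefficients,
    adi_log_or_per_10 = adi_log_or_per_10
  )
  props <- c(p_female, p_family_history_fdr, p_diabetes, p_calcium_use,
             target_prevalence)
  if (any(props < 0 | props > 1))
    stop("proportions and target_prevalence must lie in [0, 1]")
  if (blk$n_subjects <= 0) stop("n_subjects must be positive")
  sds <- c(age_sd, bmi_sd, smoking_sd, red_meat_sd, alcohol_sd, adi_target_sd)
  if (any(sds <= 0)) stop("all SDs must be positive")
  class(blk) <- "acn_race_block"
  blk
}

#' Preset race blocks for the emulated screening-colonoscopy cohort
#'
#' `ea_race_block()` and `aa_race_block()` return the default parameters of
#' the European-American (n = 1457) and African-American (n = 936) strata of
#' the emulated cohort: covariate means/SDs and proportions, target ACN
#' prevalences of 6.3% and 8.4%, and target ADI distributions of mean 28.1
#' (SD 11.5) and mean 53.1 (SD 15.3) respectively.  The race-specific
#' outcome coefficients default to the corresponding race-specific risk
#' model (EA: male sex OR 1.43, age 1.03/year, BMI 1.04/unit, family history
#' 1.83, smoking 1.01/year, calcium 0.44, ADI 1.24/10 units; AA: age 1.03,
#' smoking 1.01, diabetes 1.76, red meat 1.04/weekly serving, ADI 1.07/10
#' units), expressed as log odds ratios.
#'
#' @param ... overrides passed to [race_block()].
#' @return an `acn_race_block`.
#' @export
ea_race_block <- function(...) {
  defaults <- list(
    n_subjects = 1457,
    age_mean = 57.8, age_sd = 7.0,
    bmi_mean = 28.3, bmi_sd = 5.9,
    smoking_mean = 9.3, smoking_sd = 13.6,
    red_meat_mean = 2.9, red_meat_sd = 2.8,
    alcohol_mean = 3.0, alcohol_sd = 5.6,
    p_female = 0.567, p_family_history_fdr = 0.107,
    p_diabetes = 0.091, p_calcium_use = 0.258,
    target_prevalence = 0.063,
    adi_target_mean = 28.1, adi_target_sd = 11.5,
    coefficients = list(
      sex_male = log(1.43), age = log(1.03), bmi = log(1.04),
      family_history_fdr = log(1.83), smoking_years = log(1.01),
      calcium_use = log(0.44)
    ),
    adi_log_or_per_10 = log(1.24)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(race_block, args)
}

#' @rdname ea_race_block
#' @export
aa_race_block <- function(...) {
  defaults <- list(
    n_subjects = 936,
    age_mean = 57.9, age_sd = 7.4,
    bmi_mean = 31.8, bmi_sd = 7.9,
    smoking_mean = 17.4, smoking_sd = 16.8,
    red_meat_mean = 3.3, red_meat_sd = 3.8,
    alcohol_mean = 3.0, alcohol_sd = 12.9,
    p_female = 0.676, p_family_history_fdr = 0.112,
    p_diabetes = 0.250, p_calcium_use = 0.111,
    target_prevalence = 0.084,
    adi_target_mean = 53.1, adi_target_sd = 15.3,
    coefficients = list(
      age = log(1.03), smoking_years = log(1.01),
      diabetes = log(1.76), red_meat_per_week = log(1.04)
    ),
    adi_log_or_per_10 = log(1.07)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(race_block, args)
}

#' Generator configuration
#'
#' Full configuration of the synthetic multilevel cohort generator.  The
#' defaults emulate the study conditions of the cohort the package models:
#' 598 census tracts whose 17 socioeconomic indicators share a single
#' deprivation factor with common loading chosen so the first principal
#' component carries 60.2% of their variance, a two-race cohort (EA
#' n = 1457, AA n = 936) nested in the tracts, and a binary ACN outcome
#' drawn from a logistic model with individual covariates, a linear ADI
#' effect (per 10 units) and a tract-level random intercept.
#'
#' The 17 indicators follow the single-factor model
#' \eqn{x_k = \lambda f + \sqrt{1-\lambda^2}\,\epsilon_k} with standard
#' normal \eqn{f} and \eqn{\epsilon_k}, so their population correlation
#' matrix is equicorrelated with leading-eigenvalue share
#' \eqn{(1 + 16\lambda^2)/17}.  The default `factor_loading` inverts this at
#' a 60.2% share.
#'
#' `coefficients` holds the default log odds ratios of the outcome model,
#' overridable per race block.  Recognized names: `race_aa`, `sex_male`,
#' `age` (per year), `bmi` (per kg/m^2), `family_history_fdr`,
#' `smoking_years` (per year), `diabetes`, `calcium_use`,
#' `red_meat_per_week` and `alcohol_per_week` (per weekly frequency unit).
#' The configuration-level defaults are the combined-population risk model
#' (race AA vs EA OR 1.08, male sex 1.41, age 1.03, BMI 1.03, family
#' history 1.69, smoking 1.01, diabetes 1.49, calcium 0.59; ADI 1.07 per 10
#' units).
#'
#' The per-race intercept is not configured: it is calibrated by
#' [calibrate_intercept()] so each race block's realized expected
#' prevalence equals its `target_prevalence`.
#'
#' Seed policy: one master `seed`; child seeds are derived by fixed offsets
#' (+1 tract indicators, +2 tract random intercepts, +100·k covariates and
#' tract assignment of the k-th race block in list order, +3 outcome draws).
#'
#' @param n_tracts number of census tracts (default 598).
#' @param factor_loading common loading of the shared deprivation factor,
#'   in (0, 1).
#' @param race_blocks named list of [race_block()] objects keyed by race
#'   label (default `EA` and `AA` presets).
#' @param coefficients default named list of log odds ratios (see Details).
#' @param adi_log_or_per_10 default log odds ratio per 10 ADI units.
#' @param tract_sigma SD of the tract-level random intercept on the logit
#'   scale (default 0.3).
#' @param seed master seed (default 1).
#' @return list of class `acn_generator_config`.
#' @seealso [ea_generator_config()], [aa_generator_config()] for the
#'   single-race presets with race-specific outcome models.
#' @export
generator_config <- function(n_tracts = 598,
                             factor_loading = pc1_share_to_loading(0.602),
                             race_blocks = list(EA = ea_race_block(),
                                                AA = aa_race_block()),
                             coefficients = list(
                               race_aa = log(1.08), sex_male = log(1.41),
                               age = log(1.03), bmi = log(1.03),
                               family_history_fdr = log(1.69),
                               smoking_years = log(1.01),
                               diabetes = log(1.49), calcium_use = log(0.59)
                             ),
                             adi_log_or_per_10 = log(1.07),
                             tract_sigma = 0.3,
                             seed = 1L) {
  if (n_tracts <= 1) stop("n_tracts must exceed 1")
  if (!is.numeric(factor_loading) || factor_loading <= 0 ||
      factor_loading >= 1)
    stop("factor_loading must lie strictly in (0, 1)")
  if (tract_sigma < 0) stop("tract_sigma must be non-negative")
  if (!length(race_blocks) || is.null(names(race_blocks)) ||
      any(names(race_blocks) == ""))
    stop("race_blocks must be a named list of race_block objects")
  ok <- vapply(race_blocks, inherits, logical(1), "acn_race_block")
  if (!all(ok)) stop("race_blocks entries must be created by race_block()")
  structure(list(
    n_tracts = as.integer(n_tracts),
    factor_loading = factor_loading,
    race_blocks = race_blocks,
    coefficients = coefficients,
    adi_log_or_per_10 = adi_log_or_per_10,
    tract_sigma = tract_sigma,
    seed = as.integer(seed)
  ), class = "acn_generator_config")
}

#' Single-race generator presets
#'
#' `ea_generator_config()` and `aa_generator_config()` return single-stratum
#' configurations in which the outcome model is the corresponding
#' race-specific risk model (see [ea_race_block()]), with all 598 tracts and
#' the default tract random-intercept SD.
#'
#' @param ... overrides passed to [generator_config()].
#' @return an `acn_generator_config`.
#' @export
ea_generator_config <- function(...) {
  blk <- ea_race_block()
  args <- utils::modifyList(
    list(race_blocks = list(EA = blk),
         coefficients = blk$coefficients,
         adi_log_or_per_10 = blk$adi_log_or_per_10),
    list(...))
  do.call(generator_config, args)
}

#' @rdname ea_generator_config
#' @export
aa_generator_config <- function(...) {
  blk <- aa_race_block()
  args <- utils::modifyList(
    list(race_blocks = list(AA = blk),
         coefficients = blk$coefficients,
         adi_log_or_per_10 = blk$adi_log_or_per_10),
    list(...))
  do.call(generator_config, args)
}

#' Convert between the common factor loading and the PC1 variance share
#'
#' Under the equicorrelated single-factor model of the 17 indicators the
#' leading eigenvalue of the correlation matrix is \eqn{1 + 16\lambda^2},
#' so the first principal component's variance share is
#' \eqn{(1 + 16\lambda^2)/17}.  `pc1_share_to_loading()` inverts this.
#'
#' @param share PC1 variance share in (1/17, 1).
#' @param loading common loading in (0, 1).
#' @return the corresponding loading (or share).
#' @export
pc1_share_to_loading <- function(share) {
  if (share <= 1 / 17 || share >= 1)
    stop("share must lie in (1/17, 1)")
  sqrt((share * 17 - 1) / 16)
}

#' @rdname pc1_share_to_loading
#' @export
loading_to_pc1_share <- function(loading) (1 + 16 * loading^2) / 17

#' Tract random-intercept SD implied by a target ADI variance share
#'
#' Between-tract variation in the outcome's linear predictor has two
#' sources: the ADI fixed effect, with variance
#' \eqn{(\beta_{ADI}/10)^2 \sigma_{ADI}^2}, and the residual tract random
#' intercept with variance \eqn{\sigma_u^2}.  Given a target share
#' \eqn{s = \beta\text{-part}/(\beta\text{-part} + \sigma_u^2)} of
#' tract-level variance attributable to ADI, this returns the
#' \eqn{\sigma_u} that realizes it.
#'
#' @param share target ADI share of tract-level linear-predictor variance,
#'   in (0, 1).
#' @param adi_log_or_per_10 log odds ratio per 10 ADI units.
#' @param adi_sd SD of ADI across subjects (0-100 scale).
#' @return tract random-intercept SD on the logit scale.
#' @examples
#' # EA stratum: ADI OR 1.24 per 10 units, ADI SD 11.5, share 38.7%
#' tract_sigma_for_adi_share(0.387, log(1.24), 11.5)
#' @export
tract_sigma_for_adi_share <- function(share, adi_log_or_per_10, adi_sd) {
  if (share <= 0 || share >= 1) stop("share must lie strictly in (0, 1)")
  abs(adi_log_or_per_10) / 10 * adi_sd * sqrt((1 - share) / share)
}

#' Generate census tracts with correlated socioeconomic indicators
#'
#' Draws `n_tracts` tracts whose 17 standardized indicators `v1`..`v17`
#' follow the single-factor model described in [generator_config()].  By
#' convention `v1` is the poverty proxy used to orient the deprivation
#' index.
#'
#' @param config an [generator_config()] object.
#' @param seed integer seed (default: the config's master seed).
#' @return data frame with columns `tract_id`, `v1`..`v17` and `latent_f`
#'   (the tract's deprivation factor, kept for generator bookkeeping).
#' @export
generate_tracts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "acn_generator_config"))
  n <- config$n_tracts
  lam <- config$factor_loading
  set.seed(child_seed(seed, 1L))
  f <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * 17), n, 17)
  X <- lam * f + sqrt(1 - lam^2) * eps
  out <- data.frame(tract_id = sprintf("T%04d", seq_len(n)))
  colnames(X) <- paste0("v", 1:17)
  out <- cbind(out, as.data.frame(X))
  out$latent_f <- f
  out
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds the intercept \eqn{\alpha} such that the mean of
#' \eqn{\mathrm{logit}^{-1}(\alpha + t_i)} over the supplied per-subject
#' linear terms equals the target prevalence, by bisection on a bracketing
#' interval (tolerance 1e-6 on the attained prevalence).
#'
#' @param linear_terms per-subject log-odds contributions excluding the
#'   intercept.
#' @param target_prevalence target mean outcome probability, in (0, 1).
#' @return the calibrated intercept (log-odds scale).
#' @examples
#' calibrate_intercept(rep(0, 10), 0.5)  # 0 by symmetry
#' @export
calibrate_intercept <- function(linear_terms, target_prevalence) {
  if (!is.numeric(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1)
    stop("target_prevalence must lie strictly in (0, 1)")
  if (!length(linear_terms) || any(!is.finite(linear_terms)))
    stop("linear_terms must be finite and non-empty")
  g <- function(a) mean(inv_logit(a + linear_terms)) - target_prevalence
  lo <- -40; hi <- 40
  if (g(lo) > 0 || g(hi) < 0)
    stop("target prevalence unattainable for the supplied linear terms")
  mid <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) < 1e-9) break
    if (gm > 0) hi <- mid else lo <- mid
    if ((hi - lo) < 1e-12) break
  }
  mid
}

## Truncated-normal pre-truncation parameters matched so the post-truncation
## mean/SD equal the targets (used for age and BMI, whose truncation windows
## are narrow enough to bite).
truncnorm_match <- function(target_mean, target_sd, lower, upper) {
  obj <- function(par) {
    mu <- par[1]; sd <- exp(par[2])
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    Z <- stats::pnorm(b) - stats::pnorm(a)
    if (Z < 1e-12) return(1e10)
    dA <- stats::dnorm(a); dB <- stats::dnorm(b)
    m <- mu + sd * (dA - dB) / Z
    v <- sd^2 * (1 + (ifelse(is.finite(a), a * dA, 0) -
                        ifelse(is.finite(b), b * dB, 0)) / Z -
                   ((dA - dB) / Z)^2)
    (m - target_mean)^2 + (sqrt(max(v, 0)) - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

## Deprivation-weighted tract assignment: importance weights equal to the
## density ratio of the race's target ADI distribution over a normal
## approximation of the realized tract ADI distribution, so the sampled
## subject-level ADI distribution approaches N(target_mean, target_sd).
tract_weights <- function(adi, target_mean, target_sd) {
  m0 <- mean(adi); s0 <- stats::sd(adi)
  w <- stats::dnorm(adi, target_mean, target_sd) /
    pmax(stats::dnorm(adi, m0, s0), 1e-12)
  w <- pmin(w, stats::quantile(w, 0.999))  # guard extreme density ratios
  w / sum(w)
}

#' Generate the synthetic multilevel cohort
#'
#' Generates the tract table (via [generate_tracts()]), scores tracts with
#' the Area Deprivation Index (via [compute_adi()]), assigns subjects of
#' each race block to tracts with deprivation-dependent weights so realized
#' per-race ADI means and SDs approach their targets, draws covariates per
#' race block, and draws the binary ACN outcome from
#' \deqn{\mathrm{logit}\,p = \alpha_{race} + \sum_k \beta_k x_k +
#'       \beta_{ADI}\,(ADI/10) + u_{tract},\quad
#'       u_{tract} \sim N(0, \sigma_u^2),}
#' with each race's intercept calibrated by [calibrate_intercept()] so the
#' expected prevalence equals the block's target.  Identical `(config,
#' seed)` give identical output.
#'
#' @param config an [generator_config()] object.
#' @param seed integer master seed (default: the config's).
#' @return list with components `tracts` (tract table with an `adi` column
#'   appended) and `cohort` (subject-level data frame with columns
#'   `subject_id`, `tract_id`, `race`, `sex`, `age`, `bmi`,
#'   `family_history_fdr`, `smoking_years`, `diabetes`, `calcium_use`,
#'   `red_meat_per_week`, `alcohol_per_week`, `adi`, `acn`).
#' @examples
#' sim <- generate_cohort(generator_config(seed = 7))
#' mean(sim$cohort$acn[sim$cohort$race == "EA"])
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "acn_generator_config"))
  tracts <- generate_tracts(config, seed = seed)
  adi_res <- compute_adi(tracts)
  tracts$adi <- unname(adi_res$adi_by_tract[as.character(tracts$tract_id)])

  set.seed(child_seed(seed, 2L))
  u <- stats::rnorm(config$n_tracts, 0, config$tract_sigma)
  names(u) <- as.character(tracts$tract_id)

  races <- names(config$race_blocks)
  parts <- vector("list", length(races))
  for (k in seq_along(races)) {
    blk <- config$race_blocks[[k]]
    n <- blk$n_subjects
    set.seed(child_seed(seed, 100L * k))
    w <- tract_weights(tracts$adi, blk$adi_target_mean, blk$adi_target_sd)
    tr_idx <- sample.int(config$n_tracts, n, replace = TRUE, prob = w)
    age_par <- truncnorm_match(blk$age_mean, blk$age_sd, 50, 80)
    bmi_par <- truncnorm_match(blk$bmi_mean, blk$bmi_sd, 15, 60)
    d <- data.frame(
      tract_id = tracts$tract_id[tr_idx],
      race = races[k],
      sex = ifelse(stats::runif(n) < blk$p_female, "female", "male"),
      age = rtruncnorm(n, age_par$mean, age_par$sd, 50, 80),
      bmi = rtruncnorm(n, bmi_par$mean, bmi_par$sd, 15, 60),
      family_history_fdr = as.integer(stats::runif(n) <
                                        blk$p_family_history_fdr),
      smoking_years = pmax(stats::rnorm(n, blk$smoking_mean,
                                        blk$smoking_sd), 0),
      diabetes = as.integer(stats::runif(n) < blk$p_diabetes),
      calcium_use = as.integer(stats::runif(n) < blk$p_calcium_use),
      red_meat_per_week = pmax(stats::rnorm(n, blk$red_meat_mean,
                                            blk$red_meat_sd), 0),
      alcohol_per_week = pmax(stats::rnorm(n, blk$alcohol_mean,
                                           blk$alcohol_sd), 0),
      stringsAsFactors = FALSE
    )
    d$adi <- tracts$adi[tr_idx]
    parts[[k]] <- d
  }
  cohort <- do.call(rbind, parts)
  cohort <- cbind(subject_id = sprintf("S%05d", seq_len(nrow(cohort))),
                  cohort, stringsAsFactors = FALSE)

  ## outcome model
  set.seed(child_seed(seed, 3L))
  eta <- numeric(nrow(cohort))
  for (k in seq_along(races)) {
    blk <- config$race_blocks[[k]]
    idx <- cohort$race == races[k]
    beta <- blk$coefficients %||% config$coefficients
    b_adi <- blk$adi_log_or_per_10 %||% config$adi_log_or_per_10
    terms <- linear_terms(cohort[idx, , drop = FALSE], beta) +
      b_adi * cohort$adi[idx] / 10 +
      u[as.character(cohort$tract_id[idx])]
    alpha <- calibrate_intercept(terms, blk$target_prevalence)
    eta[idx] <- alpha + terms
  }
  cohort$acn <- as.integer(stats::runif(nrow(cohort)) < inv_logit(eta))
  rownames(cohort) <- NULL
  list(tracts = tracts, cohort = cohort)
}

## Per-subject linear-predictor contributions of a named coefficient map.
linear_terms <- function(d, beta) {
  out <- numeric(nrow(d))
  for (nm in names(beta)) {
    x <- switch(nm,
      race_aa = as.numeric(d$race == "AA"),
      sex_male = as.numeric(d$sex == "male"),
      age = d$age,
      bmi = d$bmi,
      family_history_fdr = d$family_history_fdr,
      smoking_years = d$smoking_years,
      diabetes = d$diabetes,
      calcium_use = d$calcium_use,
      red_meat_per_week = d$red_meat_per_week,
      alcohol_per_week = d$alcohol_per_week,
      stop("unknown coefficient name: ", nm)
    )
    out <- out + beta[[nm]] * x
  }
  out
}

#' @export
print.acn_generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  Tracts: %d (factor loading %.3f, PC1 share %.1f%%)\n",
              x$n_tracts, x$factor_loading,
              100 * loading_to_pc1_share(x$factor_loading)))
  for (nm in names(x$race_blocks)) {
    b <- x$race_blocks[[nm]]
    cat(sprintf(
      "  %s: n=%d, target prevalence %.1f%%, target ADI %.1f (SD %.1f)\n",
      nm, b$n_subjects, 100 * b$target_prevalence,
      b$adi_target_mean, b$adi_target_sd))
  }
  cat(sprintf("  Tract random-intercept SD: %.3f; master seed: %d\n",
              x$tract_sigma, x$seed))
  invisible(x)
}
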
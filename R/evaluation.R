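## Univariate screening statistics and model-performance metrics:
## discrimination (C-statistic, with bootstrap CI), calibration
## (Hosmer-Lemeshow over risk deciles or deprivation quantiles) and the
## prevalence trend test across ordered groups.

#' Univariate association screen of cohort covariates with the outcome
#'
#' For binary covariates, the Pearson chi-square test without continuity
#' correction; for continuous covariates, the Welch (unequal-variance)
#' t-test.  The odds ratio and its 95% Wald CI come from a one-covariate
#' logistic fit.  Covariates stored as character/factor or taking only the
#' values 0/1 are treated as binary.
#'
#' @param data cohort data frame.
#' @param outcome binary outcome column name (default `"acn"`).
#' @param variables covariate column names to screen; defaults to the
#'   canonical cohort covariates present in `data`.
#' @return data frame of class `acn_univariate` with one row per variable:
#'   `variable`, `test` ("chi-square" or "welch-t"), `statistic`, `p`,
#'   `or`, `or_lo`, `or_hi`.
#' @export
univariate_screen <- function(data, outcome = "acn",
                              variables = intersect(
                                c("race", "sex", "age", "bmi",
                                  "family_history_fdr", "smoking_years",
                                  "diabetes", "calcium_use",
                                  "red_meat_per_week", "alcohol_per_week",
                                  "adi"),
                                names(data))) {
  y <- data[[outcome]]
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2)
      stop("variable has fewer than 2 observed values: ", v)
    is_binary <- is.character(x) || is.factor(x) ||
      all(x %in% c(0, 1))
    if (is_binary) {
      xf <- factor(x)
      tab <- table(xf, y)
      xnum <- as.numeric(xf) - 1
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("degenerate table margin for ", v,
                "; Fisher exact fallback used")
        tst <- stats::fisher.test(tab)
        stat <- NA_real_; pv <- tst$p.value
        test <- "fisher-exact"
      } else {
        tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        stat <- unname(tst$statistic); pv <- tst$p.value
        test <- "chi-square"
      }
    } else {
      tst <- stats::t.test(x[y == 1], x[y == 0], var.equal = FALSE)
      xnum <- x
      stat <- unname(tst$statistic); pv <- tst$p.value
      test <- "welch-t"
    }
    d1 <- data.frame(.y = y, .x = xnum)
    orfit <- fit_logistic(.y ~ .x, d1)
    b <- orfit$coefficients[".x"]; se <- orfit$se[".x"]
    data.frame(variable = v, test = test, statistic = stat, p = pv,
               or = exp(b), or_lo = exp(b - 1.96 * se),
               or_hi = exp(b + 1.96 * se), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("acn_univariate", "data.frame")
  out
}

#' Concordance statistic (area under the ROC curve)
#'
#' The probability that a randomly chosen event has a higher predicted risk
#' than a randomly chosen non-event, with ties counted half:
#' (concordant + 0.5 tied) / (n_events * n_nonevents).  Computed via mean
#' ranks, equivalent to exhaustive pairwise enumeration.
#'
#' @param pred numeric risk predictions.
#' @param y binary outcomes (0/1).
#' @return value in \[0, 1\].
#' @export
c_statistic <- function(pred, y) {
  y <- as.integer(y)
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0)
    stop("C-statistic undefined: outcome has a single class")
  r <- rank(pred, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the C-statistic
#'
#' Applies a fitted prediction model to `B` bootstrap resamples of the
#' subjects (sampling rows with replacement, recomputing predictions and
#' the concordance statistic each time) and reports the 2.5 and 97.5
#' percentile bounds.  Resamples in which the outcome collapses to a
#' single class are redrawn and the redraw count reported.
#'
#' @param model an `acn_logit` (or any object with a `predict` method
#'   returning probabilities).
#' @param data cohort data frame.
#' @param outcome binary outcome column name.
#' @param B bootstrap replicates (default 2000, minimum 100).
#' @param seed integer seed.
#' @return list with `point`, `lower`, `upper`, `B`, `redraws`.
#' @export
c_statistic_ci <- function(model, data, outcome = "acn", B = 2000L,
                           seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  y <- data[[outcome]]
  pred <- stats::predict(model, data, type = "response")
  point <- c_statistic(pred, y)
  set.seed(child_seed(seed, 61L))
  n <- length(y)
  cs <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      redraws <- redraws + 1L
    }
    cs[b] <- c_statistic(pred[idx], y[idx])
  }
  q <- unname(stats::quantile(cs, c(0.025, 0.975), type = 7))
  list(point = point, lower = q[1], upper = q[2], B = B, redraws = redraws)
}

#' Hosmer-Lemeshow calibration test
#'
#' Groups subjects by deciles of predicted risk (default) or by supplied
#' labels (e.g. deprivation quantiles), and computes
#' \deqn{H = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g / n_g)}}
#' with \eqn{O_g} observed events and \eqn{E_g} the sum of predicted risks
#' in group \eqn{g}; the reference is chi-square with \eqn{G - 2} degrees
#' of freedom.  Decile cut points with ties are merged (df adjusted).
#'
#' @param pred predicted risk probabilities.
#' @param y binary outcomes.
#' @param groups optional explicit group labels (overrides decile grouping).
#' @param Q number of risk-quantile groups when `groups` is NULL
#'   (default 10).
#' @return object of class `acn_calibration`: list with `table` (per-group
#'   `n`, `observed`, `mean_pred`, `expected`), `statistic`, `df`, `p`,
#'   and `grouping` descriptor.
#' @export
hosmer_lemeshow <- function(pred, y, groups = NULL, Q = 10L) {
  stopifnot(length(pred) == length(y))
  if (is.null(groups)) {
    br <- unique(stats::quantile(pred, probs = seq(0, 1, length.out = Q + 1),
                                 type = 7))
    if (length(br) < 4)
      stop("fewer than 3 groups after merging tied cut points")
    groups <- cut(pred, breaks = br, include.lowest = TRUE)
    grouping <- sprintf("risk-quantile (Q=%d, %d after tie-merging)",
                        Q, length(br) - 1L)
  } else {
    grouping <- "explicit labels"
  }
  g <- factor(groups)
  if (nlevels(g) < 3) stop("at least 3 groups are required")
  n_g <- as.vector(tapply(y, g, length))
  O_g <- as.vector(tapply(y, g, sum))
  E_g <- as.vector(tapply(pred, g, sum))
  if (any(E_g <= 0) || any(E_g >= n_g))
    stop("degenerate group with expected events 0 or n; merge groups")
  H <- sum((O_g - E_g)^2 / (E_g * (1 - E_g / n_g)))
  df <- nlevels(g) - 2L
  structure(list(
    table = data.frame(group = levels(g), n = n_g, observed = O_g,
                       mean_pred = E_g / n_g, expected = E_g),
    statistic = H, df = df,
    p = stats::pchisq(H, df, lower.tail = FALSE),
    grouping = grouping
  ), class = "acn_calibration")
}

#' @export
print.acn_calibration <- function(x, ...) {
  cat("Hosmer-Lemeshow calibration,", x$grouping, "\n")
  print(transform(x$table, mean_pred = round(mean_pred, 4),
                  expected = round(expected, 2)), row.names = FALSE)
  cat(sprintf("H = %.3f on %d df, P = %.4f\n", x$statistic, x$df, x$p))
  invisible(x)
}

#' Observed vs predicted calibration plot
#'
#' Plots each group's observed event rate against its mean predicted risk
#' with the identity line, the layout used to inspect calibration across
#' deprivation quantiles.
#'
#' @param x an `acn_calibration` object.
#' @param ... passed to [plot()].
#' @export
plot.acn_calibration <- function(x, ...) {
  tb <- x$table
  obs <- tb$observed / tb$n
  lim <- range(0, obs, tb$mean_pred) * 1.05
  plot(obs, tb$mean_pred, xlim = lim, ylim = lim,
       xlab = "Observed event rate", ylab = "Mean predicted risk",
       pch = 19, ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Calibration across quantiles of a grouping variable
#'
#' Cuts a numeric grouping variable (typically the Area Deprivation Index)
#' at its sample quantiles into `Q` groups and evaluates Hosmer-Lemeshow
#' calibration of the predictions across those groups.
#'
#' @param pred predicted risk probabilities.
#' @param y binary outcomes.
#' @param group_var numeric variable to cut (e.g. ADI).
#' @param Q number of quantile groups (default 4).
#' @return an `acn_calibration` object (groups ordered by `group_var`).
#' @export
calibration_by_quantile <- function(pred, y, group_var, Q = 4L) {
  if (Q < 2) stop("Q must be >= 2")
  br <- unique(stats::quantile(group_var,
                               probs = seq(0, 1, length.out = Q + 1),
                               type = 7))
  if (length(br) < 3)
    stop("too few distinct values to form ", Q, " groups")
  g <- cut(group_var, breaks = br, include.lowest = TRUE)
  out <- hosmer_lemeshow(pred, y, groups = g)
  out$grouping <- sprintf("quantiles of grouping variable (Q=%d)", Q)
  out
}

#' Cochran-Armitage trend test of prevalence across ordered groups
#'
#' Tests for a linear trend in event prevalence across ordered groups with
#' integer scores 1..Q; returns the signed Z statistic and the two-sided
#' P value.
#'
#' @param y binary outcomes.
#' @param ordered_group_index integer (or ordered factor) group membership.
#' @return list with `z`, `p`, and the per-group prevalence table.
#' @export
trend_test <- function(y, ordered_group_index) {
  g <- if (is.factor(ordered_group_index)) as.integer(ordered_group_index)
       else as.integer(factor(ordered_group_index,
                              levels = sort(unique(ordered_group_index))))
  Q <- max(g)
  if (Q < 3) stop("at least 3 ordered groups are required")
  s <- seq_len(Q)
  n_g <- as.vector(tapply(y, g, length))
  e_g <- as.vector(tapply(y, g, sum))
  N <- sum(n_g); p_bar <- sum(e_g) / N
  num <- sum(s * (e_g - n_g * p_bar))
  den <- p_bar * (1 - p_bar) * (sum(n_g * s^2) - sum(n_g * s)^2 / N)
  z <- num / sqrt(den)
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       table = data.frame(group = s, n = n_g, events = e_g,
                          prevalence = e_g / n_g))
}
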
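## Fixed-effects logistic regression machinery implemented from first
## principles: iteratively reweighted least squares with step-halving,
## Wald tests, fast backward elimination and Nagelkerke pseudo-R^2.

## Core IRLS fitter on a numeric design matrix (first column need not be an
## intercept; callers decide).  Convergence: max |score| < 1e-8 or relative
## log-likelihood change < 1e-10, at most `maxit` iterations.
irls_logistic <- function(X, y, maxit = 100L) {
  n <- nrow(X); p <- ncol(X)
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: y contains a single class")
  if (n <= p)
    stop("more model terms than subjects")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  beta <- numeric(p)
  ic <- match("(Intercept)", colnames(X))
  if (!is.na(ic)) beta[ic] <- logit(mean(y))
  eta <- drop(X %*% beta)
  ll <- sum(bernoulli_loglik(y, eta))
  converged <- FALSE
  last_delta <- Inf
  for (it in seq_len(maxit)) {
    mu <- inv_logit(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break  # information singular (saturated fit)
    ## step-halving to guarantee likelihood ascent
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(bernoulli_loglik(y, eta_new))
      if (ll_new >= ll - 1e-12 || lam < 1e-10) break
      lam <- lam / 2
    }
    last_delta <- ll_new - ll
    rel <- abs(ll_new - ll) / (abs(ll) + 0.1)
    beta <- beta_new; eta <- eta_new; ll <- ll_new
    if (rel < 1e-10) { converged <- TRUE; break }
  }
  mu <- inv_logit(eta)
  info <- crossprod(X, X * (mu * (1 - mu)))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  separation <- any(abs(beta) > 10) && last_delta > 0
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(vc), 0))
  z <- beta / se
  list(coefficients = beta, vcov = vc, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       log_likelihood = ll, n = n, converged = converged,
       separation_flag = separation, fitted = mu, linear_predictor = eta)
}

#' Fit a logistic regression model by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with a formula interface.  The
#' fitter is an IRLS loop with step-halving (guaranteeing likelihood
#' ascent), convergence declared when the maximal score component falls
#' below 1e-8 or the relative log-likelihood change below 1e-10 (at most
#' 100 iterations).  Wald tests use the normal reference, two-sided.  A
#' `separation_flag` is set when any coefficient exceeds 10 in absolute
#' value while the likelihood is still improving at termination, the
#' signature of (quasi-)complete separation.
#'
#' @param formula model formula with a binary (0/1 or logical) response.
#' @param data data frame.
#' @return object of class `acn_logit` with components `coefficients`,
#'   `vcov`, `se`, `z`, `p_value`, `log_likelihood`,
#'   `null_log_likelihood` (intercept-only), `n`, `converged`,
#'   `separation_flag`, and bookkeeping for [predict.acn_logit()].
#' @examples
#' sim <- generate_cohort(ea_generator_config(seed = 3))
#' fit <- fit_logistic(acn ~ age + bmi + smoking_years, sim$cohort)
#' summary(fit)
#' @export
fit_logistic <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- irls_logistic(X, y)
  null_ll <- sum(bernoulli_loglik(y, logit(mean(y))))
  out <- c(fit, list(
    null_log_likelihood = null_ll,
    formula = formula,
    terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    y = y
  ))
  class(out) <- "acn_logit"
  out
}

#' @export
print.acn_logit <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$n, "\n")
  print(round(x$coefficients, 4))
  if (x$separation_flag) cat("warning: possible separation\n")
  invisible(x)
}

#' @export
summary.acn_logit <- function(object, ...) {
  tab <- cbind(
    estimate = object$coefficients,
    se = object$se,
    z = object$z,
    `p` = object$p_value,
    OR = exp(object$coefficients),
    `OR 2.5%` = exp(object$coefficients - 1.96 * object$se),
    `OR 97.5%` = exp(object$coefficients + 1.96 * object$se)
  )
  out <- list(table = tab, log_likelihood = object$log_likelihood,
              null_log_likelihood = object$null_log_likelihood,
              nagelkerke_r2 = nagelkerke_r2(object), n = object$n,
              converged = object$converged,
              separation_flag = object$separation_flag)
  class(out) <- "summary.acn_logit"
  out
}

#' @export
print.summary.acn_logit <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$n, "\n")
  print(round(x$table, 4))
  cat(sprintf("log-likelihood %.3f (null %.3f), Nagelkerke R^2 %.3f\n",
              x$log_likelihood, x$null_log_likelihood, x$nagelkerke_r2))
  invisible(x)
}

#' @export
coef.acn_logit <- function(object, ...) object$coefficients

#' @export
vcov.acn_logit <- function(object, ...) object$vcov

#' @export
logLik.acn_logit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' Predict from a fitted logistic model
#'
#' @param object an `acn_logit` fit.
#' @param newdata data frame; when omitted, the training fitted values are
#'   returned.
#' @param type `"response"` (probabilities) or `"link"` (log-odds).
#' @param ... unused.
#' @export
predict.acn_logit <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictor
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail,
                             xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients[colnames(X)])
  }
  if (type == "link") eta else inv_logit(eta)
}

#' @export
residuals.acn_logit <- function(object,
                                type = c("deviance", "pearson",
                                         "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted; y <- object$y
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) *
      sqrt(-2 * bernoulli_loglik(y, object$linear_predictor))
  )
}

#' @export
simulate.acn_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- as.data.frame(
    matrix(stats::rbinom(length(mu) * nsim, 1L, mu), ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Nagelkerke pseudo-R-squared of a fitted logistic model
#'
#' Cox-Snell \eqn{R^2_{CS} = 1 - \exp\{(2/n)(\ell_0 - \ell_1)\}} rescaled
#' by its maximum attainable value \eqn{1 - \exp\{(2/n)\ell_0\}} so the
#' statistic can reach 1.
#'
#' @param fit an `acn_logit` fit.
#' @return the rescaled pseudo-R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit) {
  stopifnot(inherits(fit, "acn_logit"))
  if (!fit$converged) warning("fit did not converge; R^2 may be unreliable")
  n <- fit$n
  r2_cs <- 1 - exp((2 / n) * (fit$null_log_likelihood - fit$log_likelihood))
  r2_max <- 1 - exp((2 / n) * fit$null_log_likelihood)
  r2_cs / r2_max
}

#' Fast backward elimination at a Wald significance threshold
#'
#' Starting from the full model on all candidate terms, repeatedly removes
#' the non-forced term with the largest two-sided Wald P value among those
#' with P above `alpha`, refitting after each removal, until every
#' non-forced term has P at or below `alpha`.  Forced terms are never
#' removed.  Ties in Wald P are broken lexicographically by term name, so
#' the result does not depend on the input ordering of candidates.
#'
#' @param data data frame containing the outcome and candidate columns.
#' @param outcome name of the binary outcome column (default `"acn"`).
#' @param candidates character vector of candidate model terms (column
#'   names; factors expand via the usual treatment contrasts).
#' @param forced subset of `candidates` that may never be eliminated.
#' @param alpha Wald P-value threshold for retention (default 0.10).
#' @return list with `selected` (character vector of surviving terms, in
#'   candidate order) and `fit` (the final `acn_logit`).
#' @export
backward_eliminate <- function(data, outcome = "acn", candidates,
                               forced = character(), alpha = 0.10) {
  if (!all(forced %in% candidates))
    stop("forced terms must be a subset of candidates")
  current <- candidates
  repeat {
    fml <- stats::reformulate(if (length(current)) current else "1",
                              response = outcome)
    fit <- fit_logistic(fml, data)
    ## map each term to its worst (largest) P over the columns it generates
    asg <- attr(stats::model.matrix(fit$terms,
                                    stats::model.frame(fit$terms, data)),
                "assign")
    labs <- attr(fit$terms, "term.labels")
    pv <- vapply(seq_along(labs), function(j)
      max(fit$p_value[asg == j]), numeric(1))
    names(pv) <- labs
    removable <- setdiff(labs, forced)
    over <- removable[pv[removable] > alpha]
    if (!length(over)) return(list(selected = current, fit = fit))
    over <- over[order(-pv[over], over)]  # largest P, then lexicographic
    current <- setdiff(current, over[1])
  }
}

#' Serialize and restore fitted logistic models
#'
#' `write_model()` writes an `acn_logit` fit to a JSON file (term names,
#' coefficients, covariance matrix, formula and factor levels), so a model
#' developed in one population can be applied to another cohort.
#' `read_model()` restores it; the restored object supports
#' [predict.acn_logit()] on any data frame with the required columns.
#'
#' @param fit an `acn_logit` fit.
#' @param path file path.
#' @return `read_model()` returns an `acn_logit`-classed object.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "acn_logit"))
  obj <- list(
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov,
    formula = deparse(fit$formula),
    xlevels = fit$xlevels,
    n = fit$n,
    log_likelihood = fit$log_likelihood,
    null_log_likelihood = fit$null_log_likelihood
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fml <- stats::as.formula(paste(obj$formula, collapse = " "))
  cf <- unlist(obj$coefficients)
  vc <- as.matrix(obj$vcov)
  dimnames(vc) <- list(names(cf), names(cf))
  xlev <- obj$xlevels
  if (is.null(xlev)) xlev <- list()
  xlev <- lapply(xlev, as.character)
  out <- list(
    coefficients = cf, vcov = vc,
    se = sqrt(pmax(diag(vc), 0)),
    formula = fml,
    terms = stats::terms(fml),
    xlevels = xlev,
    n = obj$n,
    log_likelihood = obj$log_likelihood,
    null_log_likelihood = obj$null_log_likelihood,
    converged = TRUE, separation_flag = FALSE
  )
  class(out) <- "acn_logit"
  out
}
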
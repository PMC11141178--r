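## Random-intercept logistic regression by adaptive Gauss-Hermite
## quadrature (AGQ), the two-stage deprivation augmentation model, the
## likelihood-ratio test and the tract-level variance-partition statistic.

## Posterior modes of the standardized random effects a_i (b_i = sigma a_i)
## by vectorized Newton iterations; the per-cluster integrand is strictly
## log-concave so undamped Newton converges.
cluster_modes <- function(eta0, y, cl, n_cl, sigma, a = numeric(n_cl)) {
  for (it in 1:50) {
    eta <- eta0 + sigma * a[cl]
    mu <- inv_logit(eta)
    grad <- sigma * rowsum_vec(y - mu, cl, n_cl) - a
    hess <- sigma^2 * rowsum_vec(mu * (1 - mu), cl, n_cl) + 1
    step <- grad / hess
    a <- a + step
    if (max(abs(grad)) < 1e-10) break
  }
  list(a = a, curv = hess)
}

rowsum_vec <- function(x, cl, n_cl) {
  out <- numeric(n_cl)
  s <- rowsum(x, cl, reorder = FALSE)
  out[as.integer(rownames(s))] <- s
  out
}

## AGQ-approximated marginal log-likelihood for fixed parameters.
agq_loglik <- function(beta, sigma, X, y, cl, n_cl, gh) {
  eta0 <- drop(X %*% beta)
  md <- cluster_modes(eta0, y, cl, n_cl, sigma)
  a_hat <- md$a
  curv <- pmax(md$curv, 1e-10)
  scale_i <- sqrt(2 / curv)
  q <- length(gh$nodes)
  G <- matrix(0, n_cl, q)
  for (k in seq_len(q)) {
    a_k <- a_hat + scale_i * gh$nodes[k]
    eta <- eta0 + sigma * a_k[cl]
    G[, k] <- rowsum_vec(bernoulli_loglik(y, eta), cl, n_cl) +
      stats::dnorm(a_k, log = TRUE) +
      log(gh$weights[k]) + gh$nodes[k]^2
  }
  M <- apply(G, 1, max)
  sum(M + log(rowSums(exp(G - M))) + log(scale_i))
}

#' Random-intercept logistic regression via adaptive Gauss-Hermite
#' quadrature
#'
#' Fits \eqn{\mathrm{logit}\,P(y_{ij}=1) = x_{ij}'\beta + u_i},
#' \eqn{u_i \sim N(0, \sigma_u^2)} over clusters \eqn{i} (census tracts).
#' The marginal likelihood of each cluster is approximated by adaptive
#' Gauss-Hermite quadrature: a Newton search locates the cluster's
#' posterior mode and curvature and the quadrature nodes are re-centred
#' and re-scaled accordingly.  The outer maximization over the fixed
#' coefficients and the log random-effect SD uses a quasi-Newton
#' (L-BFGS-B) search with numeric gradients; standard errors come from
#' the numeric Hessian at the optimum.
#'
#' @param formula fixed-effects formula with a binary response.
#' @param data data frame.
#' @param cluster name of the cluster-id column in `data`.
#' @param q_points number of quadrature points (default 10).
#' @param fix_sigma optionally fix the random-effect SD and maximize only
#'   the fixed effects (used for profile diagnostics).
#' @param start optional start values for the fixed coefficients.
#' @return object of class `acn_mixed` with components `coefficients`,
#'   `se`, `vcov` (fixed-effect block), `tract_sd`, `tract_variance`,
#'   `log_likelihood`, `q_points`, `n_clusters`, `n`, `converged`,
#'   `boundary_flag` (random-effect variance pinned at the zero boundary).
#' @examples
#' sim <- generate_cohort(ea_generator_config(n_tracts = 60,
#'   race_blocks = list(EA = ea_race_block(n_subjects = 300)), seed = 2))
#' fit <- fit_random_intercept_logistic(acn ~ age, sim$cohort, "tract_id",
#'                                      q_points = 5)
#' @export
fit_random_intercept_logistic <- function(formula, data, cluster,
                                          q_points = 10L,
                                          fix_sigma = NULL,
                                          start = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  if (length(unique(y)) < 2) stop("outcome has a single class")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  cl_f <- factor(data[[cluster]])
  if (nlevels(cl_f) < 2) stop("at least 2 clusters are required")
  cl <- as.integer(cl_f)
  n_cl <- nlevels(cl_f)
  gh <- gauss_hermite(q_points)
  p <- ncol(X)

  if (is.null(start)) {
    start <- irls_logistic(X, y)$coefficients
  }
  lo_ls <- log(1e-6); hi_ls <- log(10)

  if (is.null(fix_sigma)) {
    par0 <- c(start, log(0.3))
    negll <- function(par)
      -agq_loglik(par[1:p], exp(par[p + 1]), X, y, cl, n_cl, gh)
    opt <- stats::optim(par0, negll, method = "L-BFGS-B",
                        lower = c(rep(-Inf, p), lo_ls),
                        upper = c(rep(Inf, p), hi_ls),
                        control = list(maxit = 500L, factr = 1e6,
                                       ndeps = rep(1e-5, p + 1)))
    beta <- opt$par[1:p]
    sigma <- unname(exp(opt$par[p + 1]))
    converged <- opt$convergence == 0
  } else {
    sigma <- fix_sigma
    negll <- function(b) -agq_loglik(b, sigma, X, y, cl, n_cl, gh)
    opt <- stats::optim(start, negll, method = "BFGS",
                        control = list(maxit = 500L, reltol = 1e-12,
                                       ndeps = rep(1e-5, p)))
    beta <- opt$par
    converged <- opt$convergence == 0
  }
  if (!converged)
    warning("outer optimization did not report convergence (code ",
            opt$convergence, ")")
  ll <- -opt$value
  boundary <- sigma < 1e-3
  ## numeric Hessian for the fixed-effect block
  nll_beta <- function(b) -agq_loglik(b, sigma, X, y, cl, n_cl, gh)
  H <- stats::optimHess(beta, nll_beta)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vc), 0))
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  structure(list(
    coefficients = beta, se = se, vcov = vc,
    tract_sd = if (boundary) 0 else sigma,
    tract_variance = if (boundary) 0 else sigma^2,
    log_likelihood = ll,
    q_points = as.integer(q_points),
    n_clusters = n_cl, n = length(y),
    converged = converged, boundary_flag = boundary,
    formula = formula, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    cluster = cluster
  ), class = "acn_mixed")
}

#' @export
print.acn_mixed <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic regression (AGQ, %d points), %d clusters\n",
    x$q_points, x$n_clusters))
  print(round(x$coefficients, 4))
  cat(sprintf("tract SD %.4f (variance %.4f)%s; log-likelihood %.3f\n",
              x$tract_sd, x$tract_variance,
              if (x$boundary_flag) " [zero boundary]" else "",
              x$log_likelihood))
  invisible(x)
}

#' @export
coef.acn_mixed <- function(object, ...) object$coefficients

#' @export
vcov.acn_mixed <- function(object, ...) object$vcov

#' @export
logLik.acn_mixed <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients) + 1L,
            nobs = object$n, class = "logLik")
}

#' Marginal predictions from a random-intercept logistic fit
#'
#' Population-level probabilities with the random intercept integrated out
#' by Gauss-Hermite quadrature over \eqn{N(0, \hat\sigma_u^2)}.
#'
#' @param object an `acn_mixed` fit.
#' @param newdata data frame (required).
#' @param type `"response"` or `"link"` (the fixed-effect linear
#'   predictor).
#' @param ... unused.
#' @export
predict.acn_mixed <- function(object, newdata,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail,
                           xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  eta <- drop(X %*% object$coefficients[colnames(X)])
  if (type == "link") return(eta)
  if (object$tract_sd == 0) return(inv_logit(eta))
  gh <- gauss_hermite(object$q_points)
  w <- gh$weights / sqrt(pi)
  p <- numeric(length(eta))
  for (k in seq_along(gh$nodes))
    p <- p + w[k] * inv_logit(eta + sqrt(2) * object$tract_sd * gh$nodes[k])
  p
}

#' Likelihood-ratio test of nested mixed models
#'
#' @param full,null `acn_mixed` fits on the same data, the null's fixed
#'   terms a strict subset of the full's.
#' @return list with `statistic` (twice the log-likelihood difference),
#'   `df` (difference in fixed-term count) and `p` (chi-square upper
#'   tail).
#' @export
lrt_nested <- function(full, null) {
  stopifnot(inherits(full, "acn_mixed"), inherits(null, "acn_mixed"))
  if (full$n != null$n)
    stop("models were fitted to different data")
  if (!all(names(null$coefficients) %in% names(full$coefficients)))
    stop("null model terms are not nested in the full model")
  stat <- 2 * (full$log_likelihood - null$log_likelihood)
  if (stat < -1e-6)
    stop("optimization failure: full model log-likelihood below null")
  stat <- max(stat, 0)
  df <- length(full$coefficients) - length(null$coefficients)
  p <- if (df == 0) (if (stat == 0) 1 else NA_real_)
       else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Share of cluster-level variance explained by a cluster-level covariate
#'
#' The proportion of census-tract-level variation in risk accounted for by
#' the added covariate: `(var_null - var_full) / var_null`, where the two
#' variances are the random-intercept variances of the mixed fits without
#' and with the covariate.  The share can be negative in finite samples
#' (the full model's tract variance exceeding the null's); it is then
#' returned raw with a warning.
#'
#' @param var_null,var_full random-intercept variances of the null and
#'   full fits.
#' @return the variance share (fraction).
#' @export
variance_partition <- function(var_null, var_full) {
  if (var_null <= 0)
    stop("undefined proportion: null-model cluster variance is zero")
  share <- (var_null - var_full) / var_null
  if (share < 0)
    warning("negative variance share: full-model cluster variance ",
            "exceeds the null's")
  share
}

#' Two-stage augmentation of base-model risk with the deprivation index
#'
#' Fits the mixed-effects augmentation model
#' \deqn{\mathrm{logit}\,P(y=1) = \alpha + \beta_1 (\hat p_{base}/0.1) +
#'       \beta_2 (ADI/10) + u_{tract}}
#' with exactly two fixed covariates: the base model's predicted risk in
#' units of 0.1 (absolute probability scale) and the Area Deprivation
#' Index in units of 10.  Also fits the null model without ADI (for the
#' likelihood-ratio test and the tract-level variance partition) and the
#' model without the base prediction (for the base term's LRT).
#'
#' @param base_predictions base-model predicted probabilities in (0, 1).
#' @param adi ADI scores in \[0, 100\].
#' @param y binary outcomes.
#' @param cluster_ids census-tract identifiers.
#' @param q_points quadrature points (default 10).
#' @return object of class `acn_augmented`: list with `or_base_per_0p1`
#'   and `or_adi_per_10` (each a vector of `or`, `lo`, `hi`, `p` where
#'   `p` is the likelihood-ratio P value for dropping that term),
#'   `tract_variance` and `tract_variance_null`, `variance_partition`,
#'   and the three underlying `acn_mixed` fits (`fit_full`, `fit_null`,
#'   `fit_nobase`).
#' @export
augment_with_adi <- function(base_predictions, adi, y, cluster_ids,
                             q_points = 10L) {
  if (any(base_predictions <= 0 | base_predictions >= 1))
    stop("base predictions must lie strictly in (0, 1)")
  if (any(adi < 0 | adi > 100)) stop("ADI scores must lie in [0, 100]")
  if (stats::sd(base_predictions) == 0)
    stop("degenerate covariate: base predictions are constant")
  d <- data.frame(.y = as.integer(y),
                  risk01 = base_predictions / 0.1,
                  adi10 = adi / 10,
                  .cl = cluster_ids)
  full <- fit_random_intercept_logistic(.y ~ risk01 + adi10, d, ".cl",
                                        q_points = q_points)
  null <- fit_random_intercept_logistic(.y ~ risk01, d, ".cl",
                                        q_points = q_points)
  nobase <- fit_random_intercept_logistic(.y ~ adi10, d, ".cl",
                                          q_points = q_points)
  lrt_adi <- lrt_nested(full, null)
  lrt_base <- lrt_nested(full, nobase)
  ci <- function(fit, term) {
    b <- fit$coefficients[term]; s <- fit$se[term]
    c(or = unname(exp(b)), lo = unname(exp(b - 1.96 * s)),
      hi = unname(exp(b + 1.96 * s)))
  }
  vp <- if (null$tract_variance > 0)
    (null$tract_variance - full$tract_variance) / null$tract_variance
  else NA_real_
  structure(list(
    or_base_per_0p1 = c(ci(full, "risk01"), p = lrt_base$p),
    or_adi_per_10 = c(ci(full, "adi10"), p = lrt_adi$p),
    lrt_adi = lrt_adi,
    negative_share_flag = isTRUE(vp < 0),
    tract_variance = full$tract_variance,
    tract_variance_null = null$tract_variance,
    variance_partition = vp,
    fit_full = full, fit_null = null, fit_nobase = nobase
  ), class = "acn_augmented")
}

#' @export
print.acn_augmented <- function(x, ...) {
  fmt <- function(v, lab) cat(sprintf(
    "  %-28s OR %.2f (95%% CI %.2f to %.2f), LRT P = %.3g\n",
    lab, v[["or"]], v[["lo"]], v[["hi"]], v[["p"]]))
  cat("Mixed-effects augmentation of base risk with ADI\n")
  fmt(x$or_base_per_0p1, "base predicted risk (per 0.1)")
  fmt(x$or_adi_per_10, "ADI (per 10 units)")
  cat(sprintf("  tract variance: null %.4f, full %.4f; ADI share %.1f%%\n",
              x$tract_variance_null, x$tract_variance,
              100 * x$variance_partition))
  invisible(x)
}
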
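## L1-penalized logistic regression by coordinate descent on the IRLS
## quadratic approximation, with AUC-based stratified cross-validation.
## Used as a redundancy check on the predictors chosen by the bootstrap
## stability procedure.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

## Penalized fit at a single lambda on standardized X (no intercept column;
## intercept unpenalized).  Objective: (1/n) loglik - lambda * sum |beta_j|.
lasso_fit_one <- function(Xs, y, lambda, beta0, b0, maxit = 200L) {
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- beta0; b <- b0
  for (outer in seq_len(maxit)) {
    eta <- b + drop(Xs %*% beta)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    beta_old <- beta; b_old <- b
    ## coordinate descent on the weighted least-squares surrogate
    for (inner in 1:50) {
      changed <- 0
      r <- z - b - drop(Xs %*% beta)
      b_new <- b + sum(w * r) / sum(w)
      r <- r - (b_new - b); b <- b_new
      for (j in seq_len(p)) {
        xj <- Xs[, j]
        rho <- sum(w * xj * (r + xj * beta[j])) / n
        denom <- sum(w * xj * xj) / n
        bj <- soft_threshold(rho, lambda) / denom
        if (bj != beta[j]) {
          r <- r - xj * (bj - beta[j])
          changed <- changed + abs(bj - beta[j])
          beta[j] <- bj
        }
      }
      if (changed < 1e-8) break
    }
    if (max(abs(beta - beta_old)) < 1e-7 && abs(b - b_old) < 1e-7) break
  }
  list(beta = beta, intercept = b)
}

#' Cross-validated LASSO logistic regression
#'
#' L1-penalized logistic regression solved by coordinate descent on the
#' iteratively reweighted least-squares quadratic approximation, with the
#' covariates standardized (mean 0, SD 1) and the intercept unpenalized.
#' The penalty grid is log-spaced over three decades down from
#' `lambda_max`, the smallest penalty at which all coefficients are zero.
#' The penalty is chosen by stratified k-fold cross-validation maximizing
#' the mean out-of-fold area under the ROC curve (C-statistic); ties are
#' broken toward the larger penalty (the sparser model).
#'
#' @param data data frame with the outcome and predictor columns.
#' @param outcome binary outcome column name.
#' @param predictors character vector of numeric predictor column names.
#' @param folds number of cross-validation folds (default 3).
#' @param seed integer seed controlling the fold assignment.
#' @param n_lambda grid size (default 40).
#' @return object of class `acn_lasso_cv`: list with `lambda_grid`
#'   (decreasing), `cv_auc` (mean fold AUC per lambda), `chosen_lambda`,
#'   `nonzero_set` (predictors with nonzero standardized coefficient at the
#'   chosen penalty), and `coefficients` (standardized scale, full data).
#' @export
fit_lasso_cv <- function(data, outcome = "acn", predictors, folds = 3L,
                         seed = 1L, n_lambda = 40L) {
  if (folds < 2) stop("folds must be >= 2")
  y <- data[[outcome]]
  X <- as.matrix(data[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd) * sqrt((n - 1) / n)
  if (any(sds == 0)) stop("constant predictor(s): ",
                          paste(predictors[sds == 0], collapse = ", "))
  Xs <- scale(X, center = colMeans(X), scale = sds)
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-3),
                         length.out = n_lambda))
  ## stratified folds: events and non-events allocated separately
  set.seed(child_seed(seed, 41L))
  fold_id <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds)
      stop("stratification error: a class has fewer members than folds")
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  cv_auc <- matrix(NA_real_, folds, n_lambda)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
      stop("stratification error: single-class fold")
    beta <- numeric(ncol(Xs)); b <- logit(mean(y[tr]))
    for (l in seq_len(n_lambda)) {
      fit <- lasso_fit_one(Xs[tr, , drop = FALSE], y[tr],
                           lambda_grid[l], beta, b)
      beta <- fit$beta; b <- fit$intercept  # warm start
      eta_te <- fit$intercept + drop(Xs[!tr, , drop = FALSE] %*% fit$beta)
      cv_auc[f, l] <- c_statistic(inv_logit(eta_te), y[!tr])
    }
  }
  mean_auc <- colMeans(cv_auc)
  best <- which(mean_auc >= max(mean_auc) - 1e-12)[1]  # ties -> larger lambda
  ## full-data path down to the chosen lambda
  beta <- numeric(ncol(Xs)); b <- logit(mean(y))
  for (l in seq_len(best)) {
    fit <- lasso_fit_one(Xs, y, lambda_grid[l], beta, b)
    beta <- fit$beta; b <- fit$intercept
  }
  names(beta) <- predictors
  structure(list(
    lambda_grid = lambda_grid,
    cv_auc = mean_auc,
    chosen_lambda = lambda_grid[best],
    nonzero_set = predictors[abs(beta) > 1e-8],
    coefficients = beta,
    intercept = b,
    folds = folds
  ), class = "acn_lasso_cv")
}

#' @export
print.acn_lasso_cv <- function(x, ...) {
  cat(sprintf(
    "LASSO logistic regression, %d-fold CV on AUC\n", x$folds))
  cat(sprintf("  chosen lambda %.5f (mean AUC %.3f)\n", x$chosen_lambda,
              max(x$cv_auc)))
  cat("  nonzero predictors:",
      if (length(x$nonzero_set)) paste(x$nonzero_set, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
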
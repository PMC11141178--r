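#' @keywords internal
"_PACKAGE"

## Numerically safe inverse logit / log-likelihood helpers used across the
## fitting routines.

logit <- function(p) log(p) - log1p(-p)

inv_logit <- function(x) stats::plogis(x)

## Bernoulli log-likelihood contributions, stable for large |eta|:
## y*eta - log(1 + exp(eta)).
bernoulli_loglik <- function(y, eta) {
  y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Gauss-Hermite nodes and weights
#'
#' Nodes \eqn{t_k} and weights \eqn{w_k} of the physicists' Gauss-Hermite
#' rule, so that \eqn{\int e^{-t^2} g(t)\,dt \approx \sum_k w_k g(t_k)}.
#' Computed by the Golub-Welsch eigenvalue method on the symmetric Jacobi
#' matrix of the Hermite recurrence.
#'
#' @param q number of quadrature points (>= 1).
#' @return list with components `nodes` and `weights`, each of length `q`.
#' @examples
#' gh <- gauss_hermite(2)   # nodes +/- 1/sqrt(2), weights sqrt(pi)/2
#' @export
gauss_hermite <- function(q) {
  q <- as.integer(q)
  if (q < 1) stop("q must be >= 1")
  if (q == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(q - 1) / 2)
  J <- diag(0, q)
  J[cbind(seq_len(q - 1), seq_len(q - 1) + 1L)] <- off
  J[cbind(seq_len(q - 1) + 1L, seq_len(q - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

## Child seeds: one master seed, fixed per-stage offsets.  Offsets are
## documented in the generator configuration help page.
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

## Truncated-normal draws by rejection-free inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
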
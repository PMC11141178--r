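#' Area Deprivation Index from census-tract socioeconomic indicators
#'
#' Constructs a composite deprivation score for each census tract as the
#' first principal component of the tract-level socioeconomic indicators,
#' oriented so that deprivation increases the score and scaled to the
#' range 0--100.
#'
#' Each indicator column is standardized to mean 0 and unit SD, the
#' correlation-matrix eigendecomposition is taken, and tract scores are the
#' projections onto the leading eigenvector.  The sign of the eigenvector is
#' chosen so that the designated poverty-proxy column loads positively
#' (poverty is the anchor of deprivation), with a deterministic lexicographic
#' fallback when the poverty loading is numerically zero.  Scores are then
#' either min-max scaled (default) or percentile-rank scaled to \[0, 100\].
#'
#' @param tracts data frame with a `tract_id` column and the indicator
#'   columns named in `indicators`.
#' @param indicators character vector of indicator column names; defaults to
#'   `v1`..`v17`, the schema produced by [generate_tracts()].
#' @param poverty_var name of the poverty-proxy column used to orient the
#'   index (default `"v1"`, the generator's convention).
#' @param scaling `"minmax"` (sample minimum to 0, maximum to 100) or
#'   `"percentile"` (percentile ranks times 100).
#' @return object of class `adi_index`: a list with `adi_by_tract` (named
#'   numeric vector of scores in \[0,100\] keyed by `tract_id`), `loadings`
#'   (unit-norm leading eigenvector, named by indicator),
#'   `pc1_variance_share` (leading eigenvalue divided by the number of
#'   indicators), and `dominant_variable` (indicator with largest absolute
#'   loading).
#' @examples
#' tr <- generate_tracts(generator_config(n_tracts = 50), seed = 1)
#' adi <- compute_adi(tr)
#' adi$pc1_variance_share
#' @export
compute_adi <- function(tracts, indicators = paste0("v", 1:17),
                        poverty_var = indicators[1],
                        scaling = c("minmax", "percentile")) {
  scaling <- match.arg(scaling)
  missing_cols <- setdiff(indicators, names(tracts))
  if (length(missing_cols))
    stop("indicator columns missing from tract table: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tracts) < 2)
    stop("at least 2 tracts are required to compute the index")
  X <- as.matrix(tracts[, indicators, drop = FALSE])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance indicator column(s): ",
         paste(indicators[sds == 0], collapse = ", "))
  Z <- scale(X)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  if (ncol(R) > 1 && abs(e$values[1] - e$values[2]) < 1e-12) {
    warning("leading eigenvalues tied within 1e-12; ",
            "tie broken deterministically by lexicographic eigenvector sign")
  }
  v <- e$vectors[, 1]
  names(v) <- indicators
  ## orient: deprivation (poverty) increases the score
  pov <- v[[poverty_var]]
  if (abs(pov) > 1e-12) {
    if (pov < 0) v <- -v
  } else {
    nz <- which(abs(v) > 1e-12)[1]
    if (length(nz) && v[nz] < 0) v <- -v
  }
  scores <- drop(Z %*% v)
  rng <- range(scores)
  if (rng[2] - rng[1] < .Machine$double.eps)
    stop("degenerate scores: all tracts identical on the leading component")
  adi <- switch(scaling,
    minmax = 100 * (scores - rng[1]) / (rng[2] - rng[1]),
    percentile = 100 * (rank(scores, ties.method = "average") - 1) /
      (length(scores) - 1)
  )
  names(adi) <- as.character(tracts$tract_id)
  structure(list(
    adi_by_tract = adi,
    loadings = v,
    pc1_variance_share = e$values[1] / length(indicators),
    dominant_variable = indicators[which.max(abs(v))],
    scaling = scaling
  ), class = "adi_index")
}

#' @export
print.adi_index <- function(x, ...) {
  cat("Area Deprivation Index (first principal component of",
      length(x$loadings), "indicators)\n")
  cat(sprintf("  PC1 variance share : %.1f%%\n", 100 * x$pc1_variance_share))
  cat(sprintf("  Dominant indicator : %s (loading %.3f)\n",
              x$dominant_variable, x$loadings[[x$dominant_variable]]))
  cat(sprintf("  Tracts scored      : %d (scaling: %s)\n",
              length(x$adi_by_tract), x$scaling))
  invisible(x)
}
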
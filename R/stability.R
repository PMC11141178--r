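## Bootstrap model-selection: candidate screening, repeated bootstrap
## resampling each followed by backward elimination, selection-frequency
## accounting and the final-predictor rule.

#' Screen candidate predictors by univariate association
#'
#' Returns the union of the covariates with univariate association P < 0.10
#' (chi-square for binary, Welch t for continuous covariates) and the
#' forced set of established risk factors, which enter as candidates
#' regardless of their univariate significance.
#'
#' @param data cohort data frame.
#' @param outcome binary outcome column name.
#' @param forced character vector of always-included candidates; defaults
#'   to the established colorectal-cancer risk factors (sex, BMI, alcohol,
#'   smoking, family history in first-degree relatives, red meat).
#' @param alpha univariate screening threshold (default 0.10).
#' @param variables covariates to screen (defaults to the canonical
#'   individual-level covariates present in `data`).
#' @return character vector of candidate column names (screened order,
#'   forced terms appended).
#' @export
screen_candidates <- function(data, outcome = "acn",
                              forced = c("sex", "bmi", "alcohol_per_week",
                                         "smoking_years",
                                         "family_history_fdr",
                                         "red_meat_per_week"),
                              alpha = 0.10,
                              variables = intersect(
                                c("sex", "age", "bmi",
                                  "family_history_fdr", "smoking_years",
                                  "diabetes", "calcium_use",
                                  "red_meat_per_week", "alcohol_per_week"),
                                names(data))) {
  unknown <- setdiff(forced, names(data))
  if (length(unknown))
    stop("unknown forced term(s): ", paste(unknown, collapse = ", "))
  uni <- univariate_screen(data, outcome = outcome, variables = variables)
  hits <- uni$variable[uni$p < alpha]
  union(hits, forced)
}

## Matrix-level backward elimination used inside the bootstrap loop: the
## full design is built once, resamples only index rows, elimination drops
## columns.  Column 1 is the intercept and is never removable.
backward_eliminate_cols <- function(X, y, forced_cols, alpha) {
  keep <- seq_len(ncol(X))
  repeat {
    fit <- irls_logistic(X[, keep, drop = FALSE], y)
    pv <- fit$p_value
    nm <- colnames(X)[keep]
    removable <- which(!(keep %in% forced_cols) & keep != 1L)
    over <- removable[pv[removable] > alpha]
    if (!length(over)) return(list(keep = keep, fit = fit))
    ord <- order(-pv[over], nm[over])
    keep <- keep[-over[ord[1]]]
  }
}

#' Bootstrap selection frequencies of candidate predictors
#'
#' For each of `B` bootstrap resamples (same number of subjects, drawn
#' with replacement), fits the full candidate logistic model and applies
#' backward elimination at the Wald threshold `alpha`; each candidate's
#' selection count is the number of resamples in which it survives.
#' Resamples where the fit fails (single-class outcome, separation or a
#' singular design) are redrawn so `B` is exact; the redraw count is
#' reported.  The whole procedure is deterministic given `seed`.
#'
#' @param data cohort data frame.
#' @param outcome binary outcome column name.
#' @param candidates character vector of candidate predictor columns.
#' @param forced candidates never eliminated.
#' @param B bootstrap replicates (default 1000).
#' @param alpha Wald elimination threshold (default 0.10).
#' @param seed integer seed.
#' @return object of class `acn_stability`: list with `candidates`,
#'   `selection_count`, `frequency`, `sorted_frequencies` (descending,
#'   named), `B`, `alpha`, `seed`, `redraws`.
#' @export
bootstrap_frequencies <- function(data, outcome = "acn", candidates,
                                  forced = character(), B = 1000L,
                                  alpha = 0.10, seed = 1L) {
  if (!length(candidates)) stop("candidates must be non-empty")
  if (!all(forced %in% candidates))
    stop("forced terms must be a subset of candidates")
  fml <- stats::reformulate(candidates, response = outcome)
  mf <- stats::model.frame(fml, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  asg <- attr(X, "assign")
  labs <- attr(attr(mf, "terms"), "term.labels")
  forced_cols <- which(asg %in% which(labs %in% forced))
  counts <- integer(length(labs))
  names(counts) <- labs
  set.seed(child_seed(seed, 21L))
  n <- nrow(X)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch({
        r <- backward_eliminate_cols(X[idx, , drop = FALSE], y[idx],
                                     forced_cols, alpha)
        if (r$fit$separation_flag) stop("separation")
        r
      }, error = function(e) NULL)
      if (!is.null(res)) break
      redraws <- redraws + 1L
      if (redraws > 0.2 * B)
        stop("data pathology: more than 20% of bootstrap fits failed")
    }
    surv <- unique(asg[res$keep])
    surv <- surv[surv > 0]
    counts[surv] <- counts[surv] + 1L
  }
  freq <- counts / B
  sorted <- sort(freq, decreasing = TRUE)
  ## deterministic order among ties: lexicographic by name
  ties <- order(-freq, names(freq))
  sorted <- freq[ties]
  structure(list(
    candidates = labs,
    selection_count = counts,
    frequency = freq,
    sorted_frequencies = sorted,
    B = as.integer(B), alpha = alpha, seed = as.integer(seed),
    redraws = redraws
  ), class = "acn_stability")
}

#' @export
print.acn_stability <- function(x, ...) {
  cat(sprintf("Bootstrap stability selection: B = %d, alpha = %.2f\n",
              x$B, x$alpha))
  print(round(x$sorted_frequencies, 3))
  if (x$redraws) cat(x$redraws, "failed resamples were redrawn\n")
  invisible(x)
}

#' Final-predictor rule from bootstrap selection frequencies
#'
#' The base set contains every candidate with selection frequency strictly
#' above `threshold`.  With the drop rule enabled, the sorted frequency
#' sequence is scanned for the largest drop between consecutive
#' frequencies whose upper side lies below the threshold; when such a drop
#' exists, all candidates above it are added (capturing a cluster of
#' just-below-threshold predictors separated from the rest by a big gap).
#' Ties and the all-equal plateau produce no extension.
#'
#' @param result an `acn_stability` object.
#' @param threshold frequency threshold (default 0.4).
#' @param drop_rule enable the frequency-drop extension (default TRUE).
#' @return character vector of final predictors (candidate order).
#' @export
choose_final_predictors <- function(result, threshold = 0.4,
                                    drop_rule = TRUE) {
  stopifnot(inherits(result, "acn_stability"))
  freq <- result$frequency
  base <- names(freq)[freq > threshold]
  chosen <- base
  if (drop_rule) {
    f <- result$sorted_frequencies
    if (length(f) > 1) {
      gaps <- f[-length(f)] - f[-1]
      eligible <- which(f[-length(f)] <= threshold & gaps > 0)
      if (length(eligible)) {
        i_star <- eligible[which.max(gaps[eligible])]
        chosen <- union(base, names(f)[seq_len(i_star)])
      }
    }
  }
  result$candidates[result$candidates %in% chosen]
}
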
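#' @include AllClasses.R
NULL

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n-k-1)`; reduces to the AIC as
#' `n -> Inf`. Requires `n - k - 1 > 0`.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k parameter count (intercept + slopes + residual variance).
#' @param n sample size.
#' @return The AICc value.
#' @export
aiccScore <- function(log_likelihood, k, n) {
  if (n - k - 1 <= 0)
    .mmiStop("smallSampleError", "AICc undefined: need n > k + 1 (n=%d, k=%d)",
             n, k)
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Ordinary least squares fit of a predictor subset
#'
#' Fits `y ~ intercept + X[, subset]` exactly (QR), and scores the fit the
#' way the model-selection stage needs: Gaussian maximum-likelihood
#' log-likelihood `-(n/2) * (log(2*pi*rss/n) + 1)`, AICc with
#' `k = |subset| + 2` (intercept, slopes, residual variance), and adjusted
#' R-squared `1 - (1 - R2)(n - 1)/(n - p - 1)`. The empty subset is the
#' intercept-only model (`R2 = 0`, `adjR2 = 0`).
#'
#' Numerically zero RSS (noiseless data) yields a fit flagged `degenerate`
#' with `logLik = +Inf` and `AICc = -Inf` rather than an error, so noiseless
#' limits propagate through selection correctly.
#'
#' @param X numeric predictor matrix with column names (standardize columns
#'   before the all-subsets search; see [compareDataset()]).
#' @param y response vector.
#' @param subset character vector of column names (possibly empty).
#' @return A [LinearModelFit-class].
#' @export
fitOLS <- function(X, y, subset = character(0)) {
  n <- length(y)
  p <- length(subset)
  if (n <= p + 2L)
    .mmiStop("smallSampleError",
             "need n > p + 2 to fit %d predictor(s) on %d samples", p, n)
  if (p > 0 && !all(subset %in% colnames(X)))
    .mmiStop("invalidArgumentError", "unknown predictor(s): %s",
             paste(setdiff(subset, colnames(X)), collapse = ", "))
  design <- cbind(`(Intercept)` = rep(1, n),
                  X[, subset, drop = FALSE])
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    .mmiStop("singularDesignError",
             "design matrix rank-deficient for subset {%s}",
             paste(subset, collapse = ", "))
  coefs <- qr.coef(qrd, y)
  fitted <- qr.fitted(qrd, y)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0)
    .mmiStop("noVariationError", "response has zero variance")
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  k <- p + 2L
  degenerate <- rss <= tss * 1e-12
  if (degenerate) {
    ll <- Inf
    aicc <- -Inf
  } else {
    ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
    aicc <- aiccScore(ll, k, n)
  }
  new("LinearModelFit",
      predictors = as.character(subset),
      coefficients = coefs,
      rss = rss, n = as.integer(n), k = k,
      logLik = ll, aicc = aicc, r2 = r2, adjR2 = min(adj, 1),
      degenerate = degenerate)
}

#' All-subsets model fitting
#'
#' Fits one OLS model per subset of the candidate predictors up to
#' `max_terms` terms, always including the intercept-only model, for
#' `sum_{i=0..max_terms} choose(p, i)` candidates. Rank-deficient subsets are
#' skipped and reported in the `"skipped"` attribute. A hard guard refuses
#' more than 20 candidates (over a million subsets) — reduce the predictor
#' pool first.
#'
#' `max_terms` defaults to `min(p, max(1, floor(n/10)))`, a 1-in-10 rule that
#' keeps candidate models small relative to the sample size; it is further
#' capped at `n - 3` so every candidate satisfies the fitting precondition.
#'
#' @param X standardized predictor matrix.
#' @param y response vector.
#' @param predictors candidate column names (default: all columns of `X`).
#' @param max_terms largest subset size searched.
#' @return List of [LinearModelFit-class], in deterministic order (by subset
#'   size, then lexicographic enumeration).
#' @export
allSubsets <- function(X, y, predictors = colnames(X), max_terms = NULL) {
  p <- length(predictors)
  n <- length(y)
  if (p > 20L)
    .mmiStop("tooManyPredictorsError",
             "%d candidate predictors exceed the all-subsets guard (20); reduce the pool first",
             p)
  if (is.null(max_terms)) max_terms <- min(p, max(1L, n %/% 10L))
  if (max_terms < 0)
    .mmiStop("invalidArgumentError", "max_terms must be >= 0")
  max_terms <- min(max_terms, p, n - 3L)
  fits <- list(fitOLS(X, y, character(0)))
  skipped <- character(0)
  for (size in seq_len(max_terms)) {
    subsets <- combn(predictors, size, simplify = FALSE)
    for (s in subsets) {
      f <- tryCatch(fitOLS(X, y, s),
                    singularDesignError = function(e) NULL)
      if (is.null(f)) skipped <- c(skipped, paste(s, collapse = "+"))
      else fits[[length(fits) + 1L]] <- f
    }
  }
  attr(fits, "skipped") <- skipped
  attr(fits, "max_terms") <- max_terms
  fits
}

## Deterministic fit ordering: AICc, then fewer predictors, then
## lexicographic predictor names.
.orderFits <- function(fits) {
  aiccs <- vapply(fits, function(f) f@aicc, numeric(1))
  sizes <- vapply(fits, function(f) length(f@predictors), integer(1))
  keys <- vapply(fits, function(f) paste(f@predictors, collapse = "|"),
                 character(1))
  order(aiccs, sizes, keys)
}

#' Truncate candidates to the delta-AICc model set
#'
#' Retains every fit whose AICc lies within `threshold` (inclusive, default
#' 4) of the minimum, computes the AICc differences, and assigns Akaike
#' weights `exp(-delta/2)` renormalized over the retained set. Ties are
#' broken deterministically (smaller model first, then lexicographic
#' predictor order).
#'
#' @param fits list of [LinearModelFit-class] (e.g. from [allSubsets()]).
#' @param threshold delta-AICc retention threshold.
#' @return A [ModelSet-class].
#' @export
selectModelSet <- function(fits, threshold = 4) {
  if (!length(fits))
    .mmiStop("invalidArgumentError", "no fits supplied")
  fits <- fits[.orderFits(fits)]
  aiccs <- vapply(fits, function(f) f@aicc, numeric(1))
  best <- aiccs[1L]
  if (is.infinite(best)) {
    ## noiseless limit: only degenerate (rss = 0) fits compete
    keep <- is.infinite(aiccs)
    fits <- fits[keep]
    m <- length(fits)
    return(new("ModelSet", fits = fits, delta = rep(0, m),
               weights = rep(1 / m, m), threshold = threshold))
  }
  delta <- aiccs - best
  keep <- delta <= threshold + 1e-12
  fits <- fits[keep]
  delta <- delta[keep]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  new("ModelSet", fits = fits, delta = delta, weights = w,
      threshold = threshold)
}

#' Akaike-weight model averaging
#'
#' Produces the averaged final model of a [ModelSet-class]. Under the default
#' full-average convention the averaged coefficient of predictor `j` is
#' `sum_i w_i * beta_ij` with `beta_ij = 0` whenever predictor `j` is absent
#' from model `i` (shrinkage toward zero for weakly supported predictors);
#' the conditional convention divides instead by the summed weight of the
#' models containing `j`. Predictions come from the averaged coefficients,
#' and the adjusted R-squared of those predictions is penalized by the size
#' of the predictor union across the retained models — a conservative choice,
#' recorded in the object. When the union is larger than `n - 2` the adjusted
#' R-squared is undefined (`NA`) and the model is flagged.
#'
#' A one-model set reproduces that model exactly.
#'
#' @param model_set a [ModelSet-class].
#' @param X the standardized predictor matrix used for the fits.
#' @param y the response.
#' @param mode `"full"` (default) or `"conditional"` averaging.
#' @return An [AveragedModel-class].
#' @export
averageModel <- function(model_set, X, y, mode = c("full", "conditional")) {
  mode <- match.arg(mode)
  fits <- model_set@fits
  w <- model_set@weights
  union <- colnames(X)[colnames(X) %in%
                         unique(unlist(lapply(fits, function(f) f@predictors)))]
  terms <- c("(Intercept)", union)
  B <- matrix(0, length(fits), length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    B[i, c("(Intercept)", f@predictors)] <- f@coefficients
  }
  beta <- if (mode == "full") {
    colSums(B * w)
  } else {
    present <- matrix(FALSE, length(fits), length(terms),
                      dimnames = list(NULL, terms))
    for (i in seq_along(fits))
      present[i, c("(Intercept)", fits[[i]]@predictors)] <- TRUE
    denom <- colSums(present * w)
    colSums(B * w) / ifelse(denom > 0, denom, 1)
  }
  n <- length(y)
  preds <- drop(beta[1L] +
                  (if (length(union))
                    X[, union, drop = FALSE] %*% beta[-1L] else 0))
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - preds)^2) / tss
  p_eff <- length(union)
  note <- character(0)
  if (p_eff > n - 2L) {
    adj <- NA_real_
    note <- "predictor union exceeds n - 2: adjusted R2 undefined"
  } else {
    adj <- 1 - (1 - r2) * (n - 1) / (n - p_eff - 1)
  }
  new("AveragedModel",
      coefficients = beta,
      predictions = setNames(preds, names(y)),
      adjR2 = adj, r2 = r2,
      bestAICc = fits[[1L]]@aicc,
      nModels = length(fits),
      predictorUnion = union,
      mode = mode,
      note = note)
}

#' Full model-selection run for one predictor set
#'
#' Convenience wrapper chaining [allSubsets()], [selectModelSet()] and
#' [averageModel()].
#'
#' @param X standardized predictor matrix.
#' @param y response.
#' @param predictors candidate columns.
#' @param delta_threshold delta-AICc retention threshold.
#' @param max_terms largest subset size searched.
#' @param mode averaging convention.
#' @return List with `fits`, `model_set` and `averaged`.
#' @export
runModelSelection <- function(X, y, predictors = colnames(X),
                              delta_threshold = 4, max_terms = NULL,
                              mode = "full") {
  fits <- allSubsets(X, y, predictors, max_terms)
  ms <- selectModelSet(fits, delta_threshold)
  list(fits = fits, model_set = ms,
       averaged = averageModel(ms, X, y, mode = mode))
}
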
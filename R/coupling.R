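#' @include community.R
NULL

#' Redundancy-analysis R-squared
#'
#' The fraction of total variance of a (column-centered) multivariate
#' response explained by a set of constraint variables:
#' `r2 = trace(SS_fitted) / trace(SS_total)` from column-wise least squares
#' of `Y` on `X`, with the Ezekiel adjustment
#' `adj_r2 = 1 - (1 - r2)(n - 1)/(n - q - 1)` for `q` constraints. With a
#' single response column this is exactly the multiple-regression R-squared.
#'
#' @param Y response matrix or vector (centered internally).
#' @param X constraint matrix or vector.
#' @return List with `r2` and `adj_r2`.
#' @export
rdaR2 <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n)
    .mmiStop("alignmentError", "Y and X must have the same rows")
  q <- ncol(X)
  if (n <= q + 1L)
    .mmiStop("smallSampleError", "need n > q + 1 (n=%d, q=%d)", n, q)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  qrd <- qr(cbind(1, X))
  if (qrd$rank < q + 1L)
    .mmiStop("singularConstraintsError", "constraint matrix is rank-deficient")
  tot <- sum(Yc^2)
  if (tot <= 0)
    .mmiStop("noVariationError", "response matrix has no variation")
  fitted <- qr.fitted(qrd, Yc)
  r2 <- sum(fitted^2) / tot
  r2 <- min(max(r2, 0), 1)
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - q - 1))
}

## Orthonormal basis of span(1, X) beyond the intercept; NULL when X adds
## nothing. Used to turn fitted sums of squares into cheap cross-products.
.constraintBasis <- function(X) {
  n <- nrow(X)
  qrd <- qr(cbind(1, X))
  r <- qrd$rank
  if (r < 2L) return(NULL)
  qr.Q(qrd)[, 2:r, drop = FALSE]
}

#' Permutation test for adding one constraint to an RDA
#'
#' Tests whether `x_candidate` explains response variance beyond the current
#' constraints. Both response and candidate are residualized on
#' `[1, X_current]`; the statistic is the incremental explained sum of
#' squares of the residualized response on the residualized candidate. The
#' candidate's rows are permuted `n_perm` times under a fixed seed and the
#' p-value is `(1 + #{permuted >= observed}) / (1 + n_perm)`, so the smallest
#' attainable p with 999 permutations is 1/1000.
#'
#' @param Y response matrix or vector.
#' @param X_current matrix of already-selected constraints (or `NULL`).
#' @param x_candidate candidate constraint vector.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return List with `p`, `gain` (incremental R-squared) and
#'   `n_permutations`.
#' @export
rdaPermutationTest <- function(Y, X_current, x_candidate, n_perm = 999,
                               seed = 1L) {
  if (n_perm < 99)
    .mmiStop("invalidArgumentError", "n_perm must be >= 99")
  Y <- as.matrix(Y)
  x <- as.numeric(x_candidate)
  n <- nrow(Y)
  if (length(x) != n)
    .mmiStop("alignmentError", "candidate length must match Y rows")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  tot <- sum(Yc^2)
  base <- if (is.null(X_current) || NCOL(X_current) == 0)
    matrix(1, n, 1L) else cbind(1, as.matrix(X_current))
  qrd <- qr(base)
  RY <- qr.resid(qrd, Yc)
  rx <- qr.resid(qrd, x)
  ssrx <- sum(rx^2)
  obs <- if (ssrx > tot * 1e-12)
    sum(crossprod(RY, rx)^2) / ssrx else 0
  perm_idx <- withSeed(seed,
                       replicate(n_perm, sample.int(n), simplify = TRUE))
  XP <- matrix(x[perm_idx], n, n_perm)
  RXP <- qr.resid(qrd, XP)
  den <- colSums(RXP^2)
  num <- colSums(crossprod(RY, RXP)^2)
  stat <- ifelse(den > tot * 1e-12, num / den, 0)
  p <- (1 + sum(stat >= obs - 1e-12)) / (1 + n_perm)
  list(p = p, gain = obs / tot, n_permutations = n_perm)
}

#' Forward selection of RDA constraints by permutation tests
#'
#' Automated forward selection of environmental constraints for a redundancy
#' analysis, following the two-safeguard procedure that keeps stepwise
#' constrained ordination honest: (1) a global permutation test of the
#' all-constraints model (permuting response rows) must reject at `alpha`
#' before any selection starts — without it, screening several candidates
#' inflates the family-wise selection rate on pure noise far above `alpha`;
#' (2) optionally (`double_stop`), a selected model's adjusted R-squared may
#' not exceed the all-constraints model's. At each step every remaining
#' candidate gets a marginal permutation test ([rdaPermutationTest()]); the
#' candidate with the largest adjusted-R-squared gain among those with
#' `p <= alpha` is added, and selection stops when no candidate qualifies.
#'
#' @param Y response matrix (e.g. Hellinger-transformed community table) or
#'   vector (e.g. biomass).
#' @param X candidate constraint matrix with column names.
#' @param alpha permutation significance level.
#' @param n_perm permutations per test (>= 99).
#' @param seed master seed; per-test seeds are spawned deterministically.
#' @param global_test run the global pre-test (default `TRUE`).
#' @param double_stop also require the selected model's adjusted R-squared to
#'   stay at or below the all-constraints model's.
#' @return An `RdaResult`: list with `selected_constraints`, `r2`, `adj_r2`
#'   (both 0 when nothing is selected, flagged via `selection_empty`),
#'   per-step `permutation_pvalues`, `global_p`, `n_permutations`, `seed`.
#' @export
forwardSelectRDA <- function(Y, X, alpha = 0.05, n_perm = 999, seed = 1L,
                             global_test = TRUE, double_stop = FALSE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(Y)
  p <- ncol(X)
  if (p < 1L)
    .mmiStop("invalidArgumentError", "need at least one candidate constraint")
  seed_pool <- spawnSeeds(seed, (p + 1L) * (p + 2L))
  pool_at <- 0L
  nextSeed <- function() {
    pool_at <<- pool_at + 1L
    seed_pool[pool_at]
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  tot <- sum(Yc^2)
  if (tot <= 0)
    .mmiStop("noVariationError", "response matrix has no variation")

  full_ok <- n > p + 1L && qr(cbind(1, X))$rank == p + 1L
  full <- if (full_ok) rdaR2(Y, X) else NULL
  global_p <- NA_real_
  if (global_test && full_ok) {
    Q2 <- .constraintBasis(X)
    obs <- sum(crossprod(Q2, Yc)^2) / tot
    gseed <- nextSeed()
    perm_idx <- withSeed(gseed,
                         replicate(n_perm, sample.int(n), simplify = TRUE))
    stat <- vapply(seq_len(n_perm), function(b) {
      sum(crossprod(Q2, Yc[perm_idx[, b], , drop = FALSE])^2) / tot
    }, numeric(1))
    global_p <- (1 + sum(stat >= obs - 1e-12)) / (1 + n_perm)
    if (global_p > alpha) {
      return(structure(list(
        selected_constraints = character(0), r2 = 0, adj_r2 = 0,
        permutation_pvalues = numeric(0), global_p = global_p,
        n_permutations = n_perm, alpha = alpha, seed = seed,
        selection_empty = TRUE,
        note = "global permutation test not significant; no selection attempted"
      ), class = "RdaResult"))
    }
  }

  selected <- character(0)
  step_p <- numeric(0)
  cur_adj <- 0
  repeat {
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining) || n <= length(selected) + 2L) break
    Xcur <- if (length(selected)) X[, selected, drop = FALSE] else NULL
    cand <- lapply(remaining, function(v) {
      Xnew <- cbind(Xcur, X[, v])
      fit <- tryCatch(rdaR2(Y, Xnew), mmiError = function(e) NULL)
      if (is.null(fit)) return(NULL)
      pt <- rdaPermutationTest(Y, Xcur, X[, v], n_perm = n_perm,
                               seed = nextSeed())
      list(var = v, adj = fit$adj_r2, p = pt$p)
    })
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) break
    gains <- vapply(cand, function(cc) cc$adj - cur_adj, numeric(1))
    ps <- vapply(cand, function(cc) cc$p, numeric(1))
    ok <- ps <= alpha
    if (double_stop && !is.null(full))
      ok <- ok & vapply(cand, function(cc) cc$adj <= full$adj_r2 + 1e-12,
                        logical(1))
    if (!any(ok)) break
    pick <- which(ok)[which.max(gains[ok])]
    selected <- c(selected, cand[[pick]]$var)
    step_p <- c(step_p, ps[pick])
    cur_adj <- cand[[pick]]$adj
  }

  if (length(selected)) {
    fin <- rdaR2(Y, X[, selected, drop = FALSE])
    r2 <- fin$r2; adj <- fin$adj_r2
  } else {
    r2 <- 0; adj <- 0
  }
  structure(list(
    selected_constraints = selected, r2 = r2, adj_r2 = adj,
    permutation_pvalues = step_p, global_p = global_p,
    n_permutations = n_perm, alpha = alpha, seed = seed,
    selection_empty = !length(selected),
    note = if (!length(selected)) "no constraint passed forward selection"
           else NA_character_
  ), class = "RdaResult")
}

#' @export
print.RdaResult <- function(x, ...) {
  cat("RdaResult:",
      if (length(x$selected_constraints))
        paste(x$selected_constraints, collapse = " + ")
      else "(nothing selected)", "\n")
  cat(sprintf("  r2 = %.4f, adj r2 = %.4f, global p = %s\n",
              x$r2, x$adj_r2,
              if (is.na(x$global_p)) "NA" else format(x$global_p)))
  invisible(x)
}

#' Coupling between predictor sets for one dataset
#'
#' Quantifies how much variation in one predictor block is explained by
#' another, via [forwardSelectRDA()]: environment explaining community
#' structure, environment explaining biomass, and biomass explaining
#' community structure. "Community structure" is the Hellinger-transformed
#' community table by default (the constrained ordination describes the
#' community data themselves, not the condensed predictor axes); setting
#' `community_response = "axes"` switches to the ordination axis scores.
#' Functional-gene datasets use standardized log gene abundances as the
#' community response. A pairing whose blocks are absent is skipped and
#' listed in `skipped`; when selection is empty the coupling adjusted
#' R-squared is reported as 0 with the `selection_empty` flag.
#'
#' @param dataset a [ProcessDataset-class].
#' @param block the dataset's [PredictorBlock-class] (used for the `"axes"`
#'   response option).
#' @param alpha,n_perm forward-selection settings.
#' @param seed master seed (three child seeds are spawned, one per pairing).
#' @param community_response `"hellinger"` or `"axes"`.
#' @return List with `env_to_community`, `env_to_biomass`,
#'   `biomass_to_community` (each an `RdaResult` or `NULL`), `skipped`, and a
#'   flat `summary` of adjusted R-squared values.
#' @export
couplingReport <- function(dataset, block = NULL, alpha = 0.05, n_perm = 999,
                           seed = 1L,
                           community_response = c("hellinger", "axes")) {
  community_response <- match.arg(community_response)
  seeds <- spawnSeeds(seed, 3L)
  flavor <- datasetMetadata(dataset)$data_flavor
  Ycom <- if (community_response == "axes") {
    if (is.null(block)) block <- condensePredictors(dataset)
    if (ncol(axisScores(block))) axisScores(block)
    else scale(log(geneAbundances(block)), scale = FALSE)
  } else if (identical(flavor, "functional_gene")) {
    scale(log(communityData(dataset)), scale = FALSE)
  } else {
    hellingerTransform(communityData(dataset))
  }
  env <- envData(dataset)
  bio <- biomassData(dataset)
  skipped <- character(0)
  e2c <- forwardSelectRDA(Ycom, env, alpha = alpha, n_perm = n_perm,
                          seed = seeds[1L])
  e2b <- if (!is.null(bio))
    forwardSelectRDA(bio, env, alpha = alpha, n_perm = n_perm,
                     seed = seeds[2L])
  else {
    skipped <- c(skipped, "env_to_biomass")
    NULL
  }
  b2c <- if (!is.null(bio))
    forwardSelectRDA(Ycom, matrix(bio, ncol = 1L,
                                  dimnames = list(names(bio), "biomass")),
                     alpha = alpha, n_perm = n_perm, seed = seeds[3L])
  else {
    skipped <- c(skipped, "biomass_to_community")
    NULL
  }
  list(
    env_to_community = e2c,
    env_to_biomass = e2b,
    biomass_to_community = b2c,
    skipped = skipped,
    summary = list(
      env_to_community_adj_r2 = e2c$adj_r2,
      env_to_biomass_adj_r2 = if (is.null(e2b)) NA_real_ else e2b$adj_r2,
      biomass_to_community_adj_r2 = if (is.null(b2c)) NA_real_ else b2c$adj_r2
    )
  )
}
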
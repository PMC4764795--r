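test_that("AICc matches the closed form and its limits", {
  expect_equal(aiccScore(-25, 3, 20), 57.5, tolerance = 1e-12)  # 50 + 6 + 24/16
  expect_equal(aiccScore(0, 1, 4), 4, tolerance = 1e-12)        # 0 + 2 + 4/2
  expect_lt(abs(aiccScore(-10, 3, 1e9) - (20 + 6)), 1e-6)       # -> AIC
  expect_error(aiccScore(0, 5, 6), class = "smallSampleError")
})

test_that("OLS fits recover exact coefficients", {
  x <- seq(-2, 2, length.out = 25)
  y <- 3 + 2 * x
  X <- cbind(x = x)
  f <- fitOLS(X, y, "x")
  expect_equal(unname(f@coefficients), c(3, 2), tolerance = 1e-10)
  expect_equal(f@r2, 1, tolerance = 1e-12)
  expect_true(f@degenerate)
  expect_identical(f@aicc, -Inf)
  ## intercept-only model
  y2 <- withSeed(1, rnorm(25))
  f0 <- fitOLS(X, y2, character(0))
  expect_equal(unname(f0@coefficients), mean(y2), tolerance = 1e-12)
  expect_equal(f0@adjR2, 0, tolerance = 1e-12)
  ## duplicated column is rank-deficient
  X2 <- cbind(a = x, b = x)
  expect_error(fitOLS(X2, y2, c("a", "b")), class = "singularDesignError")
})

test_that("OLS coefficients match an independent normal-equations solve", {
  for (s in 1:10) {
    X <- withSeed(s, matrix(rnorm(30 * 5), 30, 5,
                            dimnames = list(NULL, paste0("v", 1:5))))
    y <- withSeed(s + 100, rnorm(30))
    sub <- paste0("v", sort(withSeed(s, sample(5, 3))))
    f <- fitOLS(X, y, sub)
    D <- cbind(1, X[, sub])
    beta <- drop(solve(crossprod(D), crossprod(D, y)))
    expect_equal(unname(f@coefficients), unname(beta), tolerance = 1e-8)
    expect_equal(f@rss, sum((y - D %*% beta)^2), tolerance = 1e-8)
    ## adjusted R2 equals the lm summary value
    sm <- summary(lm(y ~ X[, sub]))
    expect_equal(f@adjR2, sm$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("all-subsets enumeration has the binomial count", {
  X <- withSeed(2, matrix(rnorm(40 * 5), 40, 5,
                          dimnames = list(NULL, paste0("v", 1:5))))
  y <- withSeed(3, rnorm(40))
  expect_length(allSubsets(X[, 1:3], y, max_terms = 3), 8L)     # 2^3
  expect_length(allSubsets(X, y, max_terms = 2), 16L)           # 1 + 5 + 10
  expect_error(
    allSubsets(matrix(rnorm(40 * 21), 40, 21,
                      dimnames = list(NULL, paste0("v", 1:21))),
               y, max_terms = 2),
    class = "tooManyPredictorsError")
})

test_that("model-set truncation keeps the boundary and weights correctly", {
  mkFit <- function(aicc, preds = character(0)) {
    new("LinearModelFit", predictors = preds,
        coefficients = setNames(rep(0, length(preds) + 1),
                                c("(Intercept)", preds)),
        rss = 1, n = 20L, k = length(preds) + 2L, logLik = 0,
        aicc = aicc, r2 = 0.5, adjR2 = 0.5, degenerate = FALSE)
  }
  fits <- list(mkFit(100, "a"), mkFit(103.9, "b"), mkFit(104.1, "c"))
  ms <- selectModelSet(fits, threshold = 4)
  expect_length(modelFits(ms), 2L)                  # 104.1 excluded: delta 4.1
  expect_equal(deltaAICc(ms), c(0, 3.9), tolerance = 1e-12)
  ## delta = {0, 2}: weights 1/(1+e^-1), e^-1/(1+e^-1)
  ms2 <- selectModelSet(list(mkFit(10, "a"), mkFit(12, "b")))
  expect_equal(akaikeWeights(ms2), c(0.7310586, 0.2689414), tolerance = 1e-6)
  expect_equal(sum(akaikeWeights(ms2)), 1, tolerance = 1e-12)
  ## single model gets weight 1
  expect_equal(akaikeWeights(selectModelSet(list(mkFit(5, "a")))), 1)
  ## weights strictly decreasing in AICc
  expect_true(all(diff(akaikeWeights(ms2)) < 0))
})

test_that("model averaging satisfies its identities", {
  X <- withSeed(4, matrix(rnorm(50 * 4), 50, 4,
                          dimnames = list(NULL, paste0("v", 1:4))))
  y <- withSeed(5, drop(X %*% c(0.8, 0.4, 0, 0)) + rnorm(50))
  run <- runModelSelection(X, y, max_terms = 4)
  ms <- run$model_set
  am <- run$averaged
  ## averaged predictions = weight-weighted mean of per-model predictions
  w <- akaikeWeights(ms)
  pred_mix <- Reduce(`+`, lapply(seq_along(w), function(i) {
    f <- modelFits(ms)[[i]]
    D <- cbind(1, X[, f@predictors, drop = FALSE])
    w[i] * drop(D %*% f@coefficients)
  }))
  expect_equal(unname(am@predictions), pred_mix, tolerance = 1e-10)
  expect_equal(am@bestAICc, bestAICc(ms), tolerance = 1e-12)
  ## a one-model set reproduces the model exactly
  best <- modelFits(ms)[[1L]]
  one <- new("ModelSet", fits = list(best), delta = 0, weights = 1,
             threshold = 4)
  am1 <- averageModel(one, X, y)
  expect_equal(unname(averagedCoefficients(am1)), unname(best@coefficients),
               tolerance = 1e-12)
  expect_equal(adjR2(am1), best@adjR2, tolerance = 1e-12)
  ## linearity: equal-weight average of slopes 2 and 4 is 3
  mk <- function(slope) new("LinearModelFit", predictors = "v1",
                            coefficients = c(`(Intercept)` = 0, v1 = slope),
                            rss = 1, n = 50L, k = 3L, logLik = 0, aicc = 10,
                            r2 = 0.5, adjR2 = 0.5, degenerate = FALSE)
  two <- new("ModelSet", fits = list(mk(2), mk(4)), delta = c(0, 0),
             weights = c(0.5, 0.5), threshold = 4)
  avg2 <- averageModel(two, X, y)
  expect_equal(unname(averagedCoefficients(avg2)["v1"]), 3, tolerance = 1e-12)
})

test_that("least squares is monotone in nested predictor sets", {
  X <- withSeed(6, matrix(rnorm(40 * 6), 40, 6,
                          dimnames = list(NULL, paste0("v", 1:6))))
  y <- withSeed(7, drop(X[, 1:2] %*% c(1, 0.5)) + rnorm(40))
  for (j in 3:6) {
    small <- fitOLS(X, y, c("v1", "v2"))
    big <- fitOLS(X, y, c("v1", "v2", paste0("v", j)))
    expect_lte(big@rss, small@rss + 1e-12)
    expect_gte(big@r2, small@r2 - 1e-12)
  }
})

test_that("noiseless data recover the generating subset", {
  X <- withSeed(8, matrix(rnorm(30 * 5), 30, 5,
                          dimnames = list(NULL, paste0("v", 1:5))))
  y <- drop(X[, c(2, 4)] %*% c(1, -1)) + 5
  run <- runModelSelection(X, y, max_terms = 3)
  best <- modelFits(run$model_set)[[1L]]
  expect_true(all(c("v2", "v4") %in% best@predictors))
  expect_true(best@degenerate)
})

test_that("the full chain matches the brute-force oracle on random problems", {
  for (s in 1:8) {
    n <- 35
    p <- 6
    X <- withSeed(s * 11, matrix(rnorm(n * p), n, p,
                                 dimnames = list(NULL, paste0("v", 1:p))))
    y <- withSeed(s * 13,
                  drop(X %*% c(0.7, 0.3, 0, 0, 0.2, 0)) + rnorm(n))
    mt <- 3
    run <- runModelSelection(X, y, max_terms = mt)
    oracle <- bruteForceMMI(X, y, max_terms = mt)
    expect_length(run$fits, oracle$n_candidates)
    expect_identical(modelFits(run$model_set)[[1L]]@predictors,
                     oracle$best_subset)
    expect_identical(lapply(modelFits(run$model_set), slot, "predictors"),
                     oracle$retained_subsets)
    expect_equal(akaikeWeights(run$model_set), oracle$weights,
                 tolerance = 1e-10)
    expect_equal(averagedCoefficients(run$averaged),
                 oracle$averaged[names(averagedCoefficients(run$averaged))],
                 tolerance = 1e-10)
  }
})
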
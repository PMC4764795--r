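test_that("RDA R2 reduces to regression R2 and handles limit cases", {
  x <- withSeed(1, rnorm(30))
  expect_equal(rdaR2(x, x)$r2, 1, tolerance = 1e-12)
  ## constructed orthogonality
  y <- withSeed(2, rnorm(30))
  y_orth <- residuals(lm(y ~ x))
  expect_lt(rdaR2(y_orth, x)$r2, 1e-10)
  ## single response, multiple constraints: equals multiple-regression R2
  X <- withSeed(3, matrix(rnorm(40 * 4), 40, 4))
  yy <- withSeed(4, drop(X %*% c(0.5, 0.3, 0, 0)) + rnorm(40))
  out <- rdaR2(yy, X)
  sm <- summary(lm(yy ~ X))
  expect_equal(out$r2, sm$r.squared, tolerance = 1e-10)
  expect_equal(out$adj_r2, sm$adj.r.squared, tolerance = 1e-10)
  expect_lte(out$adj_r2, out$r2)
  expect_error(rdaR2(yy, cbind(X[, 1], X[, 1])),
               class = "singularConstraintsError")
})

test_that("multivariate RDA R2 agrees with vegan", {
  skip_if_not_installed("vegan")
  Y <- withSeed(5, matrix(rnorm(30 * 8), 30, 8))
  X <- withSeed(6, matrix(rnorm(30 * 3), 30, 3))
  ours <- rdaR2(Y, X)
  ref <- vegan::RsquareAdj(vegan::rda(Y ~ X))
  expect_equal(ours$r2, ref$r.squared, tolerance = 1e-10)
  expect_equal(ours$adj_r2, ref$adj.r.squared, tolerance = 1e-10)
})

test_that("the Ezekiel penalty grows with irrelevant constraints", {
  Y <- withSeed(7, matrix(rnorm(40 * 5), 40, 5))
  X1 <- withSeed(8, matrix(rnorm(40), 40, 1))
  X3 <- cbind(X1, withSeed(9, matrix(rnorm(80), 40, 2)))
  a1 <- rdaR2(Y, X1)
  a3 <- rdaR2(Y, X3)
  ## at (almost) fixed r2, more constraints mean a harsher adjustment
  expect_lt(a3$adj_r2 - a3$r2, a1$adj_r2 - a1$r2)
})

test_that("permutation tests are deterministic and floor at 1/(n_perm+1)", {
  Y <- withSeed(11, matrix(rnorm(40 * 6), 40, 6))
  p1 <- rdaPermutationTest(Y, NULL, Y[, 1], n_perm = 999, seed = 5)
  p2 <- rdaPermutationTest(Y, NULL, Y[, 1], n_perm = 999, seed = 5)
  expect_identical(p1, p2)
  ## candidate identical to a response column: smallest attainable p
  expect_equal(p1$p, 1 / 1000, tolerance = 1e-12)
  expect_error(rdaPermutationTest(Y, NULL, Y[, 1], n_perm = 50, seed = 1),
               class = "invalidArgumentError")
})

test_that("permutation p-values are calibrated under the null", {
  ## univariate pure-noise candidate, rejection rate ~ alpha
  rejections <- vapply(1:1000, function(s) withSeed(s, {
    y <- rnorm(30)
    x <- rnorm(30)
    rdaPermutationTest(y, NULL, x, n_perm = 199, seed = s)$p <= 0.05
  }), logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("forward selection finds a perfect constraint", {
  x <- withSeed(21, rnorm(40))
  X <- cbind(good = x, junk = withSeed(22, rnorm(40)))
  r <- forwardSelectRDA(x, X, seed = 23)
  expect_identical(r$selected_constraints[1], "good")
  expect_equal(r$r2, 1, tolerance = 1e-10)
  expect_false(r$selection_empty)
  expect_lte(r$permutation_pvalues[1], 0.05)
})

test_that("forward selection reports empty selections with a flag", {
  X <- withSeed(24, matrix(rnorm(50 * 5), 50, 5,
                           dimnames = list(NULL, paste0("x", 1:5))))
  y <- withSeed(25, rnorm(50))
  r <- forwardSelectRDA(y, X, seed = 26)
  ## this seed gives a null dataset; selection must come back empty & flagged
  expect_true(r$selection_empty)
  expect_equal(r$adj_r2, 0)
  expect_identical(r$selected_constraints, character(0))
  ## identical seed, identical outcome
  expect_identical(r, forwardSelectRDA(y, X, seed = 26))
  ## the double-stopping option still runs
  r2 <- forwardSelectRDA(y, X, seed = 26, double_stop = TRUE)
  expect_true(is.list(r2))
})

test_that("coupling report covers exactly the computable pairings", {
  ds <- generateDataset(tinyConfig(seed = 31, include_biomass = TRUE))
  cp <- couplingReport(ds, n_perm = 199, seed = 32)
  expect_named(cp$summary, c("env_to_community_adj_r2",
                             "env_to_biomass_adj_r2",
                             "biomass_to_community_adj_r2"))
  expect_length(cp$skipped, 0L)
  ds0 <- generateDataset(tinyConfig(seed = 33, include_biomass = FALSE))
  cp0 <- couplingReport(ds0, n_perm = 199, seed = 34)
  expect_setequal(cp0$skipped, c("env_to_biomass", "biomass_to_community"))
  expect_true(is.na(cp0$summary$env_to_biomass_adj_r2))
})

test_that("perfect coupling saturates the env-community relationship", {
  ## one env variable drives one latent axis exactly; with low taxon noise
  ## the leading ordination axis recovers it almost perfectly
  cfg <- simulationConfig(n_samples = 50, n_env = 1, n_taxa = 40,
                          n_latent_axes = 1, env_community_coupling = 1,
                          beta_env = 0.5, beta_community = 0.3,
                          include_biomass = FALSE, taxon_noise_sd = 0.1,
                          noise_sd = 0.5, seed = 41)
  ds <- generateDataset(cfg)
  cp <- couplingReport(ds, n_perm = 199, seed = 42,
                       community_response = "axes")
  expect_gte(cp$summary$env_to_community_adj_r2, 0.95)
})

test_that("uncoupled communities show near-zero coupling on average", {
  adj <- vapply(spawnSeeds(51, 60), function(s) {
    cfg <- simulationConfig(n_samples = 50, n_env = 3, n_taxa = 30,
                            n_latent_axes = 2, env_community_coupling = 0,
                            beta_env = c(0.5, 0.4, 0.3),
                            beta_community = c(0.2, 0.2),
                            include_biomass = FALSE, seed = s)
    ds <- generateDataset(cfg)
    couplingReport(ds, n_perm = 199,
                   seed = s)$summary$env_to_community_adj_r2
  }, numeric(1))
  expect_lte(mean(adj), 0.05)
})
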
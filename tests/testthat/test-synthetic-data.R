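test_that("generators are pure functions of their seed", {
  expect_identical(generateEnvironment(50, 3, seed = 1),
                   generateEnvironment(50, 3, seed = 1))
  expect_false(identical(generateEnvironment(50, 3, seed = 1),
                         generateEnvironment(50, 3, seed = 2)))
  cfg <- tinyConfig(seed = 7)
  expect_identical(generateDataset(cfg), generateDataset(cfg))
})

test_that("environmental draws are standard normal at large n", {
  E <- generateEnvironment(10000, 1, seed = 7)
  expect_lt(abs(mean(E)), 0.05)
  expect_lt(abs(var(drop(E)) - 1), 0.05)
})

test_that("degenerate generator inputs are rejected", {
  expect_error(generateEnvironment(0, 3, seed = 1),
               class = "invalidArgumentError")
  expect_error(generateEnvironment(10, 0, seed = 1),
               class = "invalidArgumentError")
  env <- generateEnvironment(20, 2, seed = 1)
  expect_error(generateCommunity(env, 10, 2, coupling = 1.2, seed = 1),
               class = "invalidArgumentError")
  expect_error(simulationConfig(n_samples = 8, n_env = 4, n_latent_axes = 3,
                                beta_env = rep(0, 4)),
               class = "invalidArgumentError")
  expect_error(simulationConfig(noise_sd = 0),
               class = "invalidArgumentError")
})

test_that("latent axes honour the environment-community coupling", {
  env <- generateEnvironment(5000, 3, seed = 11)
  ## coupling 0: latent axes independent of the environment
  com0 <- generateCommunity(env, 20, 2, coupling = 0, seed = 12)
  for (j in 1:2) {
    r2 <- summary(lm(com0$latent_axes[, j] ~ env))$r.squared
    expect_lte(r2, 0.01)
  }
  ## coupling 1, one axis, one env variable: perfect collinearity
  env1 <- generateEnvironment(100, 1, seed = 13)
  com1 <- generateCommunity(env1, 20, 1, coupling = 1, seed = 14)
  expect_equal(abs(cor(com1$latent_axes[, 1], env1[, 1])), 1,
               tolerance = 1e-12)
  ## intermediate coupling: each axis's squared multiple correlation on the
  ## environment converges to the coupling fraction
  com5 <- generateCommunity(env, 20, 2, coupling = 0.5, seed = 15)
  for (j in 1:2) {
    r2 <- summary(lm(com5$latent_axes[, j] ~ env))$r.squared
    expect_lt(abs(r2 - 0.5), 0.05)
  }
  expect_true(all(com5$community >= 0))
})

test_that("process generation respects effect sizes and alignment", {
  env <- generateEnvironment(5000, 3, seed = 21)
  com <- generateCommunity(env, 10, 2, coupling = 0, seed = 22)
  ## noiseless limit with env-only effects: exact linear function of env
  y0 <- generateProcess(env, com$latent_axes, NULL,
                        beta_env = c(1, 0.5, -0.3), beta_community = c(0, 0),
                        beta_biomass = 0, noise_sd = 1e-9, seed = 23)
  expect_gt(summary(lm(y0 ~ env))$r.squared, 1 - 1e-12)
  ## pure noise: R2 on env vanishes at large n
  y1 <- generateProcess(env, com$latent_axes, NULL,
                        beta_env = c(0, 0, 0), beta_community = c(0, 0),
                        beta_biomass = 0, noise_sd = 1, seed = 24)
  expect_lte(summary(lm(y1 ~ env))$r.squared, 0.01)
  ## misaligned blocks refuse to combine
  bad <- com$latent_axes
  rownames(bad) <- rev(rownames(bad))
  expect_error(generateProcess(env, bad, NULL, c(0, 0, 0), c(0, 0), 0, 1, 1),
               class = "alignmentError")
})

test_that("variance bookkeeping matches theory for independent blocks", {
  cfg <- simulationConfig(n_samples = 10000, n_env = 3, n_taxa = 20,
                          n_latent_axes = 2, env_community_coupling = 0,
                          beta_env = c(0.5, 0.4, 0.3),
                          beta_community = c(0.35, 0.25),
                          beta_biomass = 0.3, biomass_env_r2 = 0,
                          noise_sd = 0.6, seed = 31)
  ds <- generateDataset(cfg)
  tr <- truthRecord(ds)
  y <- processRate(ds)
  vy <- var(y)
  realized <- c(
    env = var(drop(envData(ds) %*% tr$beta_env)) / vy,
    community = var(drop(tr$latent_axes %*% tr$beta_community)) / vy,
    biomass = var(tr$beta_biomass * biomassData(ds)) / vy
  )
  theory <- unlist(tr$variance_shares[c("env", "community", "biomass")])
  expect_true(all(abs(realized - theory) / theory < 0.10))
  ## large-n realized R2 of the true model vs theoretical R2
  fit <- lm(y ~ envData(ds) + tr$latent_axes + biomassData(ds))
  expect_lt(abs(summary(fit)$r.squared - tr$theoretical_r2), 0.02)
})

test_that("dataset assembly echoes its configuration", {
  cfg <- tinyConfig(seed = 41, include_biomass = FALSE)
  ds <- generateDataset(cfg)
  expect_null(biomassData(ds))
  expect_equal(unname(truthRecord(ds)$beta_env), cfg$beta_env)
  expect_equal(unname(truthRecord(ds)$beta_community), cfg$beta_community)
  cfgB <- tinyConfig(seed = 41, include_biomass = TRUE)
  expect_length(biomassData(generateDataset(cfgB)), 30)
  ## functional-gene flavor: 1-3 gene columns, no taxon table
  cfgG <- tinyConfig(seed = 42, data_flavor = "functional_gene", n_genes = 2)
  dsG <- generateDataset(cfgG)
  expect_identical(colnames(communityData(dsG)), c("gene1", "gene2"))
  expect_true(all(communityData(dsG) >= 0))
})

test_that("collections honour stratum counts and master-seed determinism", {
  strata <- data.frame(
    process_type = c("respiration", "nitrification"),
    environment_type = "natural_soil",
    data_flavor = "abundance_table",
    n = c(26L, 14L), stringsAsFactors = FALSE)
  spec <- collectionSpec(strata, tinyConfig(n_samples = 20))
  coll <- generateCollection(spec, seed = 99)
  expect_equal(nrow(coll$manifest), 40L)
  expect_equal(sum(coll$manifest$process_type == "respiration"), 26L)
  expect_equal(sum(coll$manifest$process_type == "nitrification"), 14L)
  coll2 <- generateCollection(spec, seed = 99)
  expect_identical(coll$datasets, coll2$datasets)
  ## distinct child seeds: no two datasets identical
  procs <- vapply(coll$datasets, function(d) processRate(d)[1], numeric(1))
  expect_equal(anyDuplicated(procs), 0L)
  expect_error(collectionSpec(data.frame(process_type = "x",
                                         environment_type = "y",
                                         data_flavor = "abundance_table",
                                         n = 0L)),
               class = "invalidArgumentError")
})

test_that("the default collection has the study's subset structure", {
  spec <- defaultCollectionSpec()
  coll <- generateCollection(spec, seed = 1)
  tab <- table(coll$manifest$process_type)
  expect_equal(as.integer(tab[c("respiration", "nitrification",
                                "denitrification", "N_mineralization")]),
               c(26L, 14L, 17L, 12L))
  env_tab <- table(coll$manifest$environment_type)
  expect_gte(min(env_tab[c("sediment", "agricultural_soil")]), 12L)
})
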
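#' @include AllClasses.R
NULL

.DATA_FLAVORS <- c("abundance_table", "functional_gene", "plfa")
.PROCESS_TYPES <- c("respiration", "nitrification", "denitrification",
                    "N_mineralization")
.ENVIRONMENT_TYPES <- c("natural_soil", "sediment", "agricultural_soil")

.flavorDataType <- c(abundance_table = "sequencing",
                     functional_gene = "qPCR",
                     plfa = "PLFA")

#' Configuration for one simulated dataset
#'
#' Defines the generating model for a single synthetic dataset: `n_env`
#' independent standard-normal environmental variables; `n_latent_axes`
#' standardized latent community axes whose variance is split between an
#' environmental signal (fraction `env_community_coupling`) and independent
#' noise; a taxon table whose log-abundances are linear in the latent axes;
#' optionally a biomass vector sharing fraction `biomass_env_r2` of its
#' variance with the environment; and a process rate that is a linear function
#' of environment, latent axes and biomass plus Gaussian noise of standard
#' deviation `noise_sd`.
#'
#' Because all generating predictors are standardized and (at coupling 0)
#' independent, the theoretical R-squared of the true model is
#' `S / (S + noise_sd^2)` with `S` the sum of squared effect sizes, which is
#' what the truth record stores.
#'
#' Defaults describe a study-like dataset: 40 samples, 4 environmental
#' drivers, 60 taxa on 3 latent axes with moderate environmental coupling
#' (0.3), an environmental variance share of about 0.5, a modest community
#' contribution and a biomass effect, giving a true-model R-squared around
#' 0.7.
#'
#' @param n_samples number of samples.
#' @param n_env number of environmental variables.
#' @param n_taxa number of taxa (columns of the community table).
#' @param n_latent_axes number of latent community axes.
#' @param env_community_coupling fraction in `[0,1]` of latent-axis variance
#'   explained by the environment.
#' @param beta_env numeric vector of length `n_env`: process effect per
#'   environmental variable (standardized scale).
#' @param beta_community numeric vector of length `n_latent_axes`.
#' @param beta_biomass scalar biomass effect.
#' @param biomass_env_r2 fraction in `[0,1)` of biomass variance explained by
#'   the environment.
#' @param noise_sd positive residual standard deviation of the process rate.
#' @param include_biomass logical; generate a biomass vector?
#' @param data_flavor one of `"abundance_table"`, `"functional_gene"`,
#'   `"plfa"`.
#' @param process_type,environment_type categorical metadata labels.
#' @param microbial_data_type metadata label; defaults to a flavor-specific
#'   value (sequencing / qPCR / PLFA).
#' @param taxon_loading_sd,taxon_noise_sd spread of taxon loadings on the
#'   latent axes and of taxon-level log-abundance noise.
#' @param n_genes number of functional-gene columns (1-3) for the
#'   functional-gene flavor.
#' @param dataset_id identifier given to the generated dataset.
#' @param seed RNG seed for the dataset.
#' @return A `SimulationConfig` (a validated list).
#' @seealso [generateDataset()], [generateCollection()]
#' @export
simulationConfig <- function(n_samples = 40L,
                             n_env = 4L,
                             n_taxa = 60L,
                             n_latent_axes = 3L,
                             env_community_coupling = 0.3,
                             beta_env = c(0.5, 0.4, 0.3, 0.2),
                             beta_community = c(0.3, 0.2, 0.1),
                             beta_biomass = 0.2,
                             biomass_env_r2 = 0.5,
                             noise_sd = 0.55,
                             include_biomass = TRUE,
                             data_flavor = c("abundance_table",
                                             "functional_gene", "plfa"),
                             process_type = "respiration",
                             environment_type = "natural_soil",
                             microbial_data_type = NULL,
                             taxon_loading_sd = 0.7,
                             taxon_noise_sd = 0.7,
                             n_genes = 3L,
                             dataset_id = "sim",
                             seed = 1L) {
  data_flavor <- match.arg(data_flavor)
  n_samples <- .checkCount(n_samples, "n_samples", 8L)
  n_env <- .checkCount(n_env, "n_env")
  n_taxa <- .checkCount(n_taxa, "n_taxa")
  n_latent_axes <- .checkCount(n_latent_axes, "n_latent_axes")
  if (n_samples <= n_env + n_latent_axes + 2L)
    .mmiStop("invalidArgumentError",
             "n_samples must exceed n_env + n_latent_axes + 2")
  env_community_coupling <- .checkFraction(env_community_coupling,
                                           "env_community_coupling")
  biomass_env_r2 <- .checkFraction(biomass_env_r2, "biomass_env_r2",
                                   upper.closed = FALSE)
  if (length(beta_env) != n_env)
    .mmiStop("invalidArgumentError", "beta_env must have length n_env")
  if (length(beta_community) != n_latent_axes)
    .mmiStop("invalidArgumentError",
             "beta_community must have length n_latent_axes")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    .mmiStop("invalidArgumentError", "noise_sd must be a positive number")
  n_genes <- .checkCount(n_genes, "n_genes")
  if (n_genes > 3L) n_genes <- 3L
  if (is.null(microbial_data_type))
    microbial_data_type <- unname(.flavorDataType[data_flavor])
  cfg <- list(
    n_samples = n_samples, n_env = n_env, n_taxa = n_taxa,
    n_latent_axes = n_latent_axes,
    env_community_coupling = env_community_coupling,
    beta_env = as.numeric(beta_env),
    beta_community = as.numeric(beta_community),
    beta_biomass = as.numeric(beta_biomass),
    biomass_env_r2 = biomass_env_r2,
    noise_sd = as.numeric(noise_sd),
    include_biomass = isTRUE(include_biomass),
    data_flavor = data_flavor,
    process_type = process_type,
    environment_type = environment_type,
    microbial_data_type = microbial_data_type,
    taxon_loading_sd = as.numeric(taxon_loading_sd),
    taxon_noise_sd = as.numeric(taxon_noise_sd),
    n_genes = n_genes,
    dataset_id = as.character(dataset_id),
    seed = .checkSeed(seed)
  )
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$n_samples, "samples,", x$n_env, "env vars,",
      x$n_taxa, "taxa on", x$n_latent_axes, "latent axes\n")
  cat("  coupling =", x$env_community_coupling,
      "| noise sd =", x$noise_sd,
      "| flavor =", x$data_flavor, "| seed =", x$seed, "\n")
  invisible(x)
}

#' Generate an environmental matrix
#'
#' Environmental variables are independent standard-normal draws; downstream
#' effect sizes are therefore on a standardized scale.
#'
#' @param n_samples,n_env dimensions (`n_samples >= 2`, `n_env >= 1`).
#' @param seed RNG seed.
#' @return Numeric matrix with rownames `S001...` and colnames `env1...`.
#' @export
generateEnvironment <- function(n_samples, n_env, seed) {
  n_samples <- .checkCount(n_samples, "n_samples", 2L)
  n_env <- .checkCount(n_env, "n_env", 1L)
  E <- withSeed(seed, matrix(rnorm(n_samples * n_env), n_samples, n_env))
  dimnames(E) <- list(sprintf("S%03d", seq_len(n_samples)),
                      paste0("env", seq_len(n_env)))
  E
}

## Latent community axes: sqrt(c) * (env %*% W) + sqrt(1-c) * Z with W
## column-wise unit-norm loadings, then each axis standardized sample-wise.
.makeLatentAxes <- function(env, n_axes, coupling, seed) {
  n <- nrow(env)
  withSeed(seed, {
    W <- matrix(rnorm(ncol(env) * n_axes), ncol(env), n_axes)
    W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
    Z <- matrix(rnorm(n * n_axes), n, n_axes)
    L <- sqrt(coupling) * (env %*% W) + sqrt(1 - coupling) * Z
    L <- scale(L)
    attr(L, "scaled:center") <- NULL
    attr(L, "scaled:scale") <- NULL
    dimnames(L) <- list(rownames(env), paste0("axis", seq_len(n_axes)))
    list(axes = L, loadings = W)
  })
}

#' Generate a community abundance table coupled to the environment
#'
#' Latent axis scores are `sqrt(coupling) * (env %*% W) + sqrt(1 - coupling) * Z`
#' with `W` random unit-norm loadings and `Z` independent standard normal;
#' each axis is then standardized. Taxon log-abundances are linear in the
#' latent axes (random loadings, random per-taxon baselines) plus taxon-level
#' Gaussian noise, and the table is the exponential of that — a log-normal
#' composition, always strictly positive.
#'
#' @param env environmental matrix from [generateEnvironment()].
#' @param n_taxa number of taxa.
#' @param n_latent_axes number of latent axes.
#' @param coupling fraction in `[0,1]` of latent-axis variance carried by the
#'   environment.
#' @param seed RNG seed.
#' @param taxon_loading_sd,taxon_noise_sd taxon-level spread parameters.
#' @return List with `community` (nonnegative matrix, samples x taxa),
#'   `latent_axes` (the realized standardized axes) and `axis_loadings`.
#' @export
generateCommunity <- function(env, n_taxa, n_latent_axes, coupling, seed,
                              taxon_loading_sd = 0.7, taxon_noise_sd = 0.7) {
  coupling <- .checkFraction(coupling, "coupling")
  n_taxa <- .checkCount(n_taxa, "n_taxa")
  n_latent_axes <- .checkCount(n_latent_axes, "n_latent_axes")
  seeds <- spawnSeeds(seed, 2L)
  lat <- .makeLatentAxes(env, n_latent_axes, coupling, seeds[1L])
  n <- nrow(env)
  comm <- withSeed(seeds[2L], {
    baseline <- rnorm(n_taxa, 0, 1)
    Lam <- matrix(rnorm(n_taxa * n_latent_axes, 0, taxon_loading_sd),
                  n_taxa, n_latent_axes)
    logA <- matrix(baseline, n, n_taxa, byrow = TRUE) +
      lat$axes %*% t(Lam) +
      matrix(rnorm(n * n_taxa, 0, taxon_noise_sd), n, n_taxa)
    exp(logA)
  })
  dimnames(comm) <- list(rownames(env), paste0("taxon", seq_len(n_taxa)))
  list(community = comm, latent_axes = lat$axes, axis_loadings = lat$loadings)
}

## Functional-gene flavor: 1-3 nonnegative abundance columns directly driven
## by the leading latent axes (no taxon table, no downstream ordination).
.makeGeneTable <- function(latent_axes, n_genes, seed) {
  n <- nrow(latent_axes)
  n_genes <- min(n_genes, ncol(latent_axes))
  G <- withSeed(seed, {
    logG <- latent_axes[, seq_len(n_genes), drop = FALSE] +
      matrix(rnorm(n * n_genes, 0, 0.5), n, n_genes)
    exp(logG)
  })
  dimnames(G) <- list(rownames(latent_axes), paste0("gene", seq_len(n_genes)))
  G
}

#' Generate a biomass vector correlated with the environment
#'
#' `biomass = sqrt(r2) * s + sqrt(1 - r2) * noise` where `s` is a standardized
#' random unit-norm projection of the environmental matrix, so the population
#' R-squared of biomass on environment is `r2`.
#'
#' @param env environmental matrix.
#' @param biomass_env_r2 fraction in `[0,1)`.
#' @param seed RNG seed.
#' @return Named numeric vector.
#' @export
generateBiomass <- function(env, biomass_env_r2, seed) {
  biomass_env_r2 <- .checkFraction(biomass_env_r2, "biomass_env_r2",
                                   upper.closed = FALSE)
  n <- nrow(env)
  b <- withSeed(seed, {
    u <- rnorm(ncol(env))
    u <- u / sqrt(sum(u^2))
    s <- as.vector(scale(env %*% u))
    sqrt(biomass_env_r2) * s + sqrt(1 - biomass_env_r2) * rnorm(n)
  })
  names(b) <- rownames(env)
  b
}

#' Generate a process-rate response from known effect sizes
#'
#' `process = env %*% beta_env + latent_axes %*% beta_community +
#' beta_biomass * biomass + noise`, with Gaussian noise of standard deviation
#' `noise_sd`. All blocks must be row-aligned on the same samples.
#'
#' @param env environmental matrix.
#' @param latent_axes standardized latent community axes.
#' @param biomass biomass vector or `NULL`.
#' @param beta_env,beta_community,beta_biomass effect sizes on the
#'   standardized scale.
#' @param noise_sd positive residual standard deviation.
#' @param seed RNG seed.
#' @return Named numeric vector of process rates.
#' @export
generateProcess <- function(env, latent_axes, biomass,
                            beta_env, beta_community, beta_biomass,
                            noise_sd, seed) {
  n <- nrow(env)
  if (nrow(latent_axes) != n ||
      !identical(rownames(latent_axes), rownames(env)) ||
      (!is.null(biomass) &&
       (length(biomass) != n || !identical(names(biomass), rownames(env)))))
    .mmiStop("alignmentError", "process-generation blocks are not row-aligned")
  if (length(beta_env) != ncol(env))
    .mmiStop("invalidArgumentError", "beta_env length must match env columns")
  if (length(beta_community) != ncol(latent_axes))
    .mmiStop("invalidArgumentError",
             "beta_community length must match latent axes")
  y <- drop(env %*% beta_env) + drop(latent_axes %*% beta_community)
  if (!is.null(biomass)) y <- y + beta_biomass * biomass
  y <- y + withSeed(seed, rnorm(n, 0, noise_sd))
  names(y) <- rownames(env)
  y
}

#' Generate a complete simulated dataset
#'
#' Draws all blocks from one [simulationConfig()] and packages them as a
#' [ProcessDataset-class] whose `truth` record carries the generating effect
#' sizes, the realized latent axes and the theoretical variance shares
#' (computed as if all generating predictors were independent, which holds
#' exactly at coupling 0). The master seed deterministically spawns one child
#' seed per block via [spawnSeeds()], so the dataset is a pure function of its
#' configuration.
#'
#' @param config a `SimulationConfig`.
#' @return A [ProcessDataset-class].
#' @export
generateDataset <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    .mmiStop("invalidArgumentError", "`config` must come from simulationConfig()")
  seeds <- spawnSeeds(config$seed, 4L)
  env <- generateEnvironment(config$n_samples, config$n_env, seeds[1L])
  if (config$data_flavor == "functional_gene") {
    lat <- .makeLatentAxes(env, config$n_latent_axes,
                           config$env_community_coupling, seeds[2L])
    gseed <- spawnSeeds(seeds[2L], 1L)
    community <- .makeGeneTable(lat$axes, config$n_genes, gseed)
    latent <- lat$axes
  } else {
    com <- generateCommunity(env, config$n_taxa, config$n_latent_axes,
                             config$env_community_coupling, seeds[2L],
                             config$taxon_loading_sd, config$taxon_noise_sd)
    community <- com$community
    latent <- com$latent_axes
  }
  biomass <- if (config$include_biomass)
    generateBiomass(env, config$biomass_env_r2, seeds[3L]) else numeric(0)
  y <- generateProcess(env, latent,
                       if (length(biomass)) biomass else NULL,
                       config$beta_env, config$beta_community,
                       config$beta_biomass, config$noise_sd, seeds[4L])
  sh_env <- sum(config$beta_env^2)
  sh_com <- sum(config$beta_community^2)
  sh_bio <- if (config$include_biomass) config$beta_biomass^2 else 0
  total <- sh_env + sh_com + sh_bio + config$noise_sd^2
  truth <- list(
    beta_env = setNames(config$beta_env, colnames(env)),
    beta_community = setNames(config$beta_community, colnames(latent)),
    beta_biomass = if (config$include_biomass) config$beta_biomass else 0,
    noise_sd = config$noise_sd,
    env_community_coupling = config$env_community_coupling,
    biomass_env_r2 = if (config$include_biomass) config$biomass_env_r2 else NA,
    latent_axes = latent,
    variance_shares = list(env = sh_env / total, community = sh_com / total,
                           biomass = sh_bio / total,
                           noise = config$noise_sd^2 / total),
    theoretical_r2 = (sh_env + sh_com + sh_bio) / total,
    seed = config$seed,
    block_seeds = seeds
  )
  new("ProcessDataset",
      datasetId = config$dataset_id,
      env = env,
      community = community,
      biomass = biomass,
      process = y,
      metadata = list(process_type = config$process_type,
                      environment_type = config$environment_type,
                      microbial_data_type = config$microbial_data_type,
                      data_flavor = config$data_flavor),
      truth = truth)
}

#' Describe the strata of a simulated dataset collection
#'
#' @param strata data frame with columns `n`, `process_type`,
#'   `environment_type` and `data_flavor`; one row per stratum.
#' @param base_config the `SimulationConfig` template applied to every
#'   dataset (its metadata fields and seed are overridden per dataset).
#' @return A `CollectionSpec`.
#' @export
collectionSpec <- function(strata, base_config = simulationConfig()) {
  needed <- c("n", "process_type", "environment_type", "data_flavor")
  if (!is.data.frame(strata) || !all(needed %in% names(strata)))
    .mmiStop("invalidArgumentError",
             "`strata` must be a data frame with columns %s",
             paste(needed, collapse = ", "))
  if (any(strata$n < 1))
    .mmiStop("invalidArgumentError", "every stratum count must be >= 1")
  if (!all(strata$data_flavor %in% .DATA_FLAVORS))
    .mmiStop("invalidArgumentError", "unknown data_flavor in strata")
  structure(list(strata = strata, base_config = base_config),
            class = "CollectionSpec")
}

#' Default simulated collection mirroring the study's subset structure
#'
#' Process-type counts follow the study's synthesis subsets (respiration 26,
#' nitrification 14, denitrification 17, N mineralization 12) and environment
#' types are allocated so that sediment and agricultural soil each reach the
#' n = 12 replication floor, with natural soil taking the remainder (45).
#' Most datasets carry sequencing-style abundance tables; a few strata use
#' PLFA profiles or functional-gene (qPCR) columns so every data flavor is
#' exercised.
#'
#' @param base_config `SimulationConfig` template shared by all strata.
#' @return A `CollectionSpec` describing 69 datasets.
#' @export
defaultCollectionSpec <- function(base_config = simulationConfig()) {
  strata <- data.frame(
    process_type = c(rep("respiration", 4L), rep("nitrification", 4L),
                     rep("denitrification", 4L), rep("N_mineralization", 3L)),
    environment_type = c("natural_soil", "natural_soil", "sediment",
                         "agricultural_soil",
                         "natural_soil", "natural_soil", "sediment",
                         "agricultural_soil",
                         "natural_soil", "natural_soil", "sediment",
                         "agricultural_soil",
                         "natural_soil", "sediment", "agricultural_soil"),
    data_flavor = c("abundance_table", "plfa", "abundance_table",
                    "abundance_table",
                    "abundance_table", "functional_gene", "abundance_table",
                    "abundance_table",
                    "abundance_table", "functional_gene", "abundance_table",
                    "abundance_table",
                    "abundance_table", "abundance_table", "abundance_table"),
    n = c(14L, 4L, 4L, 4L,
          6L, 4L, 2L, 2L,
          7L, 4L, 3L, 3L,
          6L, 3L, 3L),
    stringsAsFactors = FALSE
  )
  collectionSpec(strata, base_config)
}

#' Generate a collection of simulated datasets plus a manifest
#'
#' Expands the strata of a [collectionSpec()] into individual datasets. The
#' master seed spawns one distinct child seed per dataset ([spawnSeeds()]),
#' so the collection is reproducible as a whole while its members are
#' internally independent.
#'
#' @param spec a `CollectionSpec`.
#' @param seed master seed for the collection.
#' @return A `DatasetCollection`: list with `datasets` (named list of
#'   [ProcessDataset-class]), `manifest` (data frame: dataset_id,
#'   process_type, environment_type, microbial_data_type, path) and `seed`.
#' @export
generateCollection <- function(spec, seed) {
  if (!inherits(spec, "CollectionSpec"))
    .mmiStop("invalidArgumentError", "`spec` must come from collectionSpec()")
  strata <- spec$strata
  idx <- rep(seq_len(nrow(strata)), strata$n)
  total <- length(idx)
  seeds <- spawnSeeds(seed, total)
  datasets <- vector("list", total)
  manifest <- data.frame(
    dataset_id = sprintf("ds%03d", seq_len(total)),
    process_type = strata$process_type[idx],
    environment_type = strata$environment_type[idx],
    microbial_data_type = unname(.flavorDataType[strata$data_flavor[idx]]),
    path = sprintf("ds%03d", seq_len(total)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(total)) {
    s <- idx[i]
    cfg <- spec$base_config
    cfg$process_type <- strata$process_type[s]
    cfg$environment_type <- strata$environment_type[s]
    cfg$data_flavor <- strata$data_flavor[s]
    cfg$microbial_data_type <- unname(.flavorDataType[strata$data_flavor[s]])
    cfg$dataset_id <- manifest$dataset_id[i]
    cfg$seed <- seeds[i]
    datasets[[i]] <- generateDataset(cfg)
  }
  names(datasets) <- manifest$dataset_id
  structure(list(datasets = datasets, manifest = manifest, seed = seed),
            class = "DatasetCollection")
}

#' @export
print.DatasetCollection <- function(x, ...) {
  cat("DatasetCollection:", length(x$datasets), "datasets (master seed",
      paste0(x$seed, ")\n"))
  print(table(x$manifest$process_type, x$manifest$environment_type))
  invisible(x)
}
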
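## Small in-code fixtures shared across test files.

tinyConfig <- function(seed = 1L, n_samples = 30L, ...) {
  simulationConfig(n_samples = n_samples, n_env = 3L, n_taxa = 30L,
                   n_latent_axes = 2L,
                   beta_env = c(0.5, 0.4, 0.3), beta_community = c(0.3, 0.2),
                   seed = seed, ...)
}

## Independent brute-force reference for the whole model-selection chain:
## enumerate subsets, fit by normal equations, score with the closed forms,
## truncate at delta <= threshold, weight and full-average. Shares no code
## with the package internals.
bruteForceMMI <- function(X, y, max_terms, threshold = 4) {
  p <- ncol(X)
  n <- length(y)
  subsets <- list(integer(0))
  for (size in seq_len(max_terms))
    subsets <- c(subsets, combn(p, size, simplify = FALSE))
  score <- lapply(subsets, function(s) {
    D <- cbind(1, X[, s, drop = FALSE])
    beta <- solve(crossprod(D), crossprod(D, y))
    rss <- sum((y - D %*% beta)^2)
    k <- length(s) + 2
    ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
    list(subset = colnames(X)[s], beta = drop(beta), rss = rss,
         aicc = -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  })
  aiccs <- vapply(score, `[[`, numeric(1), "aicc")
  sizes <- lengths(subsets)
  keys <- vapply(score, function(s) paste(s$subset, collapse = "|"),
                 character(1))
  ord <- order(aiccs, sizes, keys)
  score <- score[ord]
  aiccs <- aiccs[ord]
  delta <- aiccs - aiccs[1]
  keep <- delta <= threshold + 1e-12
  retained <- score[keep]
  w <- exp(-delta[keep] / 2)
  w <- w / sum(w)
  union <- colnames(X)[colnames(X) %in%
                         unique(unlist(lapply(retained, `[[`, "subset")))]
  terms <- c("(Intercept)", union)
  B <- matrix(0, length(retained), length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_along(retained))
    B[i, c("(Intercept)", retained[[i]]$subset)] <- retained[[i]]$beta
  list(n_candidates = length(subsets),
       best_subset = retained[[1]]$subset,
       retained_subsets = lapply(retained, `[[`, "subset"),
       delta = delta[keep],
       weights = w,
       averaged = colSums(B * w))
}

## Exact Mann-Whitney p-value by exhaustive enumeration of which pooled
## ranks belong to x (valid without ties).
enumerateMW <- function(x, y, alternative = "greater") {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  picks <- combn(n, nx)
  U_all <- apply(picks, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  if (alternative == "greater") mean(U_all >= U_obs) else mean(U_all <= U_obs)
}

## Flat results table for synthesis tests, with known improvement counts.
fakeResults <- function(n, n_improved = 0, process = "respiration",
                        environment = "natural_soil", datatype = "sequencing",
                        adj_E = NULL, adj_M = NULL, adj_EM = NULL,
                        seed = 1) {
  withSeed(seed, {
    adj_E <- adj_E %||% runif(n, 0.3, 0.8)
    adj_M <- adj_M %||% runif(n, 0.0, 0.5)
    adj_EM <- adj_EM %||% (adj_E + runif(n, -0.05, 0.15))
    data.frame(
      dataset_id = sprintf("ds%03d", seq_len(n)),
      process_type = process, environment_type = environment,
      microbial_data_type = datatype,
      adj_r2_E = adj_E, adj_r2_M = adj_M, adj_r2_E_M = adj_EM,
      improved_E_vs_E_M = seq_len(n) <= n_improved,
      delta_adj_r2_E_vs_E_M = adj_EM - adj_E,
      stringsAsFactors = FALSE
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
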
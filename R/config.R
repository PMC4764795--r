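#' @include utils.R
NULL

#' Pipeline configuration
#'
#' Central home for every numeric constant the framework uses, with the
#' canonical values as defaults: the delta-AICc model-set threshold (4), the
#' AICc gap defining statistical improvement (4), the relative
#' adjusted-R-squared fraction defining ecological improvement (0.10), the
#' forward-selection significance level (0.05) with 999 permutations, and
#' the n >= 12 replication floor for subset synthesis. No stage of the
#' pipeline hard-codes these numbers.
#'
#' @param ordination list: `method` (`"pca_hellinger"` or
#'   `"pcoa_bray_curtis"`), `cumulative_variance_target`, `max_axes`
#'   (`NULL` = `max(1, floor(n/10))` rule).
#' @param mmi list: `delta_threshold`, `averaging_mode` (`"full"` or
#'   `"conditional"`), `max_terms` (`NULL` = `min(p, max(1, floor(n/10)))`
#'   rule).
#' @param improvement list: `aicc_gap`, `relative_r2_fraction`, `pair_rule`
#'   (`"E_vs_E_M"`: which pair defines "percent improved").
#' @param coupling list: `alpha`, `n_permutations`, `seed`,
#'   `community_response`.
#' @param synthesis list: `min_subset_n`, `mw_comparisons`.
#' @param transforms list: `log_response`.
#' @return A validated `PipelineConfig` (nested list).
#' @export
pipelineConfig <- function(ordination = list(),
                           mmi = list(),
                           improvement = list(),
                           coupling = list(),
                           synthesis = list(),
                           transforms = list()) {
  cfg <- list(
    ordination = utils::modifyList(
      list(method = "pca_hellinger", cumulative_variance_target = 0.7,
           max_axes = NULL),
      ordination, keep.null = TRUE),
    mmi = utils::modifyList(
      list(delta_threshold = 4, averaging_mode = "full", max_terms = NULL),
      mmi, keep.null = TRUE),
    improvement = utils::modifyList(
      list(aicc_gap = 4, relative_r2_fraction = 0.10,
           pair_rule = "E_vs_E_M"),
      improvement),
    coupling = utils::modifyList(
      list(alpha = 0.05, n_permutations = 999L, seed = 20260101L,
           community_response = "hellinger"),
      coupling),
    synthesis = utils::modifyList(
      list(min_subset_n = 12L, mw_comparisons = .DEFAULT_MW),
      synthesis),
    transforms = utils::modifyList(list(log_response = FALSE), transforms)
  )
  if (cfg$mmi$delta_threshold <= 0)
    .mmiStop("invalidArgumentError", "delta_threshold must be positive")
  if (cfg$improvement$relative_r2_fraction <= 0 ||
      cfg$improvement$relative_r2_fraction >= 1)
    .mmiStop("invalidArgumentError",
             "relative_r2_fraction must lie in (0,1)")
  if (cfg$coupling$n_permutations < 99)
    .mmiStop("invalidArgumentError", "n_permutations must be >= 99")
  if (cfg$synthesis$min_subset_n < 2)
    .mmiStop("invalidArgumentError", "min_subset_n must be >= 2")
  structure(cfg, class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig\n")
  cat("  ordination:", x$ordination$method, "| cum var target",
      x$ordination$cumulative_variance_target, "\n")
  cat("  mmi: delta threshold", x$mmi$delta_threshold, "|",
      x$mmi$averaging_mode, "averaging\n")
  cat("  improvement: AICc gap", x$improvement$aicc_gap, "| relative R2 fraction",
      x$improvement$relative_r2_fraction, "\n")
  cat("  coupling: alpha", x$coupling$alpha, "|",
      x$coupling$n_permutations, "permutations | seed", x$coupling$seed, "\n")
  cat("  synthesis: min subset n", x$synthesis$min_subset_n, "\n")
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may specify any subset of the [pipelineConfig()] sections;
#' unspecified values keep their defaults.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    .mmiStop("missingDependencyError",
             "the 'yaml' package is required to read configuration files")
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw[intersect(names(raw),
                                        c("ordination", "mmi", "improvement",
                                          "coupling", "synthesis",
                                          "transforms"))])
}
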
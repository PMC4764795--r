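#' @include inference.R community.R
NULL

.SET_ORDER <- c("E", "M", "B", "E+M", "E+B", "M+B", "E+M+B")
.IMPROVEMENT_PAIRS <- list(c("E", "E+M"), c("E", "E+B"),
                           c("E", "E+M+B"), c("E+B", "E+M+B"))

#' Assemble the predictor sets for one dataset
#'
#' Builds the three predictor blocks — E (environmental variables), M
#' (microbial structure: ordination axis scores, Shannon diversity, gene
#' abundances) and B (biomass) — and every non-empty additive union of the
#' blocks present in the dataset. With all three blocks that is 7 sets
#' (E, M, B, E+M, E+B, M+B, E+M+B); without biomass, 3 (E, M, E+M). Column
#' lists are disjoint across blocks by construction.
#'
#' @param dataset a [ProcessDataset-class].
#' @param block the [PredictorBlock-class] from [condensePredictors()].
#' @return Named list of `PredictorSetSpec` (label + column names).
#' @export
buildPredictorSets <- function(dataset, block) {
  e_cols <- colnames(envData(dataset))
  if (!length(e_cols))
    .mmiStop("missingBaselineError", "dataset has no environmental variables")
  m_cols <- c(colnames(axisScores(block)),
              if (length(shannonValues(block))) "shannon",
              colnames(geneAbundances(block)))
  b_cols <- if (!is.null(biomassData(dataset))) "biomass" else character(0)
  blocks <- list(E = e_cols, M = m_cols, B = b_cols)
  sets <- list()
  for (lab in .SET_ORDER) {
    parts <- strsplit(lab, "+", fixed = TRUE)[[1L]]
    cols <- unlist(blocks[parts], use.names = FALSE)
    if (any(!lengths(blocks[parts]))) next   # a required block is absent
    sets[[lab]] <- structure(list(label = lab, columns = cols),
                             class = "PredictorSetSpec")
  }
  sets
}

## Standardized design matrix joining all predictor columns of a dataset.
.assembleDesign <- function(dataset, block) {
  X <- cbind(envData(dataset), axisScores(block))
  if (length(shannonValues(block)))
    X <- cbind(X, shannon = shannonValues(block))
  if (ncol(geneAbundances(block)))
    X <- cbind(X, geneAbundances(block))
  if (!is.null(biomassData(dataset)))
    X <- cbind(X, biomass = biomassData(dataset))
  Z <- .zscore(X)
  if (length(attr(Z, "constant")))
    Z <- Z[, setdiff(colnames(Z), attr(Z, "constant")), drop = FALSE]
  Z
}

#' Dual statistical-plus-ecological improvement decision
#'
#' A combined predictor set improves on a baseline only when both criteria
#' hold: *statistical* — the best AICc of the combined set is at least
#' `aicc_gap` (default 4) lower than the best AICc of the baseline set — and
#' *ecological* — the adjusted-R-squared gain exceeds `rel_fraction` (default
#' 10%) of the baseline's adjusted R-squared. The ecological criterion
#' removes artifacts where AICc-distinct models yield nearly identical
#' explanatory power. When the baseline adjusted R-squared is not positive
#' the relative threshold collapses to 0, so any positive gain counts as
#' ecological (a case the criterion's original formulation never encounters;
#' flagged in the output).
#'
#' @param baseline,combined [AveragedModel-class] objects fitted on the same
#'   samples and response.
#' @param aicc_gap required AICc advantage.
#' @param rel_fraction relative adjusted-R-squared threshold.
#' @return List with `statistical`, `ecological`, `improved`,
#'   `delta_adj_r2`, `ecological_threshold` and `baseline_nonpositive`.
#' @export
improvementDecision <- function(baseline, combined, aicc_gap = 4,
                                rel_fraction = 0.10) {
  if (length(baseline@predictions) != length(combined@predictions) ||
      !identical(names(baseline@predictions), names(combined@predictions)))
    .mmiStop("alignmentError",
             "baseline and combined models were fitted on different samples")
  gap <- baseline@bestAICc - combined@bestAICc
  statistical <- isTRUE(!is.na(gap) && gap >= aicc_gap)
  b_adj <- baseline@adjR2
  c_adj <- combined@adjR2
  delta <- c_adj - b_adj
  thr <- rel_fraction * max(b_adj, 0)
  ecological <- isTRUE(!is.na(delta) && delta > thr)
  list(statistical = statistical,
       ecological = ecological,
       improved = statistical && ecological,
       delta_adj_r2 = delta,
       ecological_threshold = thr,
       baseline_nonpositive = isTRUE(!is.na(b_adj) && b_adj <= 0))
}

#' Compare predictor sets for one dataset
#'
#' The per-dataset core of the framework: condense the microbial data
#' ([condensePredictors()]), assemble the predictor sets
#' ([buildPredictorSets()]), run the all-subsets / delta-AICc / Akaike-weight
#' averaging chain for each set ([runModelSelection()]), and apply the dual
#' improvement criterion to the pairs (E vs E+M), (E vs E+B), (E vs E+M+B)
#' and (E+B vs E+M+B) that the dataset supports.
#'
#' All predictors are z-score standardized before fitting; the response is
#' used untransformed unless `config$transforms$log_response` is set (applied
#' only when all responses are positive). Each set's subset search is capped
#' by the `max_terms` rule in the config.
#'
#' @param dataset a [ProcessDataset-class].
#' @param config a [pipelineConfig()].
#' @param block optional precomputed [PredictorBlock-class].
#' @return A [ComparisonResult-class].
#' @export
compareDataset <- function(dataset, config = pipelineConfig(), block = NULL) {
  if (is.null(block))
    block <- condensePredictors(
      dataset,
      method = config$ordination$method,
      cum_var_target = config$ordination$cumulative_variance_target,
      max_axes = config$ordination$max_axes)
  X <- .assembleDesign(dataset, block)
  y <- processRate(dataset)
  notes <- character(0)
  if (isTRUE(config$transforms$log_response)) {
    if (all(y > 0)) y <- log(y)
    else notes <- c(notes, "log_response requested but response has non-positive values; left untransformed")
  }
  sets <- buildPredictorSets(dataset, block)
  n <- length(y)
  perSet <- list()
  models <- list()
  for (lab in names(sets)) {
    cols <- intersect(sets[[lab]]$columns, colnames(X))
    if (!length(cols)) {
      notes <- c(notes, sprintf("set %s skipped: no usable columns", lab))
      next
    }
    mt <- min(length(cols), max(1L, n %/% 10L), n - 3L)
    run <- runModelSelection(X, y, cols,
                             delta_threshold = config$mmi$delta_threshold,
                             max_terms = mt,
                             mode = config$mmi$averaging_mode)
    am <- run$averaged
    models[[lab]] <- am
    perSet[[lab]] <- list(
      adj_r2 = am@adjR2,
      r2 = am@r2,
      best_aicc = am@bestAICc,
      n_models = am@nModels,
      n_candidates = length(run$fits),
      predictor_union = am@predictorUnion,
      max_terms = mt
    )
  }
  improvement <- list()
  for (pair in .IMPROVEMENT_PAIRS) {
    a <- pair[1L]; b <- pair[2L]
    if (is.null(models[[a]]) || is.null(models[[b]])) next
    key <- paste0(.labelKey(a), "_vs_", .labelKey(b))
    improvement[[key]] <- improvementDecision(
      models[[a]], models[[b]],
      aicc_gap = config$improvement$aicc_gap,
      rel_fraction = config$improvement$relative_r2_fraction)
  }
  new("ComparisonResult",
      datasetId = datasetId(dataset),
      perSet = perSet,
      improvement = improvement,
      metadata = datasetMetadata(dataset),
      notes = notes)
}
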
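#' @include AllGenerics.R
NULL

#' ProcessDataset: one study's aligned data blocks
#'
#' Container for a single dataset in the structure-function analysis: an
#' environmental matrix, a microbial community (or functional-gene) abundance
#' matrix, an optional microbial biomass vector, and one ecosystem process-rate
#' response, all aligned on the same ordered samples. Simulated datasets
#' additionally carry a `truth` record with the generating effect sizes, which
#' the analysis stages never read.
#'
#' Sample identifiers live in the rownames of `env` and `community` and the
#' names of `biomass` and `process`; validity enforces that they are identical
#' and ordered. Biomass is optional: a zero-length vector means "not measured".
#'
#' @slot datasetId single character identifier.
#' @slot env numeric matrix, samples x environmental variables.
#' @slot community nonnegative numeric matrix, samples x taxa (or genes for
#'   the functional-gene flavor).
#' @slot biomass numeric vector of length `nSamples` or 0.
#' @slot process numeric response vector, one value per sample.
#' @slot metadata list with `process_type`, `environment_type`,
#'   `microbial_data_type` and `data_flavor`.
#' @slot truth list of generating parameters (empty for real data).
#'
#' @seealso [generateDataset()], [readDataset()], [compareDataset()]
#' @export
setClass("ProcessDataset",
  representation(
    datasetId = "character",
    env = "matrix",
    community = "matrix",
    biomass = "numeric",
    process = "numeric",
    metadata = "list",
    truth = "list"
  ),
  prototype(
    datasetId = "dataset",
    biomass = numeric(0),
    metadata = list(),
    truth = list()
  )
)

setValidity("ProcessDataset", function(object) {
  msgs <- character(0)
  n <- nrow(object@env)
  ids <- rownames(object@env)
  if (is.null(ids)) msgs <- c(msgs, "env must carry sample ids as rownames")
  if (n < 8L) msgs <- c(msgs, "a dataset needs at least 8 samples")
  if (nrow(object@community) != n ||
      !identical(rownames(object@community), ids))
    msgs <- c(msgs, "community block not aligned with env block")
  if (length(object@process) != n ||
      !identical(names(object@process), ids))
    msgs <- c(msgs, "process block not aligned with env block")
  if (length(object@biomass) &&
      (length(object@biomass) != n ||
       !identical(names(object@biomass), ids)))
    msgs <- c(msgs, "biomass block not aligned with env block")
  if (anyNA(object@env) || anyNA(object@community) || anyNA(object@process) ||
      anyNA(object@biomass))
    msgs <- c(msgs, "missing values are not allowed after ingestion")
  if (length(object@community) && min(object@community) < 0)
    msgs <- c(msgs, "community abundances must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' PredictorBlock: condensed microbial predictors for one dataset
#'
#' Holds the community-derived predictor vectors used downstream: ordination
#' axis scores, per-sample Shannon diversity, and (for functional-gene data)
#' gene abundance columns passed through unchanged. `provenance` records the
#' ordination method, transform, axes retained and variance explained so every
#' downstream report can state how the condensation was done.
#'
#' @slot axisScores numeric matrix (samples x retained axes; zero columns when
#'   no ordination was run).
#' @slot shannon numeric vector of per-sample Shannon indices (zero length
#'   when not computed).
#' @slot geneAbundances numeric matrix of functional-gene columns (zero
#'   columns for taxon-table data).
#' @slot provenance list describing the condensation.
#' @export
setClass("PredictorBlock",
  representation(
    axisScores = "matrix",
    shannon = "numeric",
    geneAbundances = "matrix",
    provenance = "list"
  ),
  prototype(
    axisScores = matrix(numeric(0), 0, 0),
    shannon = numeric(0),
    geneAbundances = matrix(numeric(0), 0, 0),
    provenance = list()
  )
)

setValidity("PredictorBlock", function(object) {
  msgs <- character(0)
  if (length(object@shannon) && any(object@shannon < 0))
    msgs <- c(msgs, "Shannon indices must be nonnegative")
  if (ncol(object@axisScores)) {
    cm <- colMeans(object@axisScores)
    if (any(abs(cm) > 1e-9))
      msgs <- c(msgs, "axis scores must be column-centered")
  }
  if (length(msgs)) msgs else TRUE
})

#' LinearModelFit: one ordinary-least-squares fit
#'
#' One candidate model in the all-subsets search: its predictor subset,
#' exact least-squares coefficients, residual sum of squares, Gaussian
#' maximum-likelihood log-likelihood, AICc and adjusted R-squared. The
#' parameter count `k` includes the intercept, the slopes and the residual
#' variance, which makes AICc values reproducible across software.
#'
#' A fit with numerically zero RSS (noiseless data) is flagged `degenerate`:
#' its log-likelihood is `+Inf` and its AICc `-Inf`, so it dominates any model
#' set, which is the correct limiting behaviour.
#'
#' @export
setClass("LinearModelFit",
  representation(
    predictors = "character",
    coefficients = "numeric",
    rss = "numeric",
    n = "integer",
    k = "integer",
    logLik = "numeric",
    aicc = "numeric",
    r2 = "numeric",
    adjR2 = "numeric",
    degenerate = "logical"
  )
)

setValidity("LinearModelFit", function(object) {
  msgs <- character(0)
  if (object@rss < 0) msgs <- c(msgs, "rss must be nonnegative")
  if (object@k > object@n - 2L)
    msgs <- c(msgs, "k must not exceed n - 2")
  if (!is.na(object@adjR2) && object@adjR2 > 1 + 1e-12)
    msgs <- c(msgs, "adjusted R2 cannot exceed 1")
  if (length(msgs)) msgs else TRUE
})

#' ModelSet: the delta-AICc-truncated candidate set
#'
#' The fits whose AICc lies within `threshold` (default 4) of the best fit,
#' sorted by AICc, together with their AICc differences and Akaike weights
#' renormalized over the retained set.
#'
#' @export
setClass("ModelSet",
  representation(
    fits = "list",
    delta = "numeric",
    weights = "numeric",
    threshold = "numeric"
  )
)

setValidity("ModelSet", function(object) {
  msgs <- character(0)
  if (!length(object@fits)) msgs <- c(msgs, "a ModelSet needs at least one fit")
  if (length(object@delta) != length(object@fits) ||
      length(object@weights) != length(object@fits))
    msgs <- c(msgs, "delta/weights must match the number of fits")
  if (length(object@delta) && any(object@delta < -1e-12))
    msgs <- c(msgs, "delta values must be nonnegative")
  if (length(object@delta) && any(object@delta > object@threshold + 1e-9))
    msgs <- c(msgs, "all retained fits must satisfy delta <= threshold")
  if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-12)
    msgs <- c(msgs, "Akaike weights must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' AveragedModel: the Akaike-weight-averaged final model
#'
#' Full-average coefficients over the union of predictors appearing in the
#' retained model set (a predictor absent from a model contributes zero to the
#' average), the predictions they imply, the adjusted R-squared of those
#' predictions penalized by the size of the predictor union, and the minimum
#' AICc of the set.
#'
#' @export
setClass("AveragedModel",
  representation(
    coefficients = "numeric",
    predictions = "numeric",
    adjR2 = "numeric",
    r2 = "numeric",
    bestAICc = "numeric",
    nModels = "integer",
    predictorUnion = "character",
    mode = "character",
    note = "character"
  ),
  prototype(mode = "full", note = character(0))
)

#' ComparisonResult: per-dataset predictor-set comparison
#'
#' For one dataset, the fit statistics of every predictor-set model (E, M, B
#' and their additive unions) and the improvement flags for each baseline
#' versus combined pair, under the dual statistical-plus-ecological criterion.
#'
#' @export
setClass("ComparisonResult",
  representation(
    datasetId = "character",
    perSet = "list",
    improvement = "list",
    metadata = "list",
    notes = "character"
  ),
  prototype(notes = character(0))
)
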
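#' @include AllClasses.R
NULL

#' @describeIn ProcessDataset-class dataset identifier
#' @param x an object of the documented class
#' @export
setMethod("datasetId", "ProcessDataset", function(x) x@datasetId)

#' @describeIn ProcessDataset-class environmental matrix
#' @export
setMethod("envData", "ProcessDataset", function(x) x@env)

#' @describeIn ProcessDataset-class community (or gene) abundance matrix
#' @export
setMethod("communityData", "ProcessDataset", function(x) x@community)

#' @describeIn ProcessDataset-class biomass vector, or `NULL` when absent
#' @export
setMethod("biomassData", "ProcessDataset", function(x)
  if (length(x@biomass)) x@biomass else NULL)

#' @describeIn ProcessDataset-class process-rate response vector
#' @export
setMethod("processRate", "ProcessDataset", function(x) x@process)

#' @describeIn ProcessDataset-class categorical metadata list
#' @export
setMethod("datasetMetadata", "ProcessDataset", function(x) x@metadata)

#' @describeIn ProcessDataset-class generating-truth record (empty list for
#'   real data)
#' @export
setMethod("truthRecord", "ProcessDataset", function(x) x@truth)

#' @describeIn ProcessDataset-class ordered sample identifiers
#' @export
setMethod("sampleIds", "ProcessDataset", function(x) rownames(x@env))

#' @describeIn ProcessDataset-class number of samples
#' @export
setMethod("nSamples", "ProcessDataset", function(x) nrow(x@env))

setMethod("show", "ProcessDataset", function(object) {
  md <- object@metadata
  cat("ProcessDataset \"", object@datasetId, "\"\n", sep = "")
  cat("  samples: ", nrow(object@env),
      "  env vars: ", ncol(object@env),
      "  community features: ", ncol(object@community),
      "  biomass: ", if (length(object@biomass)) "yes" else "no", "\n",
      sep = "")
  cat("  process: ", md$process_type %||% "?",
      " | environment: ", md$environment_type %||% "?",
      " | data: ", md$microbial_data_type %||% "?", "\n", sep = "")
  if (length(object@truth))
    cat("  simulated (truth record attached)\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn PredictorBlock-class ordination axis scores
#' @param x an object of the documented class
#' @export
setMethod("axisScores", "PredictorBlock", function(x) x@axisScores)

#' @describeIn PredictorBlock-class per-sample Shannon indices
#' @export
setMethod("shannonValues", "PredictorBlock", function(x) x@shannon)

#' @describeIn PredictorBlock-class functional-gene columns (zero columns for
#'   taxon tables)
#' @export
setMethod("geneAbundances", "PredictorBlock", function(x) x@geneAbundances)

#' @describeIn PredictorBlock-class record of how the block was built
#' @export
setMethod("provenance", "PredictorBlock", function(x) x@provenance)

setMethod("show", "PredictorBlock", function(object) {
  cat("PredictorBlock:",
      ncol(object@axisScores), "ordination axes,",
      if (length(object@shannon)) "Shannon," else "no Shannon,",
      ncol(object@geneAbundances), "gene columns\n")
  pv <- object@provenance
  if (!is.null(pv$method))
    cat("  ordination:", pv$method, "|",
        length(pv$variance_explained %||% numeric(0)),
        "axes retained\n")
})

#' @describeIn LinearModelFit-class adjusted R-squared of the fit
#' @param x an object of the documented class
#' @export
setMethod("adjR2", "LinearModelFit", function(x) x@adjR2)

setMethod("show", "LinearModelFit", function(object) {
  cat("LinearModelFit {",
      if (length(object@predictors)) paste(object@predictors, collapse = ", ")
      else "intercept only", "}\n")
  cat(sprintf("  n = %d, k = %d, AICc = %.4g, adjR2 = %.4g%s\n",
              object@n, object@k, object@aicc, object@adjR2,
              if (object@degenerate) " (degenerate: rss = 0)" else ""))
})

#' @describeIn ModelSet-class retained fits, sorted by AICc
#' @param x an object of the documented class
#' @export
setMethod("modelFits", "ModelSet", function(x) x@fits)

#' @describeIn ModelSet-class Akaike weights over the retained set
#' @export
setMethod("akaikeWeights", "ModelSet", function(x) x@weights)

#' @describeIn ModelSet-class AICc differences from the best model
#' @export
setMethod("deltaAICc", "ModelSet", function(x) x@delta)

#' @describeIn ModelSet-class minimum AICc in the set
#' @export
setMethod("bestAICc", "ModelSet", function(x) x@fits[[1L]]@aicc)

setMethod("show", "ModelSet", function(object) {
  cat("ModelSet:", length(object@fits), "model(s) within delta AICc <=",
      object@threshold, "\n")
  best <- object@fits[[1L]]
  cat("  best: {",
      if (length(best@predictors)) paste(best@predictors, collapse = ", ")
      else "intercept only",
      sprintf("} AICc = %.4g, weight = %.3f\n", best@aicc, object@weights[1L]))
})

#' @describeIn AveragedModel-class averaged coefficients (intercept first)
#' @param x an object of the documented class
#' @export
setMethod("averagedCoefficients", "AveragedModel", function(x) x@coefficients)

#' @describeIn AveragedModel-class adjusted R-squared of the averaged
#'   predictions
#' @export
setMethod("adjR2", "AveragedModel", function(x) x@adjR2)

#' @describeIn AveragedModel-class minimum AICc over the averaged set
#' @export
setMethod("bestAICc", "AveragedModel", function(x) x@bestAICc)

#' @describeIn AveragedModel-class union of predictors across the set
#' @export
setMethod("predictorUnion", "AveragedModel", function(x) x@predictorUnion)

#' @describeIn AveragedModel-class number of models averaged
#' @export
setMethod("nModels", "AveragedModel", function(x) x@nModels)

setMethod("show", "AveragedModel", function(object) {
  cat("AveragedModel over", object@nModels, "model(s);",
      length(object@predictorUnion), "predictor(s) in union\n")
  cat(sprintf("  adjR2 = %.4g, best AICc = %.4g (%s average)\n",
              object@adjR2, object@bestAICc, object@mode))
})

#' @describeIn ComparisonResult-class per-predictor-set fit statistics
#' @param x an object of the documented class
#' @export
setMethod("perSetStats", "ComparisonResult", function(x) x@perSet)

#' @describeIn ComparisonResult-class improvement flags per comparison pair
#' @export
setMethod("improvementFlags", "ComparisonResult", function(x) x@improvement)

#' @describeIn ComparisonResult-class dataset identifier
#' @export
setMethod("datasetId", "ComparisonResult", function(x) x@datasetId)

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult for \"", object@datasetId, "\"\n", sep = "")
  for (lab in names(object@perSet)) {
    st <- object@perSet[[lab]]
    cat(sprintf("  %-6s adjR2 = %6.3f  best AICc = %9.3f  (%d model%s)\n",
                lab, st$adj_r2, st$best_aicc, st$n_models,
                if (st$n_models == 1L) "" else "s"))
  }
  for (pair in names(object@improvement)) {
    fl <- object@improvement[[pair]]
    cat(sprintf("  %s: improved = %s (statistical %s, ecological %s, dAdjR2 = %.3f)\n",
                pair, fl$improved, fl$statistical, fl$ecological,
                fl$delta_adj_r2))
  }
})
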
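#' @include utils.R
NULL

#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @export
setGeneric("envData", function(x) standardGeneric("envData"))

#' @export
setGeneric("communityData", function(x) standardGeneric("communityData"))

#' @export
setGeneric("biomassData", function(x) standardGeneric("biomassData"))

#' @export
setGeneric("processRate", function(x) standardGeneric("processRate"))

#' @export
setGeneric("datasetMetadata", function(x) standardGeneric("datasetMetadata"))

#' @export
setGeneric("truthRecord", function(x) standardGeneric("truthRecord"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("axisScores", function(x) standardGeneric("axisScores"))

#' @export
setGeneric("shannonValues", function(x) standardGeneric("shannonValues"))

#' @export
setGeneric("geneAbundances", function(x) standardGeneric("geneAbundances"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("modelFits", function(x) standardGeneric("modelFits"))

#' @export
setGeneric("akaikeWeights", function(x) standardGeneric("akaikeWeights"))

#' @export
setGeneric("deltaAICc", function(x) standardGeneric("deltaAICc"))

#' @export
setGeneric("adjR2", function(x) standardGeneric("adjR2"))

#' @export
setGeneric("bestAICc", function(x) standardGeneric("bestAICc"))

#' @export
setGeneric("averagedCoefficients", function(x) standardGeneric("averagedCoefficients"))

#' @export
setGeneric("predictorUnion", function(x) standardGeneric("predictorUnion"))

#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @export
setGeneric("perSetStats", function(x) standardGeneric("perSetStats"))

#' @export
setGeneric("improvementFlags", function(x) standardGeneric("improvementFlags"))
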
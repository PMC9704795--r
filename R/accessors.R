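#' Accessors for the core classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors number of nodes of a parcellation (or of the
#'   matrix bound to one).
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @export
setMethod("nNodes", "Parcellation", function(x) nrow(x@nodes))

#' @export
setMethod("nNodes", "ConnectivityMatrix", function(x) nrow(x@values))

#' @describeIn accessors node table of a parcellation
#'   (node_id, network, lobe, hemisphere).
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @export
setMethod("nodeTable", "Parcellation", function(x) x@nodes)

#' @describeIn accessors per-node network labels.
#' @export
setGeneric("nodeNetworks", function(x) standardGeneric("nodeNetworks"))

#' @export
setMethod("nodeNetworks", "Parcellation", function(x) x@nodes$network)

#' @describeIn accessors per-node lobe labels.
#' @export
setGeneric("nodeLobes", function(x) standardGeneric("nodeLobes"))

#' @export
setMethod("nodeLobes", "Parcellation", function(x) x@nodes$lobe)

#' @describeIn accessors numeric matrix inside a
#'   \code{ConnectivityMatrix}.
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @export
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

#' @describeIn accessors kind tag of a \code{ConnectivityMatrix}.
#' @export
setGeneric("connKind", function(x) standardGeneric("connKind"))

#' @export
setMethod("connKind", "ConnectivityMatrix", function(x) x@kind)

#' @describeIn accessors subject table of a synthetic cohort.
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' @export
setMethod("subjectTable", "SyntheticCohort", function(x) x@subjects)

#' @describeIn accessors parcellation bound to an object.
#' @export
setGeneric("parcellation", function(x) standardGeneric("parcellation"))

#' @export
setMethod("parcellation", "SyntheticCohort", function(x) x@parcellation)

#' @describeIn accessors planted ground truth of a synthetic cohort.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setMethod("groundTruth", "SyntheticCohort", function(x) x@truth)

#' @describeIn accessors per-subject node-by-time series of a cohort.
#' @export
setGeneric("timeSeries", function(x) standardGeneric("timeSeries"))

#' @export
setMethod("timeSeries", "SyntheticCohort", function(x) x@timeseries)

#' @describeIn accessors per-subject streamline-weight matrices.
#' @export
setGeneric("streamlineWeights", function(x) standardGeneric("streamlineWeights"))

#' @export
setMethod("streamlineWeights", "SyntheticCohort", function(x) x@sc)

#' @describeIn accessors number of extracted/planted components.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @export
setMethod("nComponents", "PlsModel", function(x) x@ncomp)

#' @export
setMethod("nComponents", "GroundTruth", function(x) x@nComponents)

#' @describeIn accessors score matrix of a fitted PLS model.
#' @export
setGeneric("plsScores", function(x) standardGeneric("plsScores"))

#' @export
setMethod("plsScores", "PlsModel", function(x) x@scores)

#' @describeIn accessors predictor loading matrix of a fitted PLS model.
#' @export
setGeneric("plsLoadings", function(x) standardGeneric("plsLoadings"))

#' @export
setMethod("plsLoadings", "PlsModel", function(x) x@xLoadings)

#' @describeIn accessors predictor weight matrix of a fitted PLS model.
#' @export
setGeneric("plsWeights", function(x) standardGeneric("plsWeights"))

#' @export
setMethod("plsWeights", "PlsModel", function(x) x@weights)

#' @describeIn accessors RMSEP vector (depths 0..K) of a CV report.
#' @export
setGeneric("rmsep", function(x) standardGeneric("rmsep"))

#' @export
setMethod("rmsep", "CvReport", function(x) x@rmsep)

#' @describeIn accessors COG score vector of a cognition composite.
#' @export
setGeneric("cogScores", function(x) standardGeneric("cogScores"))

#' @export
setMethod("cogScores", "CogComposite", function(x) x@scores)

#' @describeIn accessors per-test loading vector of a cognition composite.
#' @export
setGeneric("cogLoadings", function(x) standardGeneric("cogLoadings"))

#' @export
setMethod("cogLoadings", "CogComposite", function(x) x@loadings)

setMethod("show", "Parcellation", function(object) {
  tab <- table(object@nodes$network)
  cat(sprintf("Parcellation: %d nodes, %d networks (%d frontal nodes)\n",
              nrow(object@nodes), length(tab),
              sum(object@nodes$lobe == "frontal")))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix [%s]: %d x %d, %d non-zero edges\n",
              object@kind, nrow(object@values), ncol(object@values),
              sum(object@values[upper.tri(object@values)] != 0)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d subjects, %d nodes, %d planted components (seed %d)\n",
    nrow(object@subjects), nNodes(object@parcellation),
    object@truth@nComponents, object@seed))
  cat(sprintf("  age %.1f-%.1f, target age-COG correlation %.2f\n",
              min(object@subjects$age), max(object@subjects$age),
              object@truth@ageEffectCog))
})

setMethod("show", "PlsModel", function(object) {
  cat(sprintf("PlsModel: %d components, %d predictors, %d subjects\n",
              object@ncomp, nrow(object@weights), nrow(object@scores)))
})

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport: leave-one-out RMSEP over depths 0..%d\n",
              object@maxComponents))
  print(round(object@rmsep, 3))
})

setMethod("show", "SplitEnsemble", function(object) {
  cat(sprintf(
    "SplitEnsemble: %d replicates at train fraction %.2f, depth %d%s\n",
    length(object@trainIndices), object@trainFraction,
    dim(object@xLoadings)[2],
    if (object@aligned) " (sign/order aligned)" else ""))
  cat("  mean held-out r(predicted, age) per cumulative depth: ",
      paste(round(colMeans(object@testR), 3), collapse = " "), "\n")
})

setMethod("show", "AgingProfile", function(object) {
  cat(sprintf(
    "AgingProfile (component %d): score-age r = %.3f, COG loading %.4f (%.4f)\n",
    object@component, object@ageCorrelation, object@cogMean, object@cogSd))
})

setMethod("show", "CogComposite", function(object) {
  cat(sprintf(
    "CogComposite: %d subjects, first PC explains %.1f%% (KMO = %.3f)\n",
    length(object@scores), 100 * object@explainedVariance, object@kmo))
})
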
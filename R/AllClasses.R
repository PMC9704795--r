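#' @import methods
#' @importFrom stats cor sd median quantile rnorm runif rbinom prcomp
#'   lm.fit qr qr.resid qr.fitted complete.cases pnorm pt var fft mvfft
#'   coef predict t.test p.adjust
NULL

CANONICAL_NETWORKS <- c("VN", "SMN", "LN", "FPN", "DMN", "DAN", "VAN")
CONN_KINDS <- c("FC", "FCz", "FCpos", "FCneg", "SC")

#' Parcellation of cortical nodes into networks and lobes
#'
#' Fixed division of the cortex into labelled nodes, each assigned to exactly
#' one of seven canonical resting-state networks (VN, SMN, LN, FPN, DMN, DAN,
#' VAN), one lobe (\code{frontal} or \code{other}) and one hemisphere. The
#' parcellation defines the intra- versus inter-network edge sets used by all
#' strength estimates.
#'
#' @slot nodes \code{data.frame} with columns \code{node_id} (0-based integer
#'   index), \code{network}, \code{lobe}, \code{hemisphere}.
#'
#' @seealso \code{\link{makeParcellation}}
#' @export
setClass("Parcellation", slots = c(nodes = "data.frame"))

setValidity("Parcellation", function(object) {
  nd <- object@nodes
  req <- c("node_id", "network", "lobe", "hemisphere")
  if (!all(req %in% colnames(nd)))
    return(paste("nodes must have columns:", paste(req, collapse = ", ")))
  n <- nrow(nd)
  if (n < 1L) return("parcellation must contain at least one node")
  if (!identical(as.integer(nd$node_id), 0:(n - 1L)))
    return("node_id must be the contiguous 0-based sequence 0..N-1")
  if (anyNA(nd$network) || anyNA(nd$lobe))
    return("every node needs exactly one network and one lobe")
  if (!all(nd$lobe %in% c("frontal", "other")))
    return("lobe must be 'frontal' or 'other'")
  if (!all(nd$hemisphere %in% c("left", "right")))
    return("hemisphere must be 'left' or 'right'")
  if (any(table(nd$network) < 1L)) return("each network must be non-empty")
  TRUE
})

#' Symmetric node-by-node connectivity matrix with a kind tag
#'
#' Holds one subject's connectivity estimates between parcellated nodes. The
#' \code{kind} tag distinguishes raw Pearson functional connectivity
#' (\code{FC}), Fisher-transformed FC (\code{FCz}), its sign-split halves
#' (\code{FCpos}, \code{FCneg}: positive z-values and absolute values of
#' negative z-values, respectively) and log-transformed structural
#' connectivity (\code{SC}). Only the upper triangle is authoritative; the
#' diagonal carries no information and is held at zero.
#'
#' @slot values numeric node-by-node matrix, symmetric.
#' @slot kind one of \code{"FC"}, \code{"FCz"}, \code{"FCpos"},
#'   \code{"FCneg"}, \code{"SC"}.
#' @slot logTransformed logical; guards against applying the SC log
#'   transform twice.
#'
#' @export
setClass("ConnectivityMatrix",
         slots = c(values = "matrix", kind = "character",
                   logTransformed = "logical"),
         prototype = prototype(logTransformed = FALSE))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("values must be a square numeric matrix")
  if (any(!is.finite(v))) return("values must be finite")
  if (max(abs(v - t(v))) > 1e-9) return("values must be symmetric")
  if (length(object@kind) != 1L || !(object@kind %in% CONN_KINDS))
    return(paste("kind must be one of:", paste(CONN_KINDS, collapse = ", ")))
  if (object@kind %in% c("FCpos", "FCneg", "SC") && min(v) < 0)
    return(paste(object@kind, "entries must be non-negative"))
  if (object@kind == "FC" && (max(v) > 1 || min(v) < -1))
    return("raw FC entries must lie in [-1, 1]")
  TRUE
})

#' Planted ground truth of a synthetic cohort
#'
#' Records the latent structure a synthetic cohort was generated from, so
#' that recovery of the planted components can be tested downstream. The
#' component loadings live directly in predictor (feature) space: one signed
#' weight per node-wise strength predictor plus the cognition score, per
#' planted component, oriented so that a positive loading means the predictor
#' decreases at higher ages.
#'
#' @slot nComponents integer, number of planted latent components.
#' @slot componentLoadings numeric matrix, predictors x components; row names
#'   follow the feature-block predictor naming.
#' @slot ageEffectCog target correlation between age and the cognition
#'   latent (default -0.44).
#' @slot frontalDeclineRate per-year decline slope of log edge weight for
#'   frontal-incident structural edges.
#' @slot otherDeclineRate per-year decline slope for all other edges; its
#'   magnitude never exceeds \code{frontalDeclineRate}'s.
#' @slot noise named numeric vector of noise standard deviations per channel.
#' @slot params list of remaining generator settings (latent-age
#'   correlations, coupling strengths, baseline levels).
#'
#' @export
setClass("GroundTruth",
         slots = c(nComponents = "integer", componentLoadings = "matrix",
                   ageEffectCog = "numeric", frontalDeclineRate = "numeric",
                   otherDeclineRate = "numeric", noise = "numeric",
                   params = "list"))

setValidity("GroundTruth", function(object) {
  if (length(object@nComponents) != 1L || object@nComponents < 1L)
    return("nComponents must be a positive integer")
  if (any(!is.finite(object@componentLoadings)))
    return("component loadings must be finite")
  if (abs(object@frontalDeclineRate) < abs(object@otherDeclineRate))
    return("frontal decline rate must be at least as large in magnitude as the other-edge rate")
  TRUE
})

#' A generated cohort of synthetic subjects
#'
#' Bundles a subject table (age, sex, education, 16 cognitive test scores),
#' per-subject node-by-time BOLD-like series, per-subject streamline-weight
#' matrices, the parcellation and the planted ground truth, together with the
#' seed that reproduces the cohort bit-for-bit.
#'
#' @slot subjects \code{data.frame}: \code{subject_id}, \code{age},
#'   \code{sex}, \code{education}, \code{test_01}..\code{test_16}.
#' @slot timeseries list of node-by-time matrices, one per subject.
#' @slot sc list of node-by-node streamline-weight matrices, one per subject.
#' @slot parcellation a \code{\linkS4class{Parcellation}}.
#' @slot truth a \code{\linkS4class{GroundTruth}}.
#' @slot seed integer seed the cohort was generated from.
#'
#' @seealso \code{\link{simulateCohort}}
#' @export
setClass("SyntheticCohort",
         slots = c(subjects = "data.frame", timeseries = "list",
                   sc = "list", parcellation = "Parcellation",
                   truth = "GroundTruth", seed = "integer"))

setValidity("SyntheticCohort", function(object) {
  n <- nrow(object@subjects)
  if (length(object@timeseries) != n || length(object@sc) != n)
    return("one time-series and one SC matrix required per subject")
  if (any(object@subjects$age < 55 - 1e-9) ||
      any(object@subjects$age > 85 + 1e-9))
    return("ages must lie within the generator range [55, 85]")
  TRUE
})

#' Subjects-by-predictors block for partial least squares regression
#'
#' Extends \code{SummarizedExperiment}: the assay holds predictors in rows
#' (6 strength estimates per node, ordered node-major as SC_intra, SC_inter,
#' FCpos_intra, FCpos_inter, FCneg_intra, FCneg_inter, optionally followed by
#' the cognition score COG) and subjects in columns. \code{rowData} tags each
#' predictor with its node, matrix kind, intra/inter scope, network and lobe;
#' \code{colData} carries the subject covariates (age, sex, education).
#'
#' @seealso \code{\link{assembleFeatures}}, \code{\link{residualize}}
#' @export
#' @import SummarizedExperiment
setClass("FeatureBlock", contains = "SummarizedExperiment")

setValidity("FeatureBlock", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("FeatureBlock needs a 'features' assay")
  if (anyNA(SummarizedExperiment::assay(object, "features")))
    return("feature block must not contain missing values")
  req <- c("predictor", "kind", "scope")
  if (!all(req %in% colnames(SummarizedExperiment::rowData(object))))
    return(paste("rowData must carry columns:", paste(req, collapse = ", ")))
  TRUE
})

#' Fitted NIPALS partial least squares regression (single response)
#'
#' Stores the factors of a PLS1 decomposition: predictor weights, predictor
#' loadings, response loadings, per-subject score values and the centering
#' (and optional scaling) offsets; predictions at any depth up to
#' \code{ncomp} are reproducible from the stored factors.
#'
#' @slot weights p x k predictor weight matrix (unit-norm columns).
#' @slot xLoadings p x k predictor loading matrix.
#' @slot yLoadings length-k response loadings.
#' @slot scores n x k score matrix; columns mutually orthogonal.
#' @slot xMeans,yMean centering offsets.
#' @slot xScales per-predictor scaling factors (all one when unscaled).
#' @slot ncomp number of extracted components.
#'
#' @seealso \code{\link{nipalsFit}}
#' @export
setClass("PlsModel",
         slots = c(weights = "matrix", xLoadings = "matrix",
                   yLoadings = "numeric", scores = "matrix",
                   xMeans = "numeric", yMean = "numeric",
                   xScales = "numeric", ncomp = "integer"))

setValidity("PlsModel", function(object) {
  k <- object@ncomp
  if (ncol(object@weights) != k || ncol(object@xLoadings) != k ||
      length(object@yLoadings) != k || ncol(object@scores) != k)
    return("factor dimensions must agree with ncomp")
  if (k >= 2L) {
    g <- crossprod(object@scores)
    if (max(abs(g[upper.tri(g)])) > 1e-8 * max(diag(g)))
      return("score vectors must be mutually orthogonal")
  }
  TRUE
})

#' Leave-one-out cross-validation report for a PLS regression
#'
#' Per candidate component count k = 0..K (k = 0 is the mean-only model):
#' the root mean squared error of prediction (RMSEP, response units) and the
#' per-subject held-out squared errors that feed the randomization test used
#' for component selection, plus training-data variance accounting.
#'
#' @slot rmsep named numeric, RMSEP per depth 0..K.
#' @slot looErrors n x (K+1) matrix of held-out squared errors.
#' @slot xVarianceUsed cumulative percent of centered predictor
#'   sum-of-squares captured, per depth 1..K (training data).
#' @slot yVarianceExplained cumulative percent of response variance
#'   explained, per depth 1..K (training data).
#' @slot maxComponents K.
#'
#' @seealso \code{\link{looRmsep}}, \code{\link{selectNcomp}}
#' @export
setClass("CvReport",
         slots = c(rmsep = "numeric", looErrors = "matrix",
                   xVarianceUsed = "numeric", yVarianceExplained = "numeric",
                   maxComponents = "integer"))

setValidity("CvReport", function(object) {
  if (any(object@rmsep < 0)) return("RMSEP must be non-negative")
  if (length(object@rmsep) != object@maxComponents + 1L)
    return("one RMSEP per depth 0..maxComponents required")
  if (ncol(object@looErrors) != object@maxComponents + 1L)
    return("looErrors must have one column per depth 0..maxComponents")
  TRUE
})

#' Ensemble of repeated train/test split fits
#'
#' Results of fitting the PLS model on many random train subsets and
#' predicting age on the held-out subjects, the backbone of profile
#' stability: per-replicate predictor loadings, weights, response loadings
#' and centering offsets, plus the held-out correlation between predicted and
#' chronological age at every cumulative depth.
#'
#' @slot xLoadings p x k x reps array of predictor loadings.
#' @slot weights p x k x reps array of predictor weights.
#' @slot yLoadings k x reps matrix of response loadings.
#' @slot xMeans p x reps matrix of training centering offsets.
#' @slot yMeans per-replicate response centering offset.
#' @slot testR reps x k matrix: held-out r(predicted, chronological age)
#'   using cumulative components 1..k.
#' @slot testRmsep reps x k matrix of held-out RMSEP per cumulative depth.
#' @slot trainIndices list of training index vectors.
#' @slot reference full-sample \code{\linkS4class{PlsModel}} used as the
#'   sign/order alignment reference.
#' @slot trainFraction,seed split configuration.
#' @slot aligned logical; whether \code{\link{alignSigns}} has been applied.
#'
#' @seealso \code{\link{repeatedSplits}}, \code{\link{alignSigns}}
#' @export
setClass("SplitEnsemble",
         slots = c(xLoadings = "array", weights = "array",
                   yLoadings = "matrix", xMeans = "matrix",
                   yMeans = "numeric", testR = "matrix",
                   testRmsep = "matrix", trainIndices = "list",
                   reference = "PlsModel", trainFraction = "numeric",
                   seed = "integer", aligned = "logical"))

setValidity("SplitEnsemble", function(object) {
  reps <- length(object@trainIndices)
  if (dim(object@xLoadings)[3] != reps || nrow(object@testR) != reps)
    return("per-replicate slots must agree on the number of replicates")
  if (object@trainFraction <= 0.5 || object@trainFraction >= 0.95)
    return("trainFraction must lie in (0.5, 0.95)")
  TRUE
})

#' One PLS component summarized as an aging profile
#'
#' A component's full set of predictor loadings averaged across split
#' replicates (with SDs), its cognition loading, network-wise average mean
#' loadings per matrix kind and scope, and the correlation of its score
#' values with chronological age. Loadings are oriented so that a positive
#' loading marks a predictor whose value is lower at higher ages.
#'
#' @slot component component index.
#' @slot predictorMeans,predictorSds named per-predictor mean and SD of the
#'   aligned loadings across replicates.
#' @slot cogMean,cogSd cognition-score loading summary (NA when the feature
#'   block carries no COG predictor).
#' @slot networkSummary \code{data.frame}: network x (kind, scope) average
#'   mean loadings.
#' @slot ageCorrelation,ageCorrelationP Pearson r between component scores
#'   and age, with p-value.
#'
#' @seealso \code{\link{meanLoadings}}, \code{\link{networkMeanLoadings}}
#' @export
setClass("AgingProfile",
         slots = c(component = "integer", predictorMeans = "numeric",
                   predictorSds = "numeric", cogMean = "numeric",
                   cogSd = "numeric", networkSummary = "data.frame",
                   ageCorrelation = "numeric", ageCorrelationP = "numeric"))

#' PCA-based global cognition composite
#'
#' First principal component of the standardized, screened and imputed
#' 16-test battery, oriented so that the majority of test loadings are
#' positive (higher COG = better performance), together with the per-test
#' loadings, the explained-variance share and the Kaiser-Meyer-Olkin
#' sampling-adequacy index of the battery.
#'
#' @slot scores named per-subject COG values (zero mean, unit variance).
#' @slot loadings unit-norm per-test loading vector.
#' @slot explainedVariance fraction of battery variance on the first
#'   component.
#' @slot kmo overall KMO index in [0, 1].
#' @slot subjectIds ids of the retained subjects, in score order.
#'
#' @seealso \code{\link{pcaCog}}, \code{\link{kmo}}
#' @export
setClass("CogComposite",
         slots = c(scores = "numeric", loadings = "numeric",
                   explainedVariance = "numeric", kmo = "numeric",
                   subjectIds = "character"))

setValidity("CogComposite", function(object) {
  if (abs(sqrt(sum(object@loadings^2)) - 1) > 1e-8)
    return("loadings must have unit norm")
  if (length(object@scores) != length(object@subjectIds))
    return("one score per retained subject required")
  TRUE
})
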
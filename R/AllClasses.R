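#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm runif sd var median
#' @importFrom utils read.csv write.csv count.fields packageVersion
NULL

.monotone <- function(x) {
    d <- diff(x)
    all(d > 0) || all(d < 0)
}

#' SpectralSet: labelled spectral matrices
#'
#' An S4 container for a set of spectra with a shared wavenumber axis and
#' per-sample class labels, extending
#' \linkS4class{SummarizedExperiment}. Following the Bioconductor
#' features-in-rows convention, the \code{"intensity"} assay is a
#' channels x samples matrix; \code{rowData} carries the wavenumber axis
#' (reciprocal centimetres, stored strictly ascending) and \code{colData}
#' the class label and optional replicate-group id of each sample.
#'
#' Use [SpectralSet()] to construct one from a samples x channels matrix,
#' [intensities()] to recover that matrix, [wavenumbers()],
#' [spectraLabels()] and [replicateIds()] for the annotation.
#'
#' @name SpectralSet-class
#' @aliases SpectralSet-class
#' @exportClass SpectralSet
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
    msgs <- character()
    if (!("intensity" %in% SummarizedExperiment::assayNames(object)))
        msgs <- c(msgs, "assay 'intensity' is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!("wavenumber" %in% colnames(rd))) {
        msgs <- c(msgs, "rowData column 'wavenumber' is required")
    } else {
        wn <- rd$wavenumber
        if (!is.numeric(wn) || anyNA(wn))
            msgs <- c(msgs, "wavenumbers must be numeric and non-missing")
        else if (length(wn) > 1 && !all(diff(wn) > 0))
            msgs <- c(msgs, "wavenumbers must be strictly ascending")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!("label" %in% colnames(cd)))
        msgs <- c(msgs, "colData column 'label' is required")
    else if (anyNA(cd$label))
        msgs <- c(msgs, "labels must be non-missing")
    if ("intensity" %in% SummarizedExperiment::assayNames(object)) {
        a <- SummarizedExperiment::assay(object, "intensity")
        if (!is.numeric(a) || anyNA(a) || any(!is.finite(a)))
            msgs <- c(msgs, "intensities must be finite numeric values")
    }
    if (length(msgs)) msgs else TRUE
})

#' PreprocessModel: a fitted spectral preprocessing chain
#'
#' Holds an ordered chain of preprocessing steps (subset of
#' \code{"SG"}, \code{"SNV"}, \code{"MSC"}, \code{"MC"}) together with the
#' training-derived statistics needed to apply it to new spectra: the MSC
#' reference spectrum (training mean) and the per-channel means for mean
#' centring. Savitzky-Golay settings are stored as window/polyorder.
#'
#' @slot steps character vector of operator tags, applied in order.
#' @slot sgWindow odd window length in channels.
#' @slot sgPolyorder polynomial order, less than \code{sgWindow}.
#' @slot mscReference numeric reference spectrum (length d) or length 0.
#' @slot mcMeans numeric per-channel means (length d) or length 0.
#' @exportClass PreprocessModel
setClass("PreprocessModel",
    representation(steps = "character", sgWindow = "integer",
        sgPolyorder = "integer", mscReference = "numeric",
        mcMeans = "numeric"))

setValidity("PreprocessModel", function(object) {
    msgs <- character()
    known <- c("SG", "SNV", "MSC", "MC")
    if (!length(object@steps))
        msgs <- c(msgs, "steps must be non-empty")
    if (!all(object@steps %in% known))
        msgs <- c(msgs, sprintf("unknown step tag(s): %s",
            paste(setdiff(object@steps, known), collapse = ", ")))
    if (anyDuplicated(object@steps))
        msgs <- c(msgs, "each step may appear at most once")
    if ("SG" %in% object@steps) {
        if (object@sgWindow %% 2L != 1L)
            msgs <- c(msgs, "sgWindow must be odd")
        if (object@sgWindow < object@sgPolyorder + 2L)
            msgs <- c(msgs, "sgWindow must be >= sgPolyorder + 2")
    }
    if (("MSC" %in% object@steps) != (length(object@mscReference) > 0))
        msgs <- c(msgs, "mscReference present iff MSC is in steps")
    if (("MC" %in% object@steps) != (length(object@mcMeans) > 0))
        msgs <- c(msgs, "mcMeans present iff MC is in steps")
    if (length(msgs)) msgs else TRUE
})

#' PCAModel: principal components fitted on training spectra
#'
#' @slot center training mean spectrum, length d.
#' @slot loadings npc x d matrix with orthonormal rows, signs fixed so the
#'   largest-magnitude element of each row is positive.
#' @slot eigenvalues npc non-negative variances, non-increasing.
#' @slot explainedRatio proportion of total variance per component.
#' @slot npc retained component count.
#' @exportClass PCAModel
setClass("PCAModel",
    representation(center = "numeric", loadings = "matrix",
        eigenvalues = "numeric", explainedRatio = "numeric",
        npc = "integer"))

setValidity("PCAModel", function(object) {
    msgs <- character()
    if (nrow(object@loadings) != object@npc)
        msgs <- c(msgs, "loadings must have npc rows")
    if (ncol(object@loadings) != length(object@center))
        msgs <- c(msgs, "loadings columns must match center length")
    G <- tcrossprod(object@loadings)
    if (max(abs(G - diag(nrow(G)))) > 1e-8)
        msgs <- c(msgs, "loadings rows must be orthonormal (tol 1e-8)")
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
        msgs <- c(msgs, "eigenvalues must be non-increasing")
    if (any(object@eigenvalues < -1e-12))
        msgs <- c(msgs, "eigenvalues must be non-negative")
    if (sum(object@explainedRatio) > 1 + 1e-12)
        msgs <- c(msgs, "explained ratios must sum to at most 1")
    if (length(msgs)) msgs else TRUE
})

#' MembershipMatrix: fuzzy class memberships
#'
#' One-pass fuzzy-c-means memberships of n samples in c classes, computed
#' from fixed cluster centres (the crisp class means) with weight exponent
#' m. Every membership lies in [0, 1] and every row sums to 1.
#'
#' @slot U n x c membership matrix.
#' @slot centers c x d matrix of cluster centres.
#' @slot m fuzzy weight exponent, greater than 1.
#' @exportClass MembershipMatrix
setClass("MembershipMatrix",
    representation(U = "matrix", centers = "matrix", m = "numeric"))

setValidity("MembershipMatrix", function(object) {
    msgs <- character()
    if (ncol(object@U) != nrow(object@centers))
        msgs <- c(msgs, "U columns must match number of centres")
    if (any(object@U < -1e-12) || any(object@U > 1 + 1e-12))
        msgs <- c(msgs, "memberships must lie in [0, 1]")
    if (any(abs(rowSums(object@U) - 1) > 1e-10))
        msgs <- c(msgs, "membership rows must sum to 1 (tol 1e-10)")
    if (object@m <= 1)
        msgs <- c(msgs, "fuzzy exponent m must exceed 1")
    if (length(msgs)) msgs else TRUE
})

#' DiscriminantModel: a fitted LDA / DLDA / FDLDA transformation
#'
#' Stores the (c-1) x d transformation matrix W together with the scatter
#' matrices it was derived from. For DLDA and FDLDA, W simultaneously
#' diagonalizes the scatter pair: W Sw W' is the identity and W Sb W' is
#' diagonal.
#'
#' @slot W transformation matrix, at most c-1 rows.
#' @slot algorithm one of "LDA", "DLDA", "FDLDA".
#' @slot Sw within-class scatter used in the fit (crisp or fuzzy).
#' @slot Sb between-class scatter used in the fit (crisp or fuzzy).
#' @slot diagWithin eigenvalues of the transformed within-class scatter.
#' @slot m fuzzy exponent (NA unless FDLDA).
#' @slot classLevels class labels seen during fitting, in level order.
#' @exportClass DiscriminantModel
setClass("DiscriminantModel",
    representation(W = "matrix", algorithm = "character", Sw = "matrix",
        Sb = "matrix", diagWithin = "numeric", m = "numeric",
        classLevels = "character"))

setValidity("DiscriminantModel", function(object) {
    msgs <- character()
    if (!object@algorithm %in% c("LDA", "DLDA", "FDLDA"))
        msgs <- c(msgs, "algorithm must be LDA, DLDA or FDLDA")
    c <- length(object@classLevels)
    if (c >= 2 && nrow(object@W) > c - 1)
        msgs <- c(msgs, "W must have at most c-1 rows")
    if (length(msgs)) msgs else TRUE
})

#' KNNModel: a k-nearest-neighbour classifier
#'
#' @slot K odd neighbour count.
#' @slot trainScores n x p training feature matrix.
#' @slot trainLabels factor of length n.
#' @exportClass KNNModel
setClass("KNNModel",
    representation(K = "integer", trainScores = "matrix",
        trainLabels = "factor"))

setValidity("KNNModel", function(object) {
    msgs <- character()
    if (object@K %% 2L != 1L)
        msgs <- c(msgs, "K must be odd")
    if (object@K < 1L || object@K > nrow(object@trainScores))
        msgs <- c(msgs, "K must lie in [1, n]")
    if (length(object@trainLabels) != nrow(object@trainScores))
        msgs <- c(msgs, "labels must match training rows")
    if (length(msgs)) msgs else TRUE
})

#' ELMModel: a single-hidden-layer extreme learning machine
#'
#' Input weights and biases are drawn uniformly from [-1, 1] under a
#' stated seed; output weights are the minimum-norm least-squares solution
#' (Moore-Penrose pseudoinverse) mapping the hidden activations to one-hot
#' class targets.
#'
#' @slot inputWeights hidden x p matrix.
#' @slot biases length-hidden vector.
#' @slot outputWeights hidden x c matrix.
#' @slot activation activation tag (currently "sigmoid").
#' @slot seed integer seed used for the random layer.
#' @slot classLevels class labels in level order.
#' @exportClass ELMModel
setClass("ELMModel",
    representation(inputWeights = "matrix", biases = "numeric",
        outputWeights = "matrix", activation = "character",
        seed = "integer", classLevels = "character"))

setValidity("ELMModel", function(object) {
    msgs <- character()
    if (nrow(object@inputWeights) < 1L)
        msgs <- c(msgs, "at least one hidden neuron required")
    if (length(object@biases) != nrow(object@inputWeights))
        msgs <- c(msgs, "one bias per hidden neuron required")
    if (any(!is.finite(object@outputWeights)))
        msgs <- c(msgs, "output weights must be finite")
    if (length(msgs)) msgs else TRUE
})

#' NBModel: Gaussian naive Bayes
#'
#' @slot means c x p per-class feature means.
#' @slot variances c x p per-class feature variances (floored).
#' @slot priors class prior proportions, summing to 1.
#' @slot varianceFloor the floor applied to the variances.
#' @slot classLevels class labels in level order.
#' @exportClass NBModel
setClass("NBModel",
    representation(means = "matrix", variances = "matrix",
        priors = "numeric", varianceFloor = "numeric",
        classLevels = "character"))

setValidity("NBModel", function(object) {
    msgs <- character()
    if (abs(sum(object@priors) - 1) > 1e-12)
        msgs <- c(msgs, "priors must sum to 1")
    if (any(object@variances < object@varianceFloor - 1e-15))
        msgs <- c(msgs, "variances must respect the floor")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticSpec: parameters of the synthetic NIR generator
#'
#' Describes a milk-like synthetic dataset: Gaussian absorption peaks on a
#' smooth baseline, per-sample affine scatter (a multiplicative gain, the
#' regression slope against the template, plus an additive offset),
#' replicate scans sharing a noiseless template, and additive white noise. The \code{overlap} control shrinks
#' the amplitude differences of the designated overlapping classes toward
#' their common mean (0 = fully separated as configured, 1 = identical).
#'
#' @slot nClasses number of classes.
#' @slot samplesPerClass samples per class.
#' @slot replicates replicate scans per sample.
#' @slot axis wavenumber grid (cm^-1), ascending.
#' @slot peakCenters peak positions (cm^-1).
#' @slot peakWidths per-peak Gaussian standard deviations (cm^-1).
#' @slot classAmplitudes c x n_peaks matrix of peak heights.
#' @slot overlapClasses indices of the classes whose amplitudes are pulled
#'   together by \code{overlap}.
#' @slot baselineCoef coefficients (intercept, slope, quadratic) of the
#'   smooth baseline over the standardized axis.
#' @slot scatterSlopeSd sd of the per-sample multiplicative gain.
#' @slot scatterOffsetSd sd of the per-sample additive offset.
#' @slot noiseSd sd of the additive white noise.
#' @slot overlap overlap control in [0, 1].
#' @slot seed integer seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(nClasses = "integer", samplesPerClass = "integer",
        replicates = "integer", axis = "numeric", peakCenters = "numeric",
        peakWidths = "numeric", classAmplitudes = "matrix",
        overlapClasses = "integer", baselineCoef = "numeric",
        scatterSlopeSd = "numeric", scatterOffsetSd = "numeric",
        noiseSd = "numeric", overlap = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msgs <- character()
    if (object@nClasses < 2L)
        msgs <- c(msgs, "at least two classes required")
    if (object@samplesPerClass < 1L || object@replicates < 1L)
        msgs <- c(msgs, "counts must be positive")
    if (!all(diff(object@axis) > 0))
        msgs <- c(msgs, "axis must be strictly ascending")
    if (any(object@peakWidths <= 0))
        msgs <- c(msgs, "peak widths must be positive")
    if (object@scatterSlopeSd < 0 || object@scatterOffsetSd < 0 ||
        object@noiseSd < 0)
        msgs <- c(msgs, "spreads and noise sd must be non-negative")
    if (any(!is.finite(object@classAmplitudes)))
        msgs <- c(msgs, "amplitudes must be finite")
    if (nrow(object@classAmplitudes) != object@nClasses ||
        ncol(object@classAmplitudes) != length(object@peakCenters))
        msgs <- c(msgs, "classAmplitudes must be nClasses x nPeaks")
    if (object@overlap < 0 || object@overlap > 1)
        msgs <- c(msgs, "overlap must lie in [0, 1]")
    if (any(object@overlapClasses < 1L) ||
        any(object@overlapClasses > object@nClasses))
        msgs <- c(msgs, "overlapClasses out of range")
    if (length(msgs)) msgs else TRUE
})

#' ExperimentConfig: one pipeline configuration
#'
#' Everything needed to run one end-to-end experiment: a data source
#' (a SpectralSet or a SyntheticSpec to generate one), the preprocessing
#' chain, PCA component count, feature-extraction method with its fuzzy
#' exponent, the classifier with its hyperparameters, and the stratified
#' split fraction and seed.
#'
#' @slot data a SpectralSet, or NULL to generate from \code{spec}.
#' @slot spec a SyntheticSpec, or NULL when \code{data} is given.
#' @slot steps preprocessing chain tags.
#' @slot sgWindow,sgPolyorder Savitzky-Golay settings.
#' @slot npc PCA component count.
#' @slot method feature extractor: "lda", "dlda" or "fdlda".
#' @slot m fuzzy weight exponent (FDLDA).
#' @slot classifier "knn", "elm" or "nb".
#' @slot k KNN neighbour count.
#' @slot hidden ELM hidden-neuron count.
#' @slot elmRuns number of ELM repetitions averaged (seeds 1..runs).
#' @slot testFraction held-out proportion per class.
#' @slot splitSeed seed of the stratified split.
#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
    representation(data = "ANY", spec = "ANY", steps = "character",
        sgWindow = "integer", sgPolyorder = "integer", npc = "integer",
        method = "character", m = "numeric", classifier = "character",
        k = "integer", hidden = "integer", elmRuns = "integer",
        testFraction = "numeric", splitSeed = "integer"))

setValidity("ExperimentConfig", function(object) {
    msgs <- character()
    if (!object@method %in% c("lda", "dlda", "fdlda"))
        msgs <- c(msgs, "method must be lda, dlda or fdlda")
    if (!object@classifier %in% c("knn", "elm", "nb"))
        msgs <- c(msgs, "classifier must be knn, elm or nb")
    if (is.null(object@data) && is.null(object@spec))
        msgs <- c(msgs, "either data or spec must be supplied")
    if (object@testFraction <= 0 || object@testFraction >= 1)
        msgs <- c(msgs, "testFraction must lie in (0, 1)")
    if (object@method == "fdlda" && object@m <= 1)
        msgs <- c(msgs, "fuzzy exponent m must exceed 1")
    if (length(msgs)) msgs else TRUE
})

#' ExperimentReport: results of one or more pipeline runs
#'
#' @slot results data.frame with one row per configuration: the settings
#'   and the test accuracy in percent (2 decimals).
#' @slot confusion list of per-run confusion tables (predicted x truth).
#' @slot models list of fitted-model summaries for the last run.
#' @slot provenance list with seed, timestamp and package version.
#' @exportClass ExperimentReport
setClass("ExperimentReport",
    representation(results = "data.frame", confusion = "list",
        models = "list", provenance = "list"))

setValidity("ExperimentReport", function(object) {
    msgs <- character()
    if (nrow(object@results) &&
        (any(object@results$accuracy < 0) ||
         any(object@results$accuracy > 100)))
        msgs <- c(msgs, "accuracies must lie in [0, 100] percent")
    if (length(msgs)) msgs else TRUE
})
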
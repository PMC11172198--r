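# Fixed default amplitude matrix for the milk-like generator: 5 classes x
# 6 peaks (fat C-H ~6250, protein N-H ~6579/6849, lactose ~7112, protein
# ~8833, water O-H ~10417 cm-1). Classes 1-3 are the designated
# overlapping trio; 4-5 are well separated. Arbitrary fixed constants;
# no claim of matching real milk chemistry.
.milkAmplitudes <- function() {
    matrix(c(
        0.62, 0.45, 0.38, 0.95, 0.30, 0.52,
        0.58, 0.50, 0.34, 0.88, 0.34, 0.49,
        0.66, 0.41, 0.42, 0.91, 0.27, 0.55,
        0.35, 0.72, 0.60, 0.70, 0.50, 0.30,
        0.90, 0.25, 0.20, 1.15, 0.15, 0.75),
        nrow = 5, byrow = TRUE)
}

#' Canonical milk-like synthetic dataset specification
#'
#' Returns the default \linkS4class{SyntheticSpec}: 5 classes x 60 samples
#' x 3 replicate scans on a 228-channel axis spanning 5882-11111 cm^-1,
#' with six Gaussian absorption peaks at the wavenumbers where milk
#' spectra show fat, protein, lactose and water features. Three of the
#' five classes are designated "overlapping": the \code{overlap} control
#' linearly shrinks their amplitude differences toward the trio mean, so
#' that \code{overlap = 0} keeps the configured separations and
#' \code{overlap = 1} makes the trio's amplitude rows identical.
#'
#' @param overlap scalar in [0, 1].
#' @param seed integer seed for [simulateSpectra()].
#' @param noiseSd additive white-noise standard deviation.
#' @param scatterSlopeSd,scatterOffsetSd spreads of the per-sample affine
#'   scatter (multiplicative gain; additive offset).
#' @param replicates replicate scans per sample.
#' @return a \linkS4class{SyntheticSpec}.
#' @examples
#' spec <- syntheticMilkSpec(overlap = 0.5, seed = 42)
#' ds <- simulateSpectra(spec)
#' @export
syntheticMilkSpec <- function(overlap = 0.5, seed = 1L, noiseSd = 0.05,
                              scatterSlopeSd = 0.05,
                              scatterOffsetSd = 0.02, replicates = 3L) {
    if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
    new("SyntheticSpec",
        nClasses = 5L, samplesPerClass = 60L,
        replicates = as.integer(replicates),
        axis = seq(5882, 11111, length.out = 228),
        peakCenters = c(6250, 6579, 6849, 7112, 8833, 10417),
        peakWidths = c(130, 95, 95, 160, 220, 260),
        classAmplitudes = .milkAmplitudes(),
        overlapClasses = 1:3,
        baselineCoef = c(0.15, 0.05, 0.02),
        scatterSlopeSd = scatterSlopeSd,
        scatterOffsetSd = scatterOffsetSd,
        noiseSd = noiseSd, overlap = overlap, seed = as.integer(seed))
}

#' Effective class-amplitude matrix after applying the overlap control
#'
#' Amplitude rows of the designated overlapping classes are interpolated
#' linearly toward their common mean: at overlap w, row_j becomes
#' (1 - w) row_j + w mean(rows).
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return c x n_peaks matrix.
#' @export
effectiveAmplitudes <- function(spec) {
    A <- spec@classAmplitudes
    ov <- spec@overlapClasses
    if (length(ov) >= 2 && spec@overlap > 0) {
        target <- colMeans(A[ov, , drop = FALSE])
        for (j in ov)
            A[j, ] <- (1 - spec@overlap) * A[j, ] + spec@overlap * target
    }
    A
}

#' Generate a synthetic NIR dataset
#'
#' Each sample's noiseless template is the smooth baseline plus the sum of
#' its class's Gaussian peaks, distorted by a per-sample affine scatter in
#' the multiplicative-scatter-correction sense: multiplied by a gain
#' (1 + slope) and shifted by an offset, so that SNV and MSC correct the
#' distortion exactly. Replicate scans share the template and differ only
#' in additive white noise. Class labels come out in contiguous blocks (all of class 1,
#' then class 2, ...). Deterministic for a fixed \code{spec@seed}.
#'
#' @param spec a \linkS4class{SyntheticSpec}, e.g. [syntheticMilkSpec()].
#' @return a \linkS4class{SpectralSet} with
#'   \code{nClasses * samplesPerClass * replicates} spectra; replicate ids
#'   are set when \code{replicates > 1}.
#' @export
simulateSpectra <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    axis <- spec@axis
    z <- (axis - mean(axis)) / sd(axis)     # standardized axis
    A <- effectiveAmplitudes(spec)
    baseline <- spec@baselineCoef[1] + spec@baselineCoef[2] * z +
        spec@baselineCoef[3] * z^2
    peaks <- vapply(seq_along(spec@peakCenters), function(p)
        exp(-0.5 * ((axis - spec@peakCenters[p]) / spec@peakWidths[p])^2),
        numeric(length(axis)))               # d x nPeaks
    nc <- spec@nClasses; ns <- spec@samplesPerClass; nr <- spec@replicates
    d <- length(axis)
    .withSeed(spec@seed, {
        n <- nc * ns * nr
        X <- matrix(0, n, d)
        labels <- character(n)
        reps <- character(n)
        row <- 0L
        for (cl in seq_len(nc)) {
            classTemplate <- baseline + drop(peaks %*% A[cl, ])
            for (s in seq_len(ns)) {
                slope <- rnorm(1, 0, spec@scatterSlopeSd)
                offset <- rnorm(1, 0, spec@scatterOffsetSd)
                template <- classTemplate * (1 + slope) + offset
                gid <- sprintf("c%d_s%03d", cl, s)
                for (r in seq_len(nr)) {
                    row <- row + 1L
                    X[row, ] <- template + rnorm(d, 0, spec@noiseSd)
                    labels[row] <- sprintf("class%d", cl)
                    reps[row] <- gid
                }
            }
        }
        SpectralSet(X, axis, labels,
                    replicateIds = if (nr > 1L) reps else NULL)
    })
}

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(paste0("SyntheticSpec: %d classes x %d samples x %d ",
        "replicates, %d channels\n"),
        object@nClasses, object@samplesPerClass, object@replicates,
        length(object@axis)))
    cat(sprintf("  overlap %.2f (classes %s), noise sd %.4g, seed %d\n",
        object@overlap, paste(object@overlapClasses, collapse = ","),
        object@noiseSd, object@seed))
    invisible(NULL)
})
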
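# Pull a samples x channels matrix out of a SpectralSet (or pass a bare
# matrix through) and rebuild the same container around new intensities.
.asMatrix <- function(x) {
    if (is(x, "SpectralSet")) intensities(x) else as.matrix(x)
}

.rebuild <- function(x, mat) {
    if (!is(x, "SpectralSet")) return(mat)
    SpectralSet(mat, wavenumbers(x), spectraLabels(x),
                replicateIds = replicateIds(x))
}

#' Standard normal variate (SNV) transformation
#'
#' Centres every spectrum to mean 0 and scales it to unit sample standard
#' deviation (divisor n-1), removing per-spectrum multiplicative and
#' additive scatter. SNV is idempotent and needs no fitted statistics.
#'
#' @param x a \linkS4class{SpectralSet} or samples x channels matrix.
#' @return object of the same kind with transformed intensities.
#' @export
snv <- function(x) {
    X <- .asMatrix(x)
    s <- apply(X, 1, sd)
    if (any(s == 0))
        stop("degenerate input: constant spectrum in row(s) ",
             paste(which(s == 0), collapse = ", "))
    .rebuild(x, (X - rowMeans(X)) / s)
}

#' Fit a multiplicative scatter correction (MSC) reference
#'
#' The reference is the mean spectrum of the training set. Test spectra
#' must be corrected against the same training-derived reference.
#'
#' @param train a \linkS4class{SpectralSet} or matrix of training spectra.
#' @return numeric reference spectrum of length d.
#' @export
mscFit <- function(train) {
    X <- .asMatrix(train)
    if (!nrow(X)) stop("empty training set")
    ref <- colMeans(X)
    if (sd(ref) == 0) stop("degenerate input: constant reference spectrum")
    ref
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum x is regressed on the reference by ordinary least
#' squares, x ~ a + b * reference, and corrected to (x - a) / b, which
#' inverts any per-spectrum affine distortion of the reference exactly.
#'
#' @param x a \linkS4class{SpectralSet} or matrix.
#' @param reference spectrum from [mscFit()].
#' @param tol slopes with |b| below \code{tol} raise an error.
#' @return corrected object of the same kind.
#' @export
mscApply <- function(x, reference, tol = 1e-10) {
    X <- .asMatrix(x)
    if (ncol(X) != length(reference))
        stop("validation error: reference length does not match channels")
    rc <- reference - mean(reference)
    denom <- sum(rc^2)
    b <- drop(X %*% rc) / denom
    a <- rowMeans(X) - b * mean(reference)
    if (any(abs(b) < tol))
        stop("degenerate input: near-zero MSC slope in row(s) ",
             paste(which(abs(b) < tol), collapse = ", "))
    .rebuild(x, (X - a) / b)
}

#' Savitzky-Golay smoothing
#'
#' Replaces each channel by the centre value of a local least-squares
#' polynomial fit of order \code{polyorder} over a window of
#' \code{window} channels; the terminal half-windows use the polynomial
#' fitted within the first/last full window, so polynomials of degree at
#' most \code{polyorder} are reproduced exactly everywhere.
#'
#' @param x a \linkS4class{SpectralSet} or matrix.
#' @param window odd window length in channels (default 11).
#' @param polyorder polynomial order, less than \code{window} (default 2).
#' @return smoothed object of the same kind.
#' @export
sgSmooth <- function(x, window = 11L, polyorder = 2L) {
    X <- .asMatrix(x)
    window <- as.integer(window); polyorder <- as.integer(polyorder)
    if (window %% 2L != 1L) stop("validation error: window must be odd")
    if (polyorder >= window)
        stop("validation error: polyorder must be smaller than window")
    if (window > ncol(X))
        stop("validation error: window exceeds channel count")
    sm <- t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window))
    .rebuild(x, sm)
}

#' Fit mean centring (MC)
#'
#' @param train a \linkS4class{SpectralSet} or matrix of training spectra.
#' @return per-channel training means, length d.
#' @export
mcFit <- function(train) {
    X <- .asMatrix(train)
    if (!nrow(X)) stop("empty training set")
    colMeans(X)
}

#' Apply mean centring
#'
#' Subtracts the training-derived per-channel means from every spectrum.
#'
#' @param x a \linkS4class{SpectralSet} or matrix.
#' @param columnMeans vector from [mcFit()].
#' @return centred object of the same kind.
#' @export
mcApply <- function(x, columnMeans) {
    X <- .asMatrix(x)
    if (ncol(X) != length(columnMeans))
        stop("validation error: column-means length does not match channels")
    .rebuild(x, sweep(X, 2, columnMeans))
}

#' Fit a preprocessing chain on training spectra
#'
#' Builds a \linkS4class{PreprocessModel} for an ordered chain of steps
#' drawn from \code{"SG"}, \code{"SNV"}, \code{"MSC"}, \code{"MC"} (each
#' at most once). All train-derived statistics — the MSC reference and the
#' MC column means — are computed from the training set only, on the data
#' as transformed by the preceding steps of the chain, and are reused
#' verbatim when the chain is applied to test spectra.
#'
#' @param train a \linkS4class{SpectralSet} or matrix of training spectra.
#' @param steps character vector of step tags (case-insensitive).
#' @param sgWindow,sgPolyorder Savitzky-Golay settings (defaults 11 / 2).
#' @return a fitted \linkS4class{PreprocessModel}.
#' @examples
#' spec <- syntheticMilkSpec(seed = 7)
#' ds <- averageReplicates(simulateSpectra(spec))
#' model <- fitPreprocess(ds, c("SG", "SNV"))
#' applyPreprocess(model, ds)
#' @export
fitPreprocess <- function(train, steps, sgWindow = 11L, sgPolyorder = 2L) {
    steps <- toupper(steps)
    if (!length(steps)) stop("validation error: steps must be non-empty")
    known <- c("SG", "SNV", "MSC", "MC")
    if (!all(steps %in% known))
        stop("validation error: unknown step tag(s): ",
             paste(setdiff(steps, known), collapse = ", "))
    if (anyDuplicated(steps))
        stop("validation error: each step may appear at most once")
    cur <- .asMatrix(train)
    ref <- numeric(0); means <- numeric(0)
    for (s in steps) {
        cur <- switch(s,
            SG  = .asMatrix(sgSmooth(cur, sgWindow, sgPolyorder)),
            SNV = .asMatrix(snv(cur)),
            MSC = { ref <- mscFit(cur); .asMatrix(mscApply(cur, ref)) },
            MC  = { means <- mcFit(cur); .asMatrix(mcApply(cur, means)) })
    }
    new("PreprocessModel", steps = steps, sgWindow = as.integer(sgWindow),
        sgPolyorder = as.integer(sgPolyorder), mscReference = ref,
        mcMeans = means)
}

#' Apply a fitted preprocessing chain
#'
#' @param model a \linkS4class{PreprocessModel} from [fitPreprocess()].
#' @param x a \linkS4class{SpectralSet} or matrix.
#' @return transformed object of the same kind as \code{x}.
#' @export
applyPreprocess <- function(model, x) {
    stopifnot(is(model, "PreprocessModel"))
    validObject(model)
    out <- x
    for (s in model@steps) {
        out <- switch(s,
            SG  = sgSmooth(out, model@sgWindow, model@sgPolyorder),
            SNV = snv(out),
            MSC = mscApply(out, model@mscReference),
            MC  = mcApply(out, model@mcMeans))
    }
    out
}

setMethod("show", "PreprocessModel", function(object) {
    cat("PreprocessModel:", paste(object@steps, collapse = " + "))
    if ("SG" %in% object@steps)
        cat(sprintf(" (SG window %d, order %d)",
            object@sgWindow, object@sgPolyorder))
    cat("\n")
    invisible(NULL)
})
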
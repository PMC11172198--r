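#' Construct a SpectralSet
#'
#' Builds a \linkS4class{SpectralSet} from a samples x channels intensity
#' matrix. The wavenumber axis may be supplied in any strictly monotone
#' order; channels are stored ascending internally (the matrix columns are
#' reordered with the axis).
#'
#' @param intensities numeric matrix, one row per sample, one column per
#'   spectral channel.
#' @param wavenumbers numeric axis in reciprocal centimetres, strictly
#'   monotone, length equal to \code{ncol(intensities)}.
#' @param labels class label per sample (character or factor).
#' @param replicateIds optional replicate-group key per sample; replicate
#'   scans of one physical sample share a key and a label.
#' @return a validated \linkS4class{SpectralSet}.
#' @examples
#' ss <- SpectralSet(matrix(rnorm(20), 4, 5), seq(6000, 8000, length.out = 5),
#'                   labels = c("a", "a", "b", "b"))
#' dim(intensities(ss))
#' @export
SpectralSet <- function(intensities, wavenumbers, labels,
                        replicateIds = NULL) {
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    dimnames(intensities) <- NULL
    if (length(wavenumbers) != ncol(intensities))
        stop("wavenumber axis length (", length(wavenumbers),
             ") does not match channel count (", ncol(intensities), ")")
    if (!.monotone(wavenumbers))
        stop("wavenumber axis must be strictly monotone")
    if (length(labels) != nrow(intensities))
        stop("one label per sample required")
    ord <- order(wavenumbers)
    wavenumbers <- wavenumbers[ord]
    intensities <- intensities[, ord, drop = FALSE]
    cd <- S4Vectors::DataFrame(label = as.character(labels))
    if (!is.null(replicateIds)) {
        if (length(replicateIds) != nrow(intensities))
            stop("one replicate id per sample required")
        cd$replicate_id <- as.character(replicateIds)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = t(intensities)),
        rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
        colData = cd)
    new("SpectralSet", se)
}

#' @describeIn SpectralSet-class samples x channels intensity matrix
#'   (columns ordered by ascending wavenumber).
#' @param x,object a \code{SpectralSet}.
#' @export
intensities <- function(x) t(SummarizedExperiment::assay(x, "intensity"))

#' @describeIn SpectralSet-class ascending wavenumber axis (cm^-1).
#' @export
wavenumbers <- function(x) SummarizedExperiment::rowData(x)$wavenumber

#' @describeIn SpectralSet-class per-sample class labels (character).
#' @export
spectraLabels <- function(x) SummarizedExperiment::colData(x)$label

#' @describeIn SpectralSet-class per-sample replicate-group ids, or NULL.
#' @export
replicateIds <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("replicate_id" %in% colnames(cd)) cd$replicate_id else NULL
}

setMethod("show", "SpectralSet", function(object) {
    lab <- spectraLabels(object)
    wn <- wavenumbers(object)
    cat(sprintf("SpectralSet: %d spectra x %d channels (%.0f-%.0f cm-1)\n",
        ncol(object), nrow(object), min(wn), max(wn)))
    tab <- table(lab)
    cat(sprintf("  %d classes: %s\n", length(tab),
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
    if (!is.null(replicateIds(object)))
        cat(sprintf("  replicate groups: %d\n",
            length(unique(replicateIds(object)))))
    invisible(NULL)
})

#' Read a labelled spectral matrix from CSV
#'
#' Expects one row per sample: the first column holds the class label and
#' the header row carries the wavenumber of each remaining column. The
#' axis may be written in either monotone direction; channels are stored
#' ascending. An optional \code{replicate_id} second column (written by
#' [writeSpectra()] when replicate ids are present) is recognised.
#'
#' @param path CSV file path.
#' @return a \linkS4class{SpectralSet}.
#' @seealso [writeSpectra()] for the inverse; the pair round-trips
#'   losslessly.
#' @export
readSpectra <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    nf <- unique(utils::count.fields(path, sep = ","))
    if (length(nf) != 1)
        stop("format error: ragged rows (", paste(nf, collapse = "/"),
             " fields)")
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("format error: no spectral columns found")
    if (colnames(df)[1] != "label")
        stop("format error: first column must be 'label'")
    reps <- NULL
    first <- 2L
    if (ncol(df) >= 2 && colnames(df)[2] == "replicate_id") {
        reps <- as.character(df[[2]])
        first <- 3L
    }
    wn <- suppressWarnings(as.numeric(colnames(df)[first:ncol(df)]))
    if (anyNA(wn))
        stop("format error: header must carry numeric wavenumbers")
    mat <- as.matrix(df[, first:ncol(df), drop = FALSE])
    if (!is.numeric(mat) || anyNA(mat))
        stop("format error: non-numeric intensity value")
    if (!.monotone(wn))
        stop("validation error: wavenumber axis must be strictly monotone")
    SpectralSet(mat, wn, labels = as.character(df[[1]]), replicateIds = reps)
}

#' Write a SpectralSet to CSV
#'
#' Writes one row per sample with the label first (and the replicate id,
#' when present), under a header of wavenumbers in descending order — the
#' conventional plotting direction for NIR spectra. Values are written at
#' full double precision so that [readSpectra()] reproduces the object
#' exactly.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(x, path) {
    stopifnot(is(x, "SpectralSet"))
    wn <- wavenumbers(x)
    ord <- order(wn, decreasing = TRUE)
    mat <- intensities(x)[, ord, drop = FALSE]
    df <- data.frame(label = spectraLabels(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!is.null(replicateIds(x))) df$replicate_id <- replicateIds(x)
    num <- as.data.frame(mat)
    colnames(num) <- format(wn[ord], trim = TRUE, scientific = FALSE,
                            digits = 17)
    df <- cbind(df, num)
    write.csv(format(df, trim = TRUE, digits = 17, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Average replicate scans
#'
#' Collapses replicate scans of each physical sample to their arithmetic
#' mean spectrum, producing one spectrum per replicate group. Groups keep
#' their first-occurrence order and their (shared) label; the replicate id
#' column is dropped from the result.
#'
#' @param x a \linkS4class{SpectralSet} with replicate ids.
#' @return a \linkS4class{SpectralSet} with one spectrum per group.
#' @export
averageReplicates <- function(x) {
    stopifnot(is(x, "SpectralSet"))
    reps <- replicateIds(x)
    if (is.null(reps)) stop("no replicate ids present")
    lab <- spectraLabels(x)
    groups <- unique(reps)
    conflicting <- vapply(groups, function(g)
        length(unique(lab[reps == g])) > 1L, logical(1))
    if (any(conflicting))
        stop("validation error: replicate group(s) with conflicting labels: ",
             paste(groups[conflicting], collapse = ", "))
    X <- intensities(x)
    avg <- t(vapply(groups, function(g)
        colMeans(X[reps == g, , drop = FALSE]), numeric(ncol(X))))
    SpectralSet(avg, wavenumbers(x),
                labels = lab[match(groups, reps)])
}

#' Stratified train/test split
#'
#' Randomly partitions the samples of each class into a training and a
#' test share. The per-class test count is \code{round(n_class *
#' testFraction)}, clamped so every class keeps at least one sample on
#' each side; the remainder goes to training. With 60 samples per class at
#' a fraction of 1/4 this yields the conventional 45/15 split. The
#' partition is deterministic for a fixed seed.
#'
#' @param x a \linkS4class{SpectralSet}.
#' @param testFraction proportion of each class held out, in (0, 1).
#' @param seed integer seed driving the within-class shuffling.
#' @return a list with elements \code{train} and \code{test}, both
#'   \linkS4class{SpectralSet}s; together they partition \code{x}.
#' @export
stratifiedSplit <- function(x, testFraction = 0.25, seed = 1L) {
    stopifnot(is(x, "SpectralSet"))
    if (testFraction <= 0 || testFraction >= 1)
        stop("testFraction must lie in (0, 1)")
    lab <- spectraLabels(x)
    counts <- table(lab)
    if (any(counts < 2))
        stop("validation error: every class needs at least 2 samples; ",
             "offending: ", paste(names(counts)[counts < 2], collapse = ", "))
    rng <- .withSeed(as.integer(seed), {
        testIdx <- integer(0)
        for (cl in names(counts)) {
            idx <- which(lab == cl)
            nTest <- round(length(idx) * testFraction)
            nTest <- max(1L, min(length(idx) - 1L, as.integer(nTest)))
            testIdx <- c(testIdx, sample(idx, nTest))
        }
        sort(testIdx)
    })
    testIdx <- rng
    trainIdx <- setdiff(seq_along(lab), testIdx)
    list(train = x[, trainIdx], test = x[, testIdx])
}

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}
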
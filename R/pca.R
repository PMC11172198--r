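#' Fit PCA on training spectra
#'
#' Computes the top \code{npc} eigenpairs of the training covariance
#' (divisor n-1), centred at the training mean. Loadings are stored as
#' orthonormal rows with a deterministic sign convention: the
#' largest-magnitude element of every loading is positive, so downstream
#' transformation matrices are reproducible.
#'
#' @param train a \linkS4class{SpectralSet} or samples x channels matrix.
#' @param npc number of components to retain, in [1, min(n-1, d)].
#' @return a \linkS4class{PCAModel}.
#' @examples
#' ds <- averageReplicates(simulateSpectra(syntheticMilkSpec(seed = 3)))
#' model <- fitPCA(ds, npc = 5)
#' cumulativeVariance(model)
#' @export
fitPCA <- function(train, npc = 5L) {
    X <- .asMatrix(train)
    npc <- as.integer(npc)
    maxNpc <- min(nrow(X) - 1L, ncol(X))
    if (npc < 1L || npc > maxNpc)
        stop("validation error: npc must lie in [1, ", maxNpc, "]")
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    # eigen on whichever Gram matrix is smaller; d x d covariance when
    # d <= n, else the n x n inner-product trick
    if (ncol(Xc) <= nrow(Xc)) {
        ev <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
        vals <- pmax(ev$values, 0)
        vecs <- ev$vectors
    } else {
        ev <- eigen(tcrossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
        vals <- pmax(ev$values, 0)
        vecs <- crossprod(Xc, ev$vectors)
        nrm <- sqrt(colSums(vecs^2))
        nrm[nrm == 0] <- 1
        vecs <- sweep(vecs, 2, nrm, "/")
    }
    total <- sum(vals)
    L <- t(vecs[, seq_len(npc), drop = FALSE])
    for (i in seq_len(npc)) {
        j <- which.max(abs(L[i, ]))
        if (L[i, j] < 0) L[i, ] <- -L[i, ]
    }
    new("PCAModel", center = ctr, loadings = L,
        eigenvalues = vals[seq_len(npc)],
        explainedRatio = if (total > 0) vals[seq_len(npc)] / total
                         else rep(0, npc),
        npc = npc)
}

#' Project spectra onto fitted principal components
#'
#' Scores are the mean-centred intensities projected on the loadings.
#' Labels travel with the scores: for a \linkS4class{SpectralSet} input
#' the result is a list with the n x npc \code{scores} matrix and the
#' \code{labels}; a bare matrix returns the scores matrix.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param x a \linkS4class{SpectralSet} or samples x channels matrix.
#' @return scores (and labels, see above).
#' @export
pcaTransform <- function(model, x) {
    stopifnot(is(model, "PCAModel"))
    X <- .asMatrix(x)
    if (ncol(X) != length(model@center))
        stop("validation error: channel count does not match the model")
    scores <- sweep(X, 2, model@center) %*% t(model@loadings)
    colnames(scores) <- paste0("PC", seq_len(model@npc))
    if (is(x, "SpectralSet"))
        list(scores = scores, labels = spectraLabels(x))
    else scores
}

#' Cumulative explained-variance proportions
#'
#' @param model a \linkS4class{PCAModel}.
#' @return non-decreasing vector of length npc, last element at most 1.
#' @export
cumulativeVariance <- function(model) {
    stopifnot(is(model, "PCAModel"))
    cumsum(model@explainedRatio)
}

setMethod("show", "PCAModel", function(object) {
    cat(sprintf("PCAModel: %d components over %d channels\n",
        object@npc, length(object@center)))
    cat(sprintf("  cumulative explained variance: %.4f\n",
        sum(object@explainedRatio)))
    invisible(NULL)
})
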
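# Small in-code fixtures shared across the suite.

# A tiny labelled dataset: nPerClass samples per class, Gaussian blobs in
# d dimensions with unit-spaced means along the first axis.
makeBlobs <- function(nClasses = 3, nPerClass = 10, d = 4, sd = 0.3,
                      seed = 1) {
    set.seed(seed)
    X <- do.call(rbind, lapply(seq_len(nClasses), function(cl) {
        mu <- c(3 * cl, rep(0, d - 1))
        matrix(rnorm(nPerClass * d, 0, sd), nPerClass, d) +
            matrix(mu, nPerClass, d, byrow = TRUE)
    }))
    list(X = X, labels = rep(paste0("g", seq_len(nClasses)),
                             each = nPerClass))
}

# A small SpectralSet with decimal-friendly values for round-trip tests.
makeTinySpectra <- function(n = 10, d = 228, seed = 1) {
    set.seed(seed)
    X <- matrix(round(rnorm(n * d), 4), n, d)
    SpectralSet(X, seq(5882, 11111, length.out = d),
                labels = rep(c("a", "b"), length.out = n))
}

# Brute-force fuzzy-c-means membership evaluation, kept deliberately
# naive and independent of the package implementation.
bruteMembership <- function(X, V, m) {
    n <- nrow(X); cc <- nrow(V)
    U <- matrix(0, n, cc)
    for (i in seq_len(n)) {
        dists <- numeric(cc)
        for (j in seq_len(cc))
            dists[j] <- sqrt(sum((X[i, ] - V[j, ])^2))
        if (any(dists == 0)) {
            U[i, dists == 0] <- 1 / sum(dists == 0)
        } else {
            for (j in seq_len(cc)) {
                acc <- 0
                for (k in seq_len(cc))
                    acc <- acc + (dists[j] / dists[k])^(2 / (m - 1))
                U[i, j] <- 1 / acc
            }
        }
    }
    U
}

# Double-loop evaluation of the fuzzy scatter definitions.
bruteFuzzyScatter <- function(X, labels, U, m) {
    f <- factor(labels)
    p <- ncol(X)
    grand <- colMeans(X)
    Sfw <- matrix(0, p, p); Sfb <- matrix(0, p, p)
    for (j in seq_len(nlevels(f))) {
        vj <- colMeans(X[f == levels(f)[j], , drop = FALSE])
        for (i in seq_len(nrow(X))) {
            w <- U[i, j]^m
            dwv <- X[i, ] - vj
            Sfw <- Sfw + w * outer(dwv, dwv)
            dbv <- vj - grand
            Sfb <- Sfb + w * outer(dbv, dbv)
        }
    }
    list(within = Sfw, between = Sfb)
}

# Exhaustive-distance KNN voter with the package's tie-break rules.
bruteKnn <- function(trainX, trainLab, queryX, K) {
    f <- factor(trainLab)
    lev <- levels(f)
    out <- character(nrow(queryX))
    for (q in seq_len(nrow(queryX))) {
        d <- sqrt(rowSums(sweep(trainX, 2, queryX[q, ])^2))
        nb <- order(d)[seq_len(K)]
        tab <- table(factor(f[nb], levels = lev))
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1) {
            sums <- sapply(top, function(cl)
                sum(d[nb][as.character(f[nb]) == cl]))
            top <- top[sums == min(sums)]
        }
        out[q] <- top[1]
    }
    factor(out, levels = lev)
}
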
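test_that("crisp scatters match hand-computed values in 1-D", {
    X <- matrix(c(0, 2, 4, 6), 4, 1)
    sc <- crispScatter(X, c("a", "a", "b", "b"))
    # class means 1 and 5, grand mean 3:
    # Sw = 1+1+1+1 = 4; Sb = 2*(1-3)^2 + 2*(5-3)^2 = 16
    expect_equal(sc$within, matrix(4), tolerance = 1e-12)
    expect_equal(sc$between, matrix(16), tolerance = 1e-12)
})

test_that("scatter identities hold on random data", {
    blobs <- makeBlobs(nClasses = 4, nPerClass = 8, d = 5, seed = 3)
    sc <- crispScatter(blobs$X, blobs$labels)
    total <- crossprod(sweep(blobs$X, 2, colMeans(blobs$X)))
    expect_equal(sc$within + sc$between, total, tolerance = 1e-8)
    expect_equal(sc$within, t(sc$within), tolerance = 1e-10)
    expect_true(all(eigen(sc$within, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-8))
    # classes with identical means: between-scatter vanishes
    dup <- crispScatter(rbind(blobs$X, blobs$X),
                        rep(c("a", "b"), each = nrow(blobs$X)))
    expect_lt(max(abs(dup$between)), 1e-10)
    expect_error(crispScatter(blobs$X[1:8, ], rep("a", 8)),
                 "at least 2 classes")
})

test_that("class means are per-class averages in level order", {
    X <- rbind(c(0, 0), c(2, 4), c(10, 10), c(1, 3))
    V <- classMeans(X, c("b", "b", "a", "a"))
    expect_equal(V["a", ], c(5.5, 6.5), ignore_attr = TRUE)
    expect_equal(V["b", ], c(1, 2), ignore_attr = TRUE)
    # a singleton class is its own mean
    V2 <- classMeans(X, c("a", "b", "c", "d"))
    expect_equal(V2["c", ], c(10, 10), ignore_attr = TRUE)
})

test_that("fuzzy memberships follow the single-pass FCM formula", {
    # 1-D, centres 0 and 1, x = 0.25, m = 2: distances 0.25 / 0.75
    # -> u1 = 1/(1 + (1/3)^2)... = 0.9, u2 = 0.1
    U <- fuzzyMembership(matrix(0.25), matrix(c(0, 1), 2, 1), m = 2)@U
    expect_equal(drop(U), c(0.9, 0.1), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # coinciding with a centre gives an indicator row
    V5 <- matrix(rnorm(10), 5, 2)
    Ui <- fuzzyMembership(V5[3, , drop = FALSE], V5, m = 3.5)@U
    expect_equal(drop(Ui), c(0, 0, 1, 0, 0), ignore_attr = TRUE)
    # equidistant from all centres gives the uniform row
    Vsq <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
    Ue <- fuzzyMembership(matrix(c(0, 0), 1), Vsq, m = 3)@U
    expect_equal(drop(Ue), rep(0.25, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_error(fuzzyMembership(matrix(0.25), matrix(0), m = 1),
                 "m must exceed 1")
})

test_that("memberships match the brute-force oracle on random points", {
    set.seed(9)
    X <- matrix(rnorm(100 * 3), 100, 3)
    V <- matrix(rnorm(15), 5, 3)
    for (m in c(1.5, 2, 3.5)) {
        U <- fuzzyMembership(X, V, m)@U
        expect_lt(max(abs(U - bruteMembership(X, V, m))), 1e-12)
        expect_lt(max(abs(rowSums(U) - 1)), 1e-10)
    }
})

test_that("memberships are scale-invariant and flatten as m grows", {
    set.seed(10)
    X <- matrix(rnorm(60), 20, 3)
    V <- matrix(rnorm(9), 3, 3)
    expect_equal(fuzzyMembership(7 * X, 7 * V, 2.5)@U,
                 fuzzyMembership(X, V, 2.5)@U, tolerance = 1e-12)
    maxes <- sapply(c(1.5, 2, 3, 4, 6), function(m)
        mean(apply(fuzzyMembership(X, V, m)@U, 1, max)))
    expect_true(all(diff(maxes) <= 1e-12))
})

test_that("fuzzy scatters reduce to crisp scatters under one-hot U", {
    blobs <- makeBlobs(nClasses = 3, nPerClass = 7, d = 4, seed = 5)
    f <- factor(blobs$labels)
    onehot <- diag(nlevels(f))[as.integer(f), ]
    fs <- fuzzyScatter(blobs$X, blobs$labels, onehot, m = 3.5)
    cs <- crispScatter(blobs$X, blobs$labels)
    expect_equal(fs$within, cs$within, tolerance = 1e-10)
    expect_equal(fs$between, cs$between, tolerance = 1e-10)
})

test_that("fuzzy scatters match the double-loop oracle", {
    blobs <- makeBlobs(nClasses = 3, nPerClass = 6, d = 3, seed = 6)
    V <- classMeans(blobs$X, blobs$labels)
    mm <- fuzzyMembership(blobs$X, V, 2.5)
    fs <- fuzzyScatter(blobs$X, blobs$labels, mm)
    oracle <- bruteFuzzyScatter(blobs$X, blobs$labels, mm@U, 2.5)
    expect_equal(fs$within, oracle$within, tolerance = 1e-10)
    expect_equal(fs$between, oracle$between, tolerance = 1e-10)
    # uniform memberships: Sfb = (1/c)^m * n * sum_j outer(vj - grand)
    n <- nrow(blobs$X)
    Uu <- matrix(1 / 3, n, 3)
    fsu <- fuzzyScatter(blobs$X, blobs$labels, Uu, m = 2)
    grand <- colMeans(blobs$X)
    Sfb <- matrix(0, 3, 3)
    for (j in 1:3) Sfb <- Sfb + (1 / 3)^2 * n *
        tcrossprod(V[j, ] - grand)
    expect_equal(fsu$between, Sfb, tolerance = 1e-10)
})

test_that("raising m shrinks the fuzzy within-scatter norm", {
    blobs <- makeBlobs(nClasses = 3, nPerClass = 6, d = 3, seed = 7)
    V <- classMeans(blobs$X, blobs$labels)
    mm <- fuzzyMembership(blobs$X, V, 2)
    n1 <- norm(fuzzyScatter(blobs$X, blobs$labels, mm, m = 2)$within, "F")
    n2 <- norm(fuzzyScatter(blobs$X, blobs$labels, mm, m = 4)$within, "F")
    expect_lte(n2, n1)
})

test_that("two-class LDA recovers the closed-form direction", {
    blobs <- makeBlobs(nClasses = 2, nPerClass = 15, d = 4, seed = 8)
    model <- fitLDA(blobs$X, blobs$labels)
    expect_identical(nrow(model@W), 1L)
    V <- classMeans(blobs$X, blobs$labels)
    sc <- crispScatter(blobs$X, blobs$labels)
    wClosed <- solve(sc$within, V[1, ] - V[2, ])      # Sw^-1 (m1 - m2)
    cosang <- sum(model@W[1, ] * wClosed) /
        sqrt(sum(model@W[1, ]^2) * sum(wClosed^2))
    expect_equal(abs(cosang), 1, tolerance = 1e-8)
})

test_that("identical class means give zero generalized eigenvalues", {
    set.seed(11)
    X <- matrix(rnorm(40), 20, 2)
    X2 <- rbind(X, X)           # same points relabelled: equal class means
    model <- fitLDA(X2, rep(c("a", "b"), each = 20))
    expect_lt(max(abs(model@diagWithin)), 1e-10)
})

test_that("DLDA simultaneously diagonalizes the scatter pair", {
    for (seed in 1:5) {
        blobs <- makeBlobs(nClasses = 5, nPerClass = 12, d = 5,
                           seed = seed)
        model <- fitDLDA(blobs$X, blobs$labels)
        expect_identical(nrow(model@W), 4L)
        WSwW <- model@W %*% model@Sw %*% t(model@W)
        expect_lt(max(abs(WSwW - diag(4))), 1e-6)
        WSbW <- model@W %*% model@Sb %*% t(model@W)
        expect_lt(max(abs(WSbW - diag(diag(WSbW)))), 1e-6)
        # rows ordered by increasing within-class eigenvalue
        expect_true(!is.unsorted(model@diagWithin))
    }
})

test_that("DLDA separates a 2-class toy beyond its within-class spread", {
    blobs <- makeBlobs(nClasses = 2, nPerClass = 20, d = 2, sd = 0.2,
                       seed = 12)
    model <- fitDLDA(blobs$X, blobs$labels)
    proj <- discriminantTransform(model, blobs$X)
    mA <- mean(proj[blobs$labels == "g1", 1])
    mB <- mean(proj[blobs$labels == "g2", 1])
    pooled <- sd(c(proj[blobs$labels == "g1", 1] - mA,
                   proj[blobs$labels == "g2", 1] - mB))
    expect_gt(abs(mA - mB), pooled)
    # cross-check the projected separation against a generalized
    # eigendecomposition oracle: lambda_max of Sw^-1 Sb
    sc <- crispScatter(blobs$X, blobs$labels)
    lmax <- max(Re(eigen(solve(sc$within, sc$between))$values))
    # in DLDA coordinates the per-direction separation diag(W Sb W') is
    # bounded by lambda_max (DLDA restricts to the whitened range of Sb,
    # so it approaches but cannot exceed the unrestricted optimum)
    ratio <- diag(model@W %*% sc$between %*% t(model@W))
    expect_lte(max(ratio), lmax * (1 + 1e-8))
    expect_gt(max(ratio), 0.95 * lmax)
})

test_that("FDLDA equals DLDA under crisp memberships", {
    blobs <- makeBlobs(nClasses = 4, nPerClass = 10, d = 4, seed = 13)
    f <- factor(blobs$labels)
    onehot <- diag(nlevels(f))[as.integer(f), ]
    mm <- new("MembershipMatrix", U = onehot,
              centers = classMeans(blobs$X, f), m = 3.5)
    fd <- fitFDLDA(blobs$X, blobs$labels, m = 3.5, membership = mm)
    dl <- fitDLDA(blobs$X, blobs$labels)
    expect_equal(fd@Sw, dl@Sw, tolerance = 1e-10)
    expect_equal(fd@Sb, dl@Sb, tolerance = 1e-10)
    for (i in seq_len(nrow(fd@W))) {
        s <- sign(sum(fd@W[i, ] * dl@W[i, ]))
        expect_equal(fd@W[i, ], s * dl@W[i, ], tolerance = 1e-8)
    }
})

test_that("FDLDA on the synthetic dataset reports m and a 4-row W", {
    ds <- averageReplicates(simulateSpectra(syntheticMilkSpec(seed = 14)))
    pr <- applyPreprocess(fitPreprocess(ds, c("SG", "SNV")), ds)
    sc <- pcaTransform(fitPCA(pr, 5), pr)
    model <- fitFDLDA(sc$scores, sc$labels, m = 3.5)
    expect_identical(nrow(model@W), 4L)
    expect_identical(model@m, 3.5)
    expect_identical(model@algorithm, "FDLDA")
    # simultaneous diagonalization holds for the fuzzy pair too
    expect_lt(max(abs(model@W %*% model@Sw %*% t(model@W) - diag(4))),
              1e-6)
})

test_that("mean max-membership is non-increasing in m on fixed data", {
    ds <- averageReplicates(simulateSpectra(syntheticMilkSpec(seed = 15)))
    pr <- applyPreprocess(fitPreprocess(ds, c("SG", "SNV")), ds)
    sc <- pcaTransform(fitPCA(pr, 5), pr)
    V <- classMeans(sc$scores, sc$labels)
    maxes <- sapply(c(1.5, 2, 3, 4, 6), function(m)
        mean(apply(fuzzyMembership(sc$scores, V, m)@U, 1, max)))
    expect_true(all(diff(maxes) <= 1e-12))
})

test_that("scaling all inputs rescales W without changing separability", {
    blobs <- makeBlobs(nClasses = 3, nPerClass = 10, d = 4, seed = 16)
    m1 <- fitFDLDA(blobs$X, blobs$labels, m = 2.5)
    m2 <- fitFDLDA(5 * blobs$X, blobs$labels, m = 2.5)
    p1 <- discriminantTransform(m1, blobs$X)
    p2 <- discriminantTransform(m2, 5 * blobs$X)
    sep <- function(P, lab) {
        sc <- crispScatter(P, lab)
        sum(diag(sc$between)) / sum(diag(sc$within))
    }
    expect_equal(sep(p1, blobs$labels), sep(p2, blobs$labels),
                 tolerance = 1e-8)
})

test_that("projection validates dimensions and maps zero to zero", {
    blobs <- makeBlobs(nClasses = 3, nPerClass = 8, d = 4, seed = 17)
    model <- fitDLDA(blobs$X, blobs$labels)
    expect_equal(discriminantTransform(model, matrix(0, 2, 4)),
                 matrix(0, 2, 2), ignore_attr = TRUE)
    expect_error(discriminantTransform(model, matrix(0, 2, 3)),
                 "dimension")
})
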
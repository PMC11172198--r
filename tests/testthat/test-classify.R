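test_that("KNN basics: exact match, majority vote, self-accuracy", {
    X <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5), c(5, 5.1))
    lab <- c("A", "A", "B", "B", "B")
    m1 <- knnFit(X, lab, K = 1)
    expect_identical(as.character(knnPredict(m1, X[3, , drop = FALSE])),
                     "B")
    # K = 3 with neighbours (A, A, B) votes A
    m3 <- knnFit(X, lab, K = 3)
    expect_identical(as.character(knnPredict(m3,
        matrix(c(0.05, 0), 1))), "A")
    # K = 1 on its own training set is always perfect
    expect_equal(accuracy(knnPredict(m1, X), lab), 1)
    expect_error(knnFit(X, lab, K = 4), "odd")
    expect_error(knnFit(X, lab, K = 7), "exceeds")
})

test_that("KNN matches the exhaustive brute-force voter", {
    set.seed(20)
    blobs <- makeBlobs(nClasses = 4, nPerClass = 15, d = 3, sd = 1.5,
                       seed = 20)
    Q <- matrix(rnorm(200 * 3, mean = 6, sd = 3), 200, 3)
    for (K in c(1, 3, 7)) {
        model <- knnFit(blobs$X, blobs$labels, K)
        expect_identical(knnPredict(model, Q),
                         bruteKnn(blobs$X, blobs$labels, Q, K))
    }
})

test_that("KNN is invariant under a rigid rotation of both sets", {
    set.seed(21)
    blobs <- makeBlobs(nClasses = 3, nPerClass = 10, d = 3, seed = 21)
    Q <- matrix(rnorm(60), 20, 3)
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))             # orthonormal
    m0 <- knnFit(blobs$X, blobs$labels, 5)
    mR <- knnFit(blobs$X %*% R, blobs$labels, 5)
    expect_identical(knnPredict(m0, Q), knnPredict(mR, Q %*% R))
})

test_that("ELM is deterministic in its seed and interpolates with
           enough neurons", {
    blobs <- makeBlobs(nClasses = 3, nPerClass = 8, d = 4, seed = 22)
    m1 <- elmTrain(blobs$X, blobs$labels, hidden = 12, seed = 5)
    m2 <- elmTrain(blobs$X, blobs$labels, hidden = 12, seed = 5)
    expect_identical(m1@inputWeights, m2@inputWeights)
    expect_identical(m1@outputWeights, m2@outputWeights)
    expect_identical(elmPredict(m1, blobs$X), elmPredict(m2, blobs$X))
    # hidden = n_train on distinct inputs: random-feature least squares
    # interpolates the one-hot targets
    mBig <- elmTrain(blobs$X, blobs$labels, hidden = nrow(blobs$X),
                     seed = 3)
    expect_equal(accuracy(elmPredict(mBig, blobs$X), blobs$labels), 1)
})

test_that("ELM training error is non-increasing in hidden count
           (median over seeds)", {
    blobs <- makeBlobs(nClasses = 3, nPerClass = 10, d = 3, sd = 1.2,
                       seed = 23)
    trainErr <- function(hidden) median(vapply(1:20, function(s) {
        m <- elmTrain(blobs$X, blobs$labels, hidden = hidden, seed = s)
        1 - accuracy(elmPredict(m, blobs$X), blobs$labels)
    }, numeric(1)))
    expect_lte(trainErr(15), trainErr(3))
})

test_that("repeated ELM evaluation averages over the seed schedule", {
    blobs <- makeBlobs(nClasses = 2, nPerClass = 20, d = 3, seed = 24)
    test <- makeBlobs(nClasses = 2, nPerClass = 10, d = 3, seed = 25)
    one <- elmRepeatEval(blobs$X, blobs$labels, test$X, test$labels,
                         hidden = 8, runs = 1)
    m <- elmTrain(blobs$X, blobs$labels, hidden = 8, seed = 1)
    expect_equal(one, accuracy(elmPredict(m, test$X), test$labels))
    # the mean over runs lies between the min and max single runs
    singles <- vapply(1:10, function(s) {
        ms <- elmTrain(blobs$X, blobs$labels, hidden = 8, seed = s)
        accuracy(elmPredict(ms, test$X), test$labels)
    }, numeric(1))
    avg <- elmRepeatEval(blobs$X, blobs$labels, test$X, test$labels,
                         hidden = 8, runs = 10)
    expect_equal(avg, mean(singles), tolerance = 1e-12)
    expect_gte(avg, min(singles)); expect_lte(avg, max(singles))
    # well-separated 2-class toy stays accurate on average over 50 runs
    avg50 <- elmRepeatEval(blobs$X, blobs$labels, test$X, test$labels,
                           hidden = 10, runs = 50)
    expect_gte(avg50, 0.95)
})

test_that("naive Bayes places the equal-variance boundary midway", {
    set.seed(26)
    X <- matrix(c(rnorm(50, 0, 1), rnorm(50, 2, 1)), ncol = 1)
    lab <- rep(c("lo", "hi"), each = 50)
    model <- nbFit(X, lab)
    # symmetrize the fitted model so the boundary is exactly analytic
    model@means <- matrix(c(2, 0), 2, 1)   # levels: hi, lo
    model@variances <- matrix(1, 2, 1)
    model@priors <- c(0.5, 0.5)
    expect_identical(as.character(nbPredict(model, matrix(0.99))), "lo")
    expect_identical(as.character(nbPredict(model, matrix(1.01))), "hi")
})

test_that("naive Bayes posteriors are proper and match the closed-form
           log-odds with unequal priors", {
    set.seed(27)
    blobs <- makeBlobs(nClasses = 3, nPerClass = 12, d = 3, seed = 27)
    model <- nbFit(blobs$X, blobs$labels)
    Q <- matrix(rnorm(60, 3), 20, 3)
    post <- nbPredict(model, Q, posterior = TRUE)$posterior
    expect_lt(max(abs(rowSums(post) - 1)), 1e-10)
    expect_true(all(post >= 0))
    # 1-D two-class oracle: boundary x* solves the log-odds equation;
    # with equal unit variances x* = (mu1+mu2)/2 + log(p2/p1)/(mu1-mu2)
    m <- new("NBModel", means = matrix(c(0, 2), 2, 1),
             variances = matrix(1, 2, 1), priors = c(0.8, 0.2),
             varianceFloor = 1e-12, classLevels = c("a", "b"))
    xstar <- 1 + log(0.2 / 0.8) / (0 - 2)
    eps <- 1e-6
    expect_identical(as.character(nbPredict(m, matrix(xstar - eps))), "a")
    expect_identical(as.character(nbPredict(m, matrix(xstar + eps))), "b")
})

test_that("raising a class prior never shrinks its predicted count", {
    set.seed(28)
    blobs <- makeBlobs(nClasses = 2, nPerClass = 15, d = 2, sd = 2,
                       seed = 28)
    model <- nbFit(blobs$X, blobs$labels)
    Q <- matrix(rnorm(100, 4, 3), 50, 2)
    countG1 <- function(p1) {
        m <- model; m@priors <- c(p1, 1 - p1)
        sum(nbPredict(m, Q) == "g1")
    }
    counts <- vapply(c(0.2, 0.5, 0.8), countG1, numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("naive Bayes agrees with an independent implementation", {
    skip_if_not_installed("e1071")
    blobs <- makeBlobs(nClasses = 3, nPerClass = 10, d = 4, seed = 29)
    model <- nbFit(blobs$X, blobs$labels)
    # queries jittered around the training points: e1071 works in raw
    # density space and underflows far from the data
    set.seed(30)
    Q <- blobs$X + matrix(rnorm(length(blobs$X), 0, 0.5), nrow(blobs$X))
    ref <- e1071::naiveBayes(data.frame(blobs$X),
                             factor(blobs$labels))
    expect_identical(as.character(nbPredict(model, Q)),
                     as.character(predict(ref, data.frame(Q),
                                          threshold = 0, eps = 0)))
})

test_that("classes need two members for variance estimation", {
    X <- matrix(rnorm(12), 6, 2)
    expect_error(nbFit(X, c("a", "a", "a", "a", "a", "b")),
                 "fewer than 2")
})

test_that("accuracy is the correct proportion", {
    expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
    expect_equal(accuracy(c("a", "b"), c("b", "a")), 0)
    expect_equal(round(100 * accuracy(c(rep("x", 73), rep("y", 2)),
                                      rep("x", 75)), 2), 97.33)
    expect_error(accuracy("a", c("a", "b")), "length")
})
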
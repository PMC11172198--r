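#' Fit a k-nearest-neighbour classifier
#'
#' Stores the training scores and labels. K must be odd (even vote counts
#' invite exact ties) and at most n.
#'
#' @param trainScores n x p feature matrix.
#' @param trainLabels class label per row.
#' @param K odd neighbour count (default 7).
#' @return a \linkS4class{KNNModel}.
#' @export
knnFit <- function(trainScores, trainLabels, K = 7L) {
    K <- as.integer(K)
    trainScores <- as.matrix(trainScores)
    if (K > nrow(trainScores))
        stop("validation error: K exceeds the training-set size")
    new("KNNModel", K = K, trainScores = trainScores,
        trainLabels = factor(trainLabels))
}

#' Predict with a k-nearest-neighbour classifier
#'
#' Majority vote among the K Euclidean-nearest training points. Ties are
#' broken by the smallest summed neighbour distance among the tied
#' classes, then by the lowest class index (factor-level order).
#'
#' @param model a \linkS4class{KNNModel}.
#' @param scores query feature matrix, p columns.
#' @return factor of predicted labels.
#' @export
knnPredict <- function(model, scores) {
    stopifnot(is(model, "KNNModel"))
    scores <- as.matrix(scores)
    if (ncol(scores) != ncol(model@trainScores))
        stop("validation error: feature dimension mismatch")
    tr <- model@trainScores
    lev <- levels(model@trainLabels)
    labInt <- as.integer(model@trainLabels)
    out <- integer(nrow(scores))
    for (q in seq_len(nrow(scores))) {
        d2 <- rowSums(sweep(tr, 2, scores[q, ])^2)
        nb <- order(d2)[seq_len(model@K)]
        votes <- tabulate(labInt[nb], nbins = length(lev))
        top <- which(votes == max(votes))
        if (length(top) > 1L) {
            sums <- vapply(top, function(cl)
                sum(sqrt(d2[nb][labInt[nb] == cl])), numeric(1))
            top <- top[sums == min(sums)]
        }
        out[q] <- min(top)
    }
    factor(lev[out], levels = lev)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train an extreme learning machine
#'
#' A single-hidden-layer network whose input weights and biases are drawn
#' uniformly from [-1, 1] under the given seed and then frozen; the
#' hidden activations H = sigmoid(X W' + b) determine the output weights
#' as the minimum-norm least-squares solution beta = H^+ T against
#' one-hot class targets (Moore-Penrose pseudoinverse).
#'
#' @param trainScores n x p feature matrix.
#' @param trainLabels class label per row.
#' @param hidden hidden-neuron count (>= 1).
#' @param seed integer seed for the random layer.
#' @param activation activation tag; "sigmoid" is implemented.
#' @return an \linkS4class{ELMModel}.
#' @export
elmTrain <- function(trainScores, trainLabels, hidden = 10L, seed = 1L,
                     activation = "sigmoid") {
    X <- as.matrix(trainScores)
    f <- factor(trainLabels)
    hidden <- as.integer(hidden)
    if (hidden < 1L) stop("validation error: hidden must be >= 1")
    if (activation != "sigmoid")
        stop("validation error: unsupported activation: ", activation)
    p <- ncol(X)
    par <- .withSeed(as.integer(seed), list(
        Win = matrix(runif(hidden * p, -1, 1), hidden, p),
        b = runif(hidden, -1, 1)))
    H <- .sigmoid(X %*% t(par$Win) + matrix(par$b, nrow(X), hidden,
                                            byrow = TRUE))
    if (all(apply(H, 2, function(col) diff(range(col)) < 1e-12)))
        warning("degenerate hidden layer: all activations constant")
    Tmat <- diag(nlevels(f))[as.integer(f), , drop = FALSE]
    beta <- MASS::ginv(H) %*% Tmat
    new("ELMModel", inputWeights = par$Win, biases = par$b,
        outputWeights = beta, activation = activation,
        seed = as.integer(seed), classLevels = levels(f))
}

#' Predict with an extreme learning machine
#'
#' @param model an \linkS4class{ELMModel}.
#' @param scores query feature matrix.
#' @return factor of predicted labels (argmax of the network output).
#' @export
elmPredict <- function(model, scores) {
    stopifnot(is(model, "ELMModel"))
    X <- as.matrix(scores)
    if (ncol(X) != ncol(model@inputWeights))
        stop("validation error: feature dimension mismatch")
    H <- .sigmoid(X %*% t(model@inputWeights) +
        matrix(model@biases, nrow(X), length(model@biases), byrow = TRUE))
    out <- H %*% model@outputWeights
    factor(model@classLevels[max.col(out, ties.method = "first")],
           levels = model@classLevels)
}

#' Average ELM test accuracy over repeated random initializations
#'
#' Because the random hidden layer makes single ELM runs stochastic, the
#' reported figure is the arithmetic mean of the test accuracy over
#' \code{runs} trainings with seeds 1, 2, ..., runs.
#'
#' @param trainScores,trainLabels training data.
#' @param testScores,testLabels held-out data.
#' @param hidden hidden-neuron count.
#' @param runs number of repetitions (default 50).
#' @return mean test accuracy in [0, 1].
#' @export
elmRepeatEval <- function(trainScores, trainLabels, testScores,
                          testLabels, hidden = 10L, runs = 50L) {
    runs <- as.integer(runs)
    if (runs < 1L) stop("validation error: runs must be >= 1")
    accs <- vapply(seq_len(runs), function(s) {
        mdl <- elmTrain(trainScores, trainLabels, hidden = hidden,
                        seed = s)
        accuracy(elmPredict(mdl, testScores), testLabels)
    }, numeric(1))
    mean(accs)
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Estimates per-class feature means and variances (sample variance,
#' divisor n-1) under the feature-independence assumption, with priors
#' equal to class frequencies. Variances are floored at
#' \code{1e-9 * mean feature variance} to guard against degenerate
#' projected features.
#'
#' @param trainScores n x p feature matrix.
#' @param trainLabels class label per row; every class needs >= 2
#'   samples.
#' @return an \linkS4class{NBModel}.
#' @export
nbFit <- function(trainScores, trainLabels) {
    X <- as.matrix(trainScores)
    f <- factor(trainLabels)
    counts <- table(f)
    if (any(counts < 2))
        stop("validation error: class(es) with fewer than 2 samples: ",
             paste(names(counts)[counts < 2], collapse = ", "))
    mu <- t(vapply(levels(f), function(cl)
        colMeans(X[f == cl, , drop = FALSE]), numeric(ncol(X))))
    v <- t(vapply(levels(f), function(cl)
        apply(X[f == cl, , drop = FALSE], 2, var), numeric(ncol(X))))
    floorV <- 1e-9 * mean(apply(X, 2, var))
    if (floorV <= 0) floorV <- 1e-12
    v <- pmax(v, floorV)
    new("NBModel", means = mu, variances = v,
        priors = as.numeric(counts) / length(f), varianceFloor = floorV,
        classLevels = levels(f))
}

#' Predict with a Gaussian naive Bayes classifier
#'
#' Posterior probabilities are computed from the Gaussian log-likelihoods
#' plus log priors, normalized per query; the predicted class maximizes
#' the posterior.
#'
#' @param model an \linkS4class{NBModel}.
#' @param scores query feature matrix.
#' @param posterior if TRUE, return a list with \code{labels} and the
#'   n x c \code{posterior} matrix (rows summing to 1).
#' @return factor of predicted labels, or the list described above.
#' @export
nbPredict <- function(model, scores, posterior = FALSE) {
    stopifnot(is(model, "NBModel"))
    X <- as.matrix(scores)
    if (ncol(X) != ncol(model@means))
        stop("validation error: feature dimension mismatch")
    cc <- length(model@classLevels)
    logp <- matrix(0, nrow(X), cc)
    for (j in seq_len(cc)) {
        mu <- model@means[j, ]; v <- model@variances[j, ]
        ll <- -0.5 * (sweep(X, 2, mu)^2 %*% (1 / v)) -
            0.5 * sum(log(2 * pi * v))
        logp[, j] <- ll + log(model@priors[j])
    }
    shift <- logp - apply(logp, 1, max)
    post <- exp(shift) / rowSums(exp(shift))
    colnames(post) <- model@classLevels
    labels <- factor(model@classLevels[max.col(post, ties.method = "first")],
                     levels = model@classLevels)
    if (posterior) list(labels = labels, posterior = post) else labels
}

#' Classification accuracy
#'
#' @param predicted,truth label vectors of equal length.
#' @return proportion correct, in [0, 1].
#' @export
accuracy <- function(predicted, truth) {
    if (length(predicted) != length(truth))
        stop("validation error: length mismatch")
    mean(as.character(predicted) == as.character(truth))
}
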
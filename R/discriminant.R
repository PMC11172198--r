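.checkClasses <- function(labels) {
    f <- factor(labels)
    if (nlevels(f) < 2) stop("validation error: at least 2 classes required")
    if (any(table(f) == 0)) stop("validation error: empty class")
    f
}

#' Crisp within- and between-class scatter matrices
#'
#' Computes the classical scatter pair on a feature matrix: the
#' within-class scatter Sw sums the outer products (x_k - xbar_i)(x_k -
#' xbar_i)' of every sample around its class mean, and the between-class
#' scatter Sb sums n_i (xbar_i - xbar)(xbar_i - xbar)' of the class means
#' around the grand mean. Sw + Sb equals the total scatter.
#'
#' @param X n x p feature matrix (typically PCA scores).
#' @param labels class label per row.
#' @return list with symmetric PSD matrices \code{within} and
#'   \code{between}, and \code{fuzzy = FALSE}.
#' @export
crispScatter <- function(X, labels) {
    X <- as.matrix(X)
    f <- .checkClasses(labels)
    grand <- colMeans(X)
    p <- ncol(X)
    Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
    for (cl in levels(f)) {
        Xi <- X[f == cl, , drop = FALSE]
        mi <- colMeans(Xi)
        Xc <- sweep(Xi, 2, mi)
        Sw <- Sw + crossprod(Xc)
        dmi <- mi - grand
        Sb <- Sb + nrow(Xi) * tcrossprod(dmi)
    }
    list(within = Sw, between = Sb, fuzzy = FALSE)
}

#' Per-class mean vectors (cluster centres)
#'
#' Row j is the mean of the class-j rows of X. These crisp class means
#' are the fixed cluster centres from which fuzzy memberships are
#' computed.
#'
#' @param X n x p feature matrix.
#' @param labels class label per row.
#' @return c x p matrix, rows in class-level order (named).
#' @export
classMeans <- function(X, labels) {
    X <- as.matrix(X)
    f <- factor(labels)
    if (any(table(f) == 0)) stop("validation error: empty class")
    V <- t(vapply(levels(f), function(cl)
        colMeans(X[f == cl, , drop = FALSE]), numeric(ncol(X))))
    rownames(V) <- levels(f)
    V
}

#' One-pass fuzzy-c-means memberships from fixed centres
#'
#' Computes the fuzzy membership of each sample in each class from its
#' Euclidean distances to fixed cluster centres, using the fuzzy-c-means
#' update with weight exponent m:
#' \deqn{U_{ij} = \left[\sum_k (\|x_i - v_j\| / \|x_i - v_k\|)^{2/(m-1)}\right]^{-1}}
#' No centre iteration is performed. A sample coinciding with one or more
#' centres gets its membership split equally over the coinciding centres
#' and 0 elsewhere. Memberships are invariant to rescaling all inputs,
#' flatten toward 1/c as m grows, and sharpen toward crisp indicators as
#' m approaches 1.
#'
#' @param X n x p feature matrix.
#' @param centers c x p matrix of centres, e.g. [classMeans()].
#' @param m fuzzy weight exponent, greater than 1 (default 3.5).
#' @return a \linkS4class{MembershipMatrix}.
#' @export
fuzzyMembership <- function(X, centers, m = 3.5) {
    X <- as.matrix(X); centers <- as.matrix(centers)
    if (m <= 1) stop("validation error: m must exceed 1")
    if (ncol(X) != ncol(centers))
        stop("validation error: feature dimension mismatch")
    n <- nrow(X); cc <- nrow(centers)
    D <- matrix(0, n, cc)
    for (j in seq_len(cc))
        D[, j] <- sqrt(rowSums(sweep(X, 2, centers[j, ])^2))
    U <- matrix(0, n, cc)
    expo <- 2 / (m - 1)
    for (i in seq_len(n)) {
        zero <- D[i, ] == 0
        if (any(zero)) {
            U[i, zero] <- 1 / sum(zero)
        } else {
            # u_ij = 1 / sum_k (d_ij/d_ik)^expo
            U[i, ] <- vapply(seq_len(cc), function(j)
                1 / sum((D[i, j] / D[i, ])^expo), numeric(1))
        }
    }
    colnames(U) <- rownames(centers)
    new("MembershipMatrix", U = U, centers = centers, m = m)
}

#' Fuzzy within- and between-class scatter matrices
#'
#' Each sample's contribution is weighted by its membership raised to the
#' exponent m: the fuzzy within-class scatter is
#' \deqn{S_{fw} = \sum_j \sum_i U_{ij}^m (x_i - \bar x_j)(x_i - \bar x_j)'}
#' and the fuzzy between-class scatter is
#' \deqn{S_{fb} = \sum_j \sum_i U_{ij}^m (\bar x_j - \bar x)(\bar x_j - \bar x)'}
#' where xbar_j are the crisp class means and xbar the grand mean. With
#' one-hot (crisp) memberships both reduce exactly to the classical
#' scatter pair.
#'
#' @param X n x p feature matrix.
#' @param labels class label per row (defines the crisp class means;
#'   classes in factor-level order must match the membership columns).
#' @param membership a \linkS4class{MembershipMatrix} over the same rows.
#' @param m fuzzy exponent; defaults to the membership's own.
#' @return list with \code{within}, \code{between}, \code{fuzzy = TRUE}
#'   and \code{m}.
#' @export
fuzzyScatter <- function(X, labels, membership, m = membership@m) {
    X <- as.matrix(X)
    f <- .checkClasses(labels)
    U <- if (is(membership, "MembershipMatrix")) membership@U
         else as.matrix(membership)
    if (nrow(U) != nrow(X) || ncol(U) != nlevels(f))
        stop("validation error: membership shape must be n x c")
    grand <- colMeans(X)
    V <- classMeans(X, f)
    p <- ncol(X)
    Um <- U^m
    Sfw <- matrix(0, p, p); Sfb <- matrix(0, p, p)
    for (j in seq_len(nlevels(f))) {
        Xc <- sweep(X, 2, V[j, ])
        Sfw <- Sfw + crossprod(Xc * sqrt(Um[, j]))
        dv <- V[j, ] - grand
        Sfb <- Sfb + sum(Um[, j]) * tcrossprod(dv)
    }
    list(within = Sfw, between = Sfb, fuzzy = TRUE, m = m)
}

# Shared DLDA-style simultaneous diagonalization of a scatter pair:
# whiten the between-class scatter on its range space, then diagonalize
# the transformed within-class scatter; rows ordered by increasing
# within-class eigenvalue.
.directDiscriminant <- function(Sw, Sb, nClasses, tol = 1e-10,
                                floorDw = 1e-12) {
    eb <- eigen(Sb, symmetric = TRUE)
    keep <- eb$values > tol * max(eb$values, 0)
    if (!any(keep))
        stop("validation error: between-class scatter has rank 0")
    r <- min(sum(keep), nClasses - 1L)
    Y <- eb$vectors[, seq_len(r), drop = FALSE]
    Db <- eb$values[seq_len(r)]
    Z <- Y %*% diag(1 / sqrt(Db), r)
    M <- crossprod(Z, Sw %*% Z)
    M <- (M + t(M)) / 2
    ew <- eigen(M, symmetric = TRUE)
    ord <- order(ew$values)               # smallest within-scatter first
    U <- ew$vectors[, ord, drop = FALSE]
    Dw <- ew$values[ord]
    if (any(Dw < floorDw)) {
        warning("within-class eigenvalue(s) below floor; floored at ",
                floorDw)
        Dw <- pmax(Dw, floorDw)
    }
    W <- diag(1 / sqrt(Dw), r) %*% t(U) %*% t(Z)
    list(W = W, Dw = Dw)
}

#' Fit classical linear discriminant directions
#'
#' Solves the generalized eigenproblem Sb w = lambda Sw w via a Cholesky
#' factorization of Sw and returns the top \code{outDim} directions as
#' rows of W, sorted by decreasing generalized eigenvalue. When Sw is
#' singular in the feature space, a small ridge
#' (1e-8 trace(Sw)/p on the diagonal) is added, with a message.
#'
#' @param X n x p feature matrix (typically PCA scores).
#' @param labels class label per row.
#' @param outDim number of directions (default c - 1).
#' @return a \linkS4class{DiscriminantModel} with algorithm "LDA".
#' @export
fitLDA <- function(X, labels, outDim = NULL) {
    X <- as.matrix(X)
    f <- .checkClasses(labels)
    sc <- crispScatter(X, f)
    Sw <- sc$within; Sb <- sc$between
    if (is.null(outDim)) outDim <- nlevels(f) - 1L
    outDim <- min(as.integer(outDim), nlevels(f) - 1L, ncol(X))
    L <- tryCatch(chol(Sw), error = function(e) NULL)
    if (is.null(L)) {
        ridge <- 1e-8 * sum(diag(Sw)) / ncol(X)
        message("within-class scatter singular; adding ridge ",
                format(ridge))
        L <- tryCatch(chol(Sw + ridge * diag(ncol(X))),
                      error = function(e)
            stop("numerical error: within-class scatter is singular even ",
                 "after ridge regularization; reduce npc or add samples"))
    }
    # Sw = L'L; solve the symmetric problem L'^-1 Sb L^-1
    Li <- backsolve(L, diag(ncol(X)))
    Msym <- crossprod(Li, Sb %*% Li)
    Msym <- (Msym + t(Msym)) / 2
    ev <- eigen(Msym, symmetric = TRUE)
    W <- t(Li %*% ev$vectors[, seq_len(outDim), drop = FALSE])
    new("DiscriminantModel", W = W, algorithm = "LDA", Sw = Sw, Sb = Sb,
        diagWithin = ev$values[seq_len(outDim)], m = NA_real_,
        classLevels = levels(f))
}

#' Fit a direct linear discriminant analysis (DLDA) transformation
#'
#' DLDA diagonalizes the scatter pair directly, in an order that remains
#' valid when the within-class scatter is singular (the small-sample
#' setting): the between-class scatter Sb is eigendecomposed and its null
#' space discarded, the data are whitened on the retained range space
#' (Z = Y Db^(-1/2)), the transformed within-class scatter Z' Sw Z is
#' eigendecomposed into U and Dw, and the transformation matrix is
#' W = Dw^(-1/2) U' Z'. Rows are ordered by increasing within-class
#' eigenvalue — the directions where the within-class scatter is smallest
#' carry the most discriminant information. By construction W Sw W' is
#' the identity and W Sb W' is diagonal.
#'
#' @param X n x p feature matrix.
#' @param labels class label per row.
#' @param tol relative eigenvalue tolerance for discarding the Sb null
#'   space.
#' @return a \linkS4class{DiscriminantModel} with algorithm "DLDA" and at
#'   most c - 1 rows in W.
#' @export
fitDLDA <- function(X, labels, tol = 1e-10) {
    X <- as.matrix(X)
    f <- .checkClasses(labels)
    sc <- crispScatter(X, f)
    dd <- .directDiscriminant(sc$within, sc$between, nlevels(f), tol)
    new("DiscriminantModel", W = dd$W, algorithm = "DLDA",
        Sw = sc$within, Sb = sc$between, diagWithin = dd$Dw,
        m = NA_real_, classLevels = levels(f))
}

#' Fit a fuzzy direct linear discriminant analysis (FDLDA) transformation
#'
#' Identical pipeline to [fitDLDA()], but run on the fuzzy scatter pair:
#' class-mean cluster centres ([classMeans()]) give one-pass fuzzy
#' memberships ([fuzzyMembership()]) with weight exponent m, which weight
#' each sample's contribution to the scatters ([fuzzyScatter()]).
#' Boundary samples of overlapping classes — whose memberships are spread
#' over several classes — are down-weighted, which is what lets FDLDA
#' cope with overlapped data better than crisp DLDA.
#'
#' @param X n x p feature matrix.
#' @param labels class label per row.
#' @param m fuzzy weight exponent, greater than 1 (default 3.5).
#' @param membership optional precomputed \linkS4class{MembershipMatrix};
#'   by default computed from the crisp class means.
#' @param tol as in [fitDLDA()].
#' @return a \linkS4class{DiscriminantModel} with algorithm "FDLDA".
#' @export
fitFDLDA <- function(X, labels, m = 3.5, membership = NULL, tol = 1e-10) {
    X <- as.matrix(X)
    f <- .checkClasses(labels)
    if (m <= 1) stop("validation error: m must exceed 1")
    if (is.null(membership)) {
        V <- classMeans(X, f)
        membership <- fuzzyMembership(X, V, m)
    }
    sc <- fuzzyScatter(X, f, membership, m)
    dd <- .directDiscriminant(sc$within, sc$between, nlevels(f), tol)
    new("DiscriminantModel", W = dd$W, algorithm = "FDLDA",
        Sw = sc$within, Sb = sc$between, diagWithin = dd$Dw, m = m,
        classLevels = levels(f))
}

#' Project features through a fitted discriminant model
#'
#' @param model a \linkS4class{DiscriminantModel}.
#' @param X n x p feature matrix with p matching the model.
#' @return n x nrow(W) matrix of discriminant scores (columns DV1, ...).
#' @export
discriminantTransform <- function(model, X) {
    stopifnot(is(model, "DiscriminantModel"))
    X <- as.matrix(X)
    if (ncol(X) != ncol(model@W))
        stop("validation error: feature dimension does not match W")
    S <- X %*% t(model@W)
    colnames(S) <- paste0("DV", seq_len(ncol(S)))
    S
}

setMethod("show", "DiscriminantModel", function(object) {
    cat(sprintf("DiscriminantModel (%s): %d discriminant vectors in %d-D\n",
        object@algorithm, nrow(object@W), ncol(object@W)))
    if (object@algorithm == "FDLDA")
        cat(sprintf("  fuzzy weight exponent m = %g\n", object@m))
    invisible(NULL)
})

setMethod("show", "MembershipMatrix", function(object) {
    cat(sprintf("MembershipMatrix: %d samples x %d classes, m = %g\n",
        nrow(object@U), ncol(object@U), object@m))
    cat(sprintf("  mean max membership: %.3f\n",
        mean(apply(object@U, 1, max))))
    invisible(NULL)
})
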
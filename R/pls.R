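#' Principal component analysis by singular value decomposition
#'
#' Exploratory PCA of a preprocessed sample-by-feature matrix: the matrix is
#' column-centered and decomposed by SVD; scores are `U D`, loadings `V`.
#'
#' @param X numeric matrix, samples x features (already scaled as desired)
#' @param nPC number of components to return
#' @return list with `scores` (samples x nPC), `loadings` (features x nPC)
#'   and `explained` (variance fractions for all components, non-increasing)
#' @export
pca <- function(X, nPC = 2L) {
    X <- as.matrix(X)
    nPC <- as.integer(nPC)
    stopifnot(nPC >= 1L, nPC <= min(dim(X)))
    Xc <- sweep(X, 2L, colMeans(X))
    sv <- svd(Xc)
    if (sum(sv$d^2) < .Machine$double.eps)
        stop("degenerate matrix: no variance to decompose")
    scores <- sv$u[, seq_len(nPC), drop = FALSE] %*%
        diag(sv$d[seq_len(nPC)], nPC)
    rownames(scores) <- rownames(X)
    loadings <- sv$v[, seq_len(nPC), drop = FALSE]
    rownames(loadings) <- colnames(X)
    colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(nPC))
    list(scores = scores, loadings = loadings,
         explained = sv$d^2 / sum(sv$d^2))
}

# Internal preprocessing used by fitPLS: center or autoscale. Unlike the
# exported autoscale(), zero-variance columns get unit scale (they carry no
# information and must not break cross-validation refits).
.plsPrep <- function(m, how) {
    center <- colMeans(m)
    s <- rep(1, ncol(m))
    if (how == "autoscale") {
        s <- colSds(m)
        s[s == 0] <- 1
    } else if (how == "none") {
        center <- rep(0, ncol(m))
    }
    list(m = sweep(sweep(m, 2L, center), 2L, s, "/"), center = center,
         scale = s)
}

#' Fit a PLS model by NIPALS
#'
#' Nonlinear iterative partial least squares with X-deflation: components are
#' extracted one at a time, each maximizing the covariance between an X-score
#' and a Y-score; X (and Y) are deflated by the extracted component before
#' the next one. The regression coefficient matrix is
#' `B = W (P'W)^-1 Q'`. Preprocessing of both blocks is captured in the model
#' so [predict()] consumes and returns raw-scale data.
#'
#' @param X samples x features matrix
#' @param Y samples x responses matrix (or vector)
#' @param nLV number of latent variables (must not exceed the rank of the
#'   preprocessed X)
#' @param xScale,yScale "center", "autoscale" or "none"
#' @param maxIter,tol NIPALS inner-loop iteration cap and convergence
#'   tolerance on the X-score
#' @param responseKind "continuous" or "class-dummy"
#' @param classLevels class labels when `responseKind = "class-dummy"`
#' @return a [PLSModel-class]
#' @export
fitPLS <- function(X, Y, nLV,
                   xScale = c("center", "autoscale", "none"),
                   yScale = c("center", "autoscale", "none"),
                   maxIter = 500L, tol = 1e-10,
                   responseKind = "continuous",
                   classLevels = character()) {
    xScale <- match.arg(xScale)
    yScale <- match.arg(yScale)
    X <- as.matrix(X)
    Y <- as.matrix(Y)
    stopifnot(nrow(X) == nrow(Y))
    nLV <- as.integer(nLV)
    if (nLV < 1L) stop("nLV must be >= 1")

    px <- .plsPrep(X, xScale)
    py <- .plsPrep(Y, yScale)
    E <- px$m
    F <- py$m
    rank <- qr(E)$rank
    if (nLV > rank)
        stop("nLV (", nLV, ") exceeds the rank of the preprocessed X (",
             rank, ")")

    n <- nrow(E); p <- ncol(E); q <- ncol(F)
    W <- matrix(0, p, nLV); P <- matrix(0, p, nLV)
    Q <- matrix(0, q, nLV); Tm <- matrix(0, n, nLV)
    ssX <- sum(E^2); ssY <- sum(F^2)
    expX <- expY <- numeric(nLV)

    for (a in seq_len(nLV)) {
        u <- F[, which.max(colSums(F^2)), drop = TRUE]
        tOld <- rep(Inf, n)
        for (it in seq_len(maxIter)) {
            w <- crossprod(E, u)
            w <- w / sqrt(sum(w^2))
            tt <- as.vector(E %*% w)
            qv <- crossprod(F, tt) / sum(tt^2)
            if (q == 1L) break
            u <- as.vector(F %*% qv) / sum(qv^2)
            if (sqrt(sum((tt - tOld)^2)) / sqrt(sum(tt^2)) < tol) break
            tOld <- tt
            if (it == maxIter)
                stop("NIPALS did not converge for component ", a,
                     " after ", maxIter, " iterations")
        }
        pv <- crossprod(E, tt) / sum(tt^2)
        E <- E - tcrossprod(tt, pv)
        F <- F - tcrossprod(tt, qv)
        W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
        expX[a] <- sum(tcrossprod(tt, pv)^2) / ssX
        expY[a] <- if (ssY > 0) sum(tcrossprod(tt, qv)^2) / ssY else 0
    }

    B <- W %*% solve(crossprod(P, W), t(Q))
    rownames(B) <- colnames(X)
    colnames(B) <- colnames(Y)
    rownames(W) <- rownames(P) <- colnames(X)
    rownames(Q) <- colnames(Y)
    rownames(Tm) <- rownames(X)
    colnames(W) <- colnames(P) <- colnames(Q) <- colnames(Tm) <-
        paste0("LV", seq_len(nLV))

    new("PLSModel", nLV = nLV, weights = W, xLoadings = P, yLoadings = Q,
        scores = Tm, coefficients = B,
        xCenter = px$center, xScale = px$scale,
        yCenter = py$center, yScale = py$scale,
        responseKind = responseKind, classLevels = classLevels,
        featureNames = colnames(X) %||% character(),
        responseNames = colnames(Y) %||% character(),
        explainedX = expX, explainedY = expY, cv = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname PLSModel-class
setMethod("nComponents", "PLSModel", function(object) object@nLV)

setMethod("show", "PLSModel", function(object) {
    cat(sprintf("PLSModel (%s): %d LV, %d features, %d response(s)\n",
                object@responseKind, object@nLV, nrow(object@coefficients),
                ncol(object@coefficients)))
    cat(sprintf("  cumulative explained variance: X %.1f%%, Y %.1f%%\n",
                100 * sum(object@explainedX),
                100 * sum(object@explainedY)))
})

# Coefficients truncated to the first a components.
.plsB <- function(model, a) {
    if (a == model@nLV) return(model@coefficients)
    W <- model@weights[, seq_len(a), drop = FALSE]
    P <- model@xLoadings[, seq_len(a), drop = FALSE]
    Q <- model@yLoadings[, seq_len(a), drop = FALSE]
    W %*% solve(crossprod(P, W), t(Q))
}

#' Predict from a fitted PLS model
#'
#' Applies the stored X preprocessing, the regression coefficients, and the
#' inverse Y preprocessing, so raw-scale inputs give raw-scale predictions.
#'
#' @param object a [PLSModel-class]
#' @param newdata samples x features matrix on the model's feature grid
#' @param nLV number of components to use (defaults to the fitted count)
#' @param ... unused
#' @return samples x responses prediction matrix
#' @export
setMethod("predict", "PLSModel", function(object, newdata,
                                          nLV = object@nLV, ...) {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object@xCenter))
        stop("newdata feature grid does not match the model (",
             ncol(newdata), " vs ", length(object@xCenter), ")")
    if (length(object@featureNames) && !is.null(colnames(newdata)) &&
        !identical(colnames(newdata), object@featureNames))
        stop("newdata feature names do not match the model's feature grid")
    nLV <- as.integer(nLV)
    stopifnot(nLV >= 1L, nLV <= object@nLV)
    Xc <- sweep(sweep(newdata, 2L, object@xCenter), 2L, object@xScale, "/")
    Yc <- Xc %*% .plsB(object, nLV)
    out <- sweep(sweep(Yc, 2L, object@yScale, "*"), 2L, object@yCenter, "+")
    rownames(out) <- rownames(newdata)
    colnames(out) <- if (length(object@responseNames)) object@responseNames
    out
})

#' Venetian-blinds cross-validation
#'
#' Interleaved folds: split s contains the samples whose (1-based) index i
#' satisfies `(i - 1) mod nSplits == s - 1`, in the dataset's stored sample
#' order. For each candidate LV count 1..maxLV, each fold is predicted by a
#' model fitted - including its preprocessing states - on the remaining
#' folds only, and the root mean squared prediction error is pooled over all
#' held-out entries. With `nSplits` equal to the sample count this is
#' leave-one-out. For class responses the misclassification rate per LV
#' count is recorded as well, and folds that lose an entire class are noted
#' in the split descriptor.
#'
#' @inheritParams fitPLS
#' @param maxLV largest LV count to evaluate (capped at the minimum training
#'   rank across folds; the cap is recorded in the split descriptor)
#' @param nSplits number of interleaved folds (>= 2)
#' @return a [CVResult-class]; `splits$predictions` holds the held-out
#'   predictions as a samples x responses x LV array
#' @export
venetianBlindsCV <- function(X, Y, maxLV, nSplits = 5L,
                             xScale = c("center", "autoscale", "none"),
                             yScale = c("center", "autoscale", "none"),
                             responseKind = "continuous",
                             classLevels = character()) {
    xScale <- match.arg(xScale)
    yScale <- match.arg(yScale)
    X <- as.matrix(X)
    Y <- as.matrix(Y)
    n <- nrow(X)
    nSplits <- as.integer(nSplits)
    stopifnot(nSplits >= 2L, nSplits <= n, nrow(Y) == n)
    foldId <- ((seq_len(n) - 1L) %% nSplits) + 1L

    warnings <- character()
    isClass <- responseKind == "class-dummy"
    # cap candidates at what every fold can support
    rankCap <- min(vapply(seq_len(nSplits), function(s) {
        tr <- X[foldId != s, , drop = FALSE]
        qr(sweep(tr, 2L, colMeans(tr)))$rank
    }, integer(1L)))
    aMax <- min(as.integer(maxLV), rankCap)
    if (aMax < maxLV)
        warnings <- c(warnings, sprintf(
            "maxLV reduced from %d to %d (training-fold rank)", maxLV, aMax))

    # late components can oscillate in the NIPALS inner loop once the Y
    # residual is noise-dominated; truncate the candidate range rather than
    # abort the whole cross-validation
    preds <- NULL
    while (is.null(preds) && aMax >= 1L) {
        preds <- tryCatch({
            pr <- array(NA_real_, c(n, ncol(Y), aMax),
                        dimnames = list(rownames(X), colnames(Y), NULL))
            for (s in seq_len(nSplits)) {
                tr <- foldId != s
                if (isClass) {
                    lost <- colSums(Y[tr, , drop = FALSE]) == 0
                    if (any(lost))
                        warnings <- c(warnings, sprintf(
                            "fold %d training set lost class(es): %s", s,
                            paste(colnames(Y)[lost], collapse = ", ")))
                }
                fit <- fitPLS(X[tr, , drop = FALSE],
                              Y[tr, , drop = FALSE],
                              nLV = aMax, xScale = xScale,
                              yScale = yScale,
                              responseKind = responseKind,
                              classLevels = classLevels)
                for (a in seq_len(aMax))
                    pr[!tr, , a] <- predict(fit, X[!tr, , drop = FALSE],
                                            nLV = a)
            }
            pr
        }, error = function(e) {
            if (!grepl("NIPALS did not converge", conditionMessage(e)) ||
                aMax == 1L)
                stop(e)
            warnings <<- c(warnings, sprintf(
                "maxLV reduced from %d to %d (NIPALS non-convergence)",
                aMax, aMax - 1L))
            aMax <<- aMax - 1L
            NULL
        })
    }
    warnings <- unique(warnings)

    rmsecv <- vapply(seq_len(aMax),
                     function(a) sqrt(mean((preds[, , a] - Y)^2)),
                     numeric(1L))
    classError <- numeric(0)
    if (isClass) {
        lv <- if (length(classLevels)) classLevels else colnames(Y)
        truth <- lv[max.col(Y, ties.method = "first")]
        classError <- vapply(seq_len(aMax), function(a) {
            assigned <- plsdaAssign(preds[, , a, drop = FALSE][, , 1L],
                                    classLevels = lv)
            mean(as.character(assigned) != truth)
        }, numeric(1L))
    }

    full <- fitPLS(X, Y, nLV = aMax, xScale = xScale, yScale = yScale,
                   responseKind = responseKind, classLevels = classLevels)
    new("CVResult", rmsecv = rmsecv, classError = classError,
        explainedX = full@explainedX, explainedY = full@explainedY,
        chosenNLV = NA_integer_,
        splits = list(nSplits = nSplits, foldId = foldId, maxLV = aMax,
                      warnings = warnings, predictions = preds,
                      observed = Y))
}

#' Choose the LV count by the parsimony rule
#'
#' Returns the smallest LV count whose cross-validation criterion
#' (misclassification rate for class responses, RMSECV otherwise) lies
#' within a relative tolerance of the global minimum - the smallest model
#' that is statistically as good as the best one, minimizing overfitting
#' risk.
#'
#' @param cv a [CVResult-class]
#' @param tol relative tolerance (default 2\%)
#' @return integer LV count
#' @export
selectNLV <- function(cv, tol = 0.02) {
    crit <- if (length(cv@classError)) cv@classError else cv@rmsecv
    stopifnot(length(crit) >= 1L)
    m <- min(crit)
    as.integer(which(crit <= m * (1 + tol))[1L])
}

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: %d-fold venetian blinds, %d LV candidates\n",
                object@splits$nSplits, length(object@rmsecv)))
    cat("  RMSECV:", paste(sprintf("%.4g", object@rmsecv), collapse = " "),
        "\n")
    if (length(object@classError))
        cat("  class error:",
            paste(sprintf("%.3f", object@classError), collapse = " "), "\n")
    if (!is.na(object@chosenNLV))
        cat("  chosen nLV:", object@chosenNLV, "\n")
})

#' Serialize / restore a PLS model as structured text (JSON)
#'
#' @param model a [PLSModel-class]
#' @param file path
#' @name pls-io
#' @export
writePLSModel <- function(model, file) {
    jsonlite::write_json(list(
        nLV = model@nLV, weights = model@weights,
        xLoadings = model@xLoadings, yLoadings = model@yLoadings,
        scores = model@scores, coefficients = model@coefficients,
        xCenter = model@xCenter, xScale = model@xScale,
        yCenter = model@yCenter, yScale = model@yScale,
        responseKind = model@responseKind, classLevels = model@classLevels,
        featureNames = model@featureNames,
        responseNames = model@responseNames,
        explainedX = model@explainedX, explainedY = model@explainedY),
        file, digits = NA, auto_unbox = TRUE)
    invisible(file)
}

#' @rdname pls-io
#' @export
readPLSModel <- function(file) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    new("PLSModel", nLV = as.integer(x$nLV),
        weights = as.matrix(x$weights), xLoadings = as.matrix(x$xLoadings),
        yLoadings = as.matrix(x$yLoadings), scores = as.matrix(x$scores),
        coefficients = as.matrix(x$coefficients),
        xCenter = as.numeric(x$xCenter), xScale = as.numeric(x$xScale),
        yCenter = as.numeric(x$yCenter), yScale = as.numeric(x$yScale),
        responseKind = x$responseKind,
        classLevels = as.character(x$classLevels %||% character()),
        featureNames = as.character(x$featureNames %||% character()),
        responseNames = as.character(x$responseNames %||% character()),
        explainedX = as.numeric(x$explainedX),
        explainedY = as.numeric(x$explainedY), cv = list())
}
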
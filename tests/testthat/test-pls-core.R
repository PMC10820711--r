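test_that("pca matches direct eigendecomposition and SVD identities", {
    set.seed(3)
    # rank-1 matrix: first PC explains everything
    X1 <- outer(rnorm(10), rnorm(6))
    p1 <- pca(X1, 1L)
    expect_gt(p1$explained[1L], 1 - 1e-12)

    X <- matrix(rnorm(80), 16, 5)
    p <- pca(X, 5L)
    Xc <- sweep(X, 2L, colMeans(X))
    expect_lt(max(abs(p$scores %*% t(p$loadings) - Xc)), 1e-10)
    ev <- eigen(cov(X), symmetric = TRUE)$values
    expect_equal(p$explained, ev / sum(ev), tolerance = 1e-10)
    expect_true(all(diff(p$explained) <= 1e-12))
    expect_error(pca(matrix(1, 4, 3), 2L), "degenerate")
})

test_that("single-factor noiseless responses are captured by one LV", {
    set.seed(4)
    t1 <- rnorm(20)
    X <- outer(t1, rnorm(8))
    y <- 2 * t1 + 1
    m <- fitPLS(X, matrix(y), nLV = 1L)
    expect_lt(max(abs(predict(m, X) - y)), 1e-8)
})

test_that("full-rank PLS equals ordinary least squares", {
    set.seed(5)
    X <- matrix(rnorm(120), 24, 5)
    y <- rnorm(24)
    m <- fitPLS(X, matrix(y), nLV = 5L)
    # normal-equations oracle on centered data
    Xc <- sweep(X, 2L, colMeans(X))
    yc <- y - mean(y)
    beta <- solve(crossprod(Xc), crossprod(Xc, yc))
    ols <- as.numeric(Xc %*% beta) + mean(y)
    expect_lt(max(abs(as.numeric(predict(m, X)) - ols)), 1e-6)
})

test_that("the first PLS1 weight vector is proportional to X'y", {
    set.seed(6)
    X <- matrix(rnorm(100), 20, 5)
    y <- rnorm(20)
    m <- fitPLS(X, matrix(y), nLV = 3L)
    Xc <- sweep(X, 2L, colMeans(X))
    w0 <- crossprod(Xc, y - mean(y))
    w0 <- w0 / sqrt(sum(w0^2))
    expect_lt(min(max(abs(m@weights[, 1L] - w0)),
                  max(abs(m@weights[, 1L] + w0))), 1e-10)
})

test_that("scores are orthogonal and deflation shrinks the residual", {
    set.seed(7)
    X <- matrix(rnorm(200), 20, 10)
    Y <- cbind(rnorm(20), rnorm(20))
    m <- fitPLS(X, Y, nLV = 6L)
    G <- crossprod(m@scores)
    offdiag <- G - diag(diag(G))
    expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
    # residual X norm strictly decreases with each extracted component
    Xc <- sweep(X, 2L, colMeans(X))
    res <- numeric(6L)
    E <- Xc
    for (a in 1:6) {
        tt <- m@scores[, a]
        E <- E - tcrossprod(tt, m@xLoadings[, a])
        res[a] <- sum(E^2)
    }
    expect_true(all(diff(c(sum(Xc^2), res)) < 0))
    # B reproduces training predictions on the preprocessed scale
    expect_lt(max(abs(Xc %*% m@coefficients -
                      m@scores %*% t(m@yLoadings))), 1e-10)
})

test_that("prediction matches the step-by-step score projection", {
    set.seed(8)
    X <- matrix(rnorm(150), 15, 10)
    Y <- cbind(rnorm(15), rnorm(15))
    Xnew <- matrix(rnorm(50), 5, 10)
    m <- fitPLS(X, Y, nLV = 4L)
    # independent prediction path: project scores component by component
    E <- sweep(Xnew, 2L, m@xCenter)
    yhat <- matrix(0, 5, 2)
    for (a in 1:4) {
        tt <- E %*% m@weights[, a]
        yhat <- yhat + tcrossprod(tt, m@yLoadings[, a])
        E <- E - tcrossprod(tt, m@xLoadings[, a])
    }
    yhat <- sweep(yhat, 2L, m@yCenter, "+")
    expect_lt(max(abs(yhat - predict(m, Xnew))), 1e-10)
    # training predictions reproduce the fit; duplicated rows duplicate
    expect_equal(predict(m, X[c(1, 1), ])[1L, ],
                 predict(m, X[c(1, 1), ])[2L, ])
})

test_that("sample permutation permutes scores and leaves B unchanged", {
    set.seed(9)
    X <- matrix(rnorm(120), 12, 10)
    Y <- matrix(rnorm(12))
    m <- fitPLS(X, Y, nLV = 3L)
    perm <- sample(12)
    mp <- fitPLS(X[perm, ], Y[perm, , drop = FALSE], nLV = 3L)
    expect_equal(unname(mp@coefficients), unname(m@coefficients),
                 tolerance = 1e-10)
    expect_equal(unname(mp@scores), unname(m@scores[perm, ]),
                 tolerance = 1e-10)
})

test_that("rank violations and convergence caps raise errors", {
    X <- outer(rnorm(8), rnorm(5))        # rank 1
    expect_error(fitPLS(X, matrix(rnorm(8)), nLV = 3L), "rank")
})

test_that("venetian blinds with n splits equals leave-one-out", {
    set.seed(10)
    n <- 14L
    X <- matrix(rnorm(n * 5), n, 5)
    y <- X %*% rnorm(5) + 0.3 * rnorm(n)
    cv <- venetianBlindsCV(X, matrix(y), maxLV = 3L, nSplits = n)
    # explicit LOO loop oracle
    errs <- matrix(NA_real_, n, 3L)
    for (i in seq_len(n)) {
        m <- fitPLS(X[-i, ], matrix(y[-i]), nLV = 3L)
        for (a in 1:3)
            errs[i, a] <- predict(m, X[i, , drop = FALSE], nLV = a) - y[i]
    }
    expect_equal(cv@rmsecv, sqrt(colMeans(errs^2)), tolerance = 1e-10)
})

test_that("noiseless rank-2 systems are solved exactly at 2 LVs", {
    set.seed(12)
    T2 <- matrix(rnorm(40), 20, 2)
    X <- T2 %*% matrix(rnorm(16), 2, 8)
    y <- T2 %*% c(1, -2)
    cv <- venetianBlindsCV(X, matrix(y), maxLV = 2L, nSplits = 5L)
    expect_lt(cv@rmsecv[2L], 1e-8)
    expect_gt(cv@rmsecv[1L], 10 * cv@rmsecv[2L])
})

test_that("cross-validation never touches held-out rows", {
    set.seed(13)
    X <- matrix(rnorm(100), 20, 5)
    y <- X %*% rnorm(5) + rnorm(20)
    cv1 <- venetianBlindsCV(X, matrix(y), maxLV = 3L, nSplits = 4L)
    fold <- cv1@splits$foldId
    # each fold's model (including preprocessing) is a pure function of
    # the other folds: a manual refit reproduces the fold predictions
    for (s in c(1L, 3L)) {
        m <- fitPLS(X[fold != s, ], matrix(y[fold != s]), nLV = 3L)
        for (a in 1:3)
            expect_equal(cv1@splits$predictions[fold == s, 1L, a],
                         predict(m, X[fold == s, ], nLV = a)[, 1L],
                         tolerance = 1e-10)
    }
    # corrupting the held-out responses cannot change their predictions
    y2 <- y
    y2[fold == 2L] <- y2[fold == 2L] + 100
    cv2 <- venetianBlindsCV(X, matrix(y2), maxLV = 3L, nSplits = 4L)
    expect_equal(cv1@splits$predictions[fold == 2L, , , drop = FALSE],
                 cv2@splits$predictions[fold == 2L, , , drop = FALSE],
                 tolerance = 1e-10)
})

test_that("the parsimony rule picks the smallest near-optimal LV count", {
    mk <- function(v) new("CVResult", rmsecv = v, classError = numeric(0),
                          explainedX = numeric(0),
                          explainedY = numeric(0),
                          chosenNLV = NA_integer_, splits = list())
    expect_equal(selectNLV(mk(c(0.9, 0.5, 0.52))), 2L)
    expect_equal(selectNLV(mk(c(0.5, 0.499, 0.498))), 1L)
    expect_equal(selectNLV(mk(c(0.9, 0.8, 0.7, 0.6))), 4L)
})

test_that("PLS-DA separates well-separated classes and not shuffled ones", {
    set.seed(14)
    n <- 45L
    cls <- rep(c("light", "medium", "dark"), each = 15L)
    centers <- rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
    X <- centers[rep(1:3, each = 15L), ] + matrix(rnorm(n * 3, 0, 0.4),
                                                  n, 3)
    X <- cbind(X, matrix(rnorm(n * 4), n, 4))
    ord <- sample(n)                       # interleave for the blinds
    fit <- plsdaFit(X[ord, ], cls[ord], maxLV = 4L, nSplits = 5L)
    expect_equal(min(fit$cv@classError), 0)
    expect_lte(fit$cv@classError[fit$cv@chosenNLV], 0.05)

    shuf <- sample(cls)
    fitS <- plsdaFit(X[ord, ], shuf[ord], maxLV = 4L, nSplits = 5L)
    acc <- 1 - fitS$cv@classError[fitS$cv@chosenNLV]
    expect_lt(abs(acc - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n) + 0.05)

    expect_error(plsdaFit(X, rep("one", n)), "2 classes")
    expect_error(plsdaFit(X[1:4, ], c("a", "a", "a", "b")), "fewer than 2")
})

test_that("identical samples with different labels force errors", {
    set.seed(15)
    X <- rbind(matrix(rnorm(40), 10, 4), 0, 0)
    labs <- c(rep(c("a", "b"), 5L), "a", "b")
    fit <- plsdaFit(X, labs, maxLV = 2L, nSplits = 4L)
    pred <- predict(fit$model, X)
    assigned <- plsdaAssign(pred)
    expect_gte(mean(as.character(assigned) != labs), 1 / nrow(X))
})

test_that("class assignment is arg-max with flagged first-class ties", {
    p <- rbind(c(0.9, 0.3, -0.1), c(0.5, 0.5, 0.0), c(0.1, 0.2, 0.7))
    colnames(p) <- c("light", "medium", "dark")
    a <- plsdaAssign(p)
    expect_equal(as.character(a), c("light", "light", "dark"))
    expect_equal(attr(a, "ties"), 2L)
    # invariant to adding a constant to all columns of a row
    a2 <- plsdaAssign(sweep(p, 1L, c(5, -2, 0.3), "+"))
    expect_equal(as.character(a2), as.character(a))
})

test_that("classification metrics match hand arithmetic and a tally oracle", {
    truth <- rep(c("x", "y"), c(9, 11))
    assigned <- c(rep("x", 8), "y", rep("x", 2), rep("y", 9))
    m <- classificationMetrics(truth, assigned)
    expect_equal(unname(m@sensitivity["x"]), 8 / 9)
    expect_equal(unname(m@specificity["x"]), 9 / 11)
    expect_equal(m@accuracy, 17 / 20)
    expect_equal(sum(m@confusion), 20)

    # perfect assignment
    mp <- classificationMetrics(truth, truth)
    expect_equal(mp@accuracy, 1)
    expect_equal(mp@classError, 0)
    expect_true(all(mp@sensitivity == 1) && all(mp@specificity == 1))

    # independent exhaustive recount on random labels
    set.seed(16)
    t2 <- sample(c("a", "b", "c"), 60, replace = TRUE)
    a2 <- sample(c("a", "b", "c"), 60, replace = TRUE)
    m2 <- classificationMetrics(t2, a2)
    for (k in c("a", "b", "c")) {
        tp <- sum(t2 == k & a2 == k); fn <- sum(t2 == k & a2 != k)
        tn <- sum(t2 != k & a2 != k); fp <- sum(t2 != k & a2 == k)
        expect_equal(unname(m2@sensitivity[k]), tp / (tp + fn))
        expect_equal(unname(m2@specificity[k]), tn / (tn + fp))
    }
    expect_equal(m2@accuracy, mean(t2 == a2))
    expect_error(classificationMetrics(c("a", "a"), c("b", "b")),
                 "disjoint")
})

test_that("PLS models serialize and restore through JSON", {
    set.seed(17)
    X <- matrix(rnorm(60), 12, 5)
    m <- fitPLS(X, matrix(rnorm(12)), nLV = 2L)
    f <- tempfile(fileext = ".json")
    writePLSModel(m, f)
    back <- readPLSModel(f)
    expect_equal(back@coefficients, m@coefficients)
    expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
})
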
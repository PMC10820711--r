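test_that("VID coefficients equal direct Pearson correlations", {
    set.seed(21)
    n <- 30L
    areas <- matrix(exp(rnorm(n * 8, 12, 1)), n, 8,
                    dimnames = list(NULL, sprintf("c%d", 1:8)))
    vt <- toyVolatileTable(areas, origins = c("E", "C"), batches = 5L)
    P <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL,
                                                    c("l", "m", "d")))
    vid <- vidScores(vt, P)
    oracle <- matrix(NA_real_, 8, 3)
    for (j in 1:8) for (k in 1:3)
        oracle[j, k] <- cor(areas[, j], P[, k])
    expect_lt(max(abs(vid@coefficients - oracle)), 1e-12)
    expect_true(all(abs(vid@coefficients) <= 1))
    expect_error(vidScores(vt, P[-1, ]), "do not match")
})

test_that("VID is affine-invariant and antisymmetric in the abundance", {
    set.seed(22)
    n <- 18L
    x <- exp(rnorm(n, 10, 0.5))
    P <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    base <- vidScores(toyVolatileTable(cbind(v = x), batches = 3L,
                                       origins = c("E", "C")), P)
    aff <- vidScores(toyVolatileTable(cbind(v = 3.7 * x + 100),
                                      batches = 3L, origins = c("E", "C")),
                     P)
    expect_equal(aff@coefficients, base@coefficients, tolerance = 1e-12)
    # negation flips the sign (areas must stay >= 0, so reflect around max)
    neg <- vidScores(toyVolatileTable(cbind(v = max(x) - x), batches = 3L,
                                      origins = c("E", "C")), P)
    expect_equal(neg@coefficients, -base@coefficients, tolerance = 1e-12)

    # a compound that is a positive affine image of a membership column
    vt2 <- toyVolatileTable(cbind(v = 2 * (P[, 1] - min(P[, 1])) + 5),
                            batches = 3L, origins = c("E", "C"))
    expect_equal(unname(vidScores(vt2, P)@coefficients[1L, "a"]), 1,
                 tolerance = 1e-12)
})

test_that("zero-variance compounds are flagged, not scored", {
    n <- 9L
    vt <- toyVolatileTable(cbind(flatline = rep(7, n),
                                 ok = exp(rnorm(n))), batches = 3L)
    P <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    vid <- vidScores(vt, P)
    expect_identical(vid@undefined, "flatline")
    expect_true(all(is.na(vid@coefficients["flatline", ])))
    expect_true(all(is.finite(vid@coefficients["ok", ])))
})

test_that("threshold rules: signed 0.8 marker rule, |0.9| heatmap rule", {
    cc <- rbind(a = c(0.85, -0.1), b = c(-0.95, 0.2), c = c(0.99, 0.3),
                d = c(1.0, -1.0), e = c(NA, 0.5))
    colnames(cc) <- c("dark", "light")
    vid <- new("VIDResult", coefficients = cc, thresholds = numeric(0),
               selected = list(), undefined = "e")
    signed <- selectDiscriminant(vid, 0.8, signed = TRUE)
    expect_identical(signed$dark, c("d", "c", "a"))   # descending |VID|
    expect_false("b" %in% signed$dark)
    mag <- selectDiscriminant(vid, 0.9, signed = FALSE)
    expect_identical(mag$dark, c("d", "c", "b"))
    # boundary: threshold 1 admits only exact +/-1
    one <- selectDiscriminant(vid, 1.0, signed = FALSE)
    expect_identical(one$dark, "d")
    expect_identical(one$light, "d")
    expect_warning(selectDiscriminant(
        new("VIDResult", coefficients = cc * 0.1,
            thresholds = numeric(0), selected = list(),
            undefined = character(0)), 0.9), "no compound")
})

test_that("an exact class indicator has its largest VID for that class", {
    md <- as.data.frame(sampleData(fx$volatiles))
    iE <- md$origin == "Ethiopia"
    vt <- fx$volatiles[, iE]
    A <- peakAreas(vt)
    A <- cbind(A, indicator = 1e5 + 9e5 * (md$roast[iE] == "dark"))
    rd <- rbind(as.data.frame(compoundData(vt))[, "compoundClass",
                                                drop = FALSE],
                data.frame(compoundClass = "other",
                           row.names = "indicator"))
    vt2 <- VolatileTable(A, rd, md[iE, ])
    fit <- plsdaFit(A, md$roast[iE], maxLV = 4L, nSplits = 5L,
                    xScale = "autoscale")
    vid <- vidScores(vt2, predict(fit$model, A))
    v <- vid@coefficients["indicator", ]
    expect_equal(names(which.max(v)), "dark")
    expect_gt(v["dark"], max(v[names(v) != "dark"]))
})

test_that("heatmap rows are scaled class means in stable order", {
    # zero within-class variance: row equals the scaled class means,
    # maximal in the class where the compound peaks
    n <- 9L
    up <- rep(c(1, 2, 3), each = 3) * 1e5       # light, medium, dark
    down <- rep(c(3, 2, 1), each = 3) * 1e5
    vt <- toyVolatileTable(cbind(up = up, down = down), batches = 3L)
    sel <- list(dark = "up", light = "down")
    hm <- heatmapMatrix(vt, sel)
    md <- as.data.frame(sampleData(vt))
    for (cid in c("up", "down")) {
        z <- as.numeric(scale(get(cid)))
        oracle <- tapply(z, factor(md$roast, c("light", "medium", "dark")),
                         mean)
        expect_equal(as.numeric(hm[cid, names(oracle)]),
                     as.numeric(oracle), tolerance = 1e-12)
    }
    expect_equal(names(which.max(hm["up", ])), "dark")
    expect_equal(names(which.max(hm["down", ])), "light")
    expect_identical(rownames(hm), c("up", "down"))
    expect_identical(attr(hm, "memberClass"),
                     c(up = "dark", down = "light"))
    # deterministic under recomputation
    expect_identical(hm, heatmapMatrix(vt, sel))
    expect_error(heatmapMatrix(vt, list(dark = character(0))), "empty")
})

test_that("fixture dark markers peak in the dark column of the heatmap", {
    md <- as.data.frame(sampleData(fx$volatiles))
    iE <- md$origin == "Ethiopia"
    vt <- zeroMissing(reproducibilityFilter(
        abundanceFilter(fx$volatiles[, iE], 5e4)$table, 0.8)$table)
    A <- peakAreas(vt)
    fit <- plsdaFit(A, md$roast[iE], maxLV = 6L, nSplits = 5L,
                    xScale = "autoscale")
    vid <- vidScores(vt, predict(fit$model, A))
    sel <- selectDiscriminant(vid, 0.9, signed = FALSE)
    hm <- heatmapMatrix(vt, sel)
    rd <- as.data.frame(compoundData(vt))
    darkUp <- rownames(hm)[rd[rownames(hm), "trend"] == "increasing"]
    for (cid in darkUp)
        expect_equal(names(which.max(hm[cid, ])), "dark", info = cid)
})
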
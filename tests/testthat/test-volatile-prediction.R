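# batch-level, EMSC-corrected fixture blocks used across these tests
.predFixture <- local({
    vtB <- averageReplicates(fx$volatiles)
    spB <- averageReplicates(fx$spectra)
    iE <- sampleData(spB)$origin == "Ethiopia"
    em <- emsc(spB[, iE])
    emV <- applyEMSC(em$state, spB[, !iE])
    list(spCal = em$spectra, spVal = emV$spectra,
         vtCal = vtB[, sampleData(vtB)$origin == "Ethiopia"],
         vtVal = vtB[, sampleData(vtB)$origin == "Congo"])
})

test_that("a noiseless linear response is calibrated perfectly", {
    d <- noiselessDesign()
    vt <- generateVolatileTable(d)
    sp <- generateSpectra(d, vt)
    spB <- averageReplicates(sp)
    iE <- sampleData(spB)$origin == "Ethiopia"
    X <- specMatrix(spB)[iE, ]
    y <- as.numeric(X %*% rnorm(ncol(X), 0, 0.1)) + 5
    m <- fitVolatileModel(spB[, iE], y, maxLV = 3L, nSplits = 3L)
    pred <- as.numeric(predict(m, X))
    r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    expect_gt(r2, 1 - 1e-6)
})

test_that("responses decoupled from the spectra fail validation", {
    pf <- .predFixture
    rd <- as.data.frame(compoundData(fx$volatiles))
    cid <- rownames(rd)[rd$role == "trend"][1L]
    yCal <- peakAreas(pf$vtCal)[match(rownames(specMatrix(pf$spCal)),
                                      rownames(peakAreas(pf$vtCal))), cid]
    yVal <- peakAreas(pf$vtVal)[match(rownames(specMatrix(pf$spVal)),
                                      rownames(peakAreas(pf$vtVal))), cid]
    set.seed(31)
    m <- fitVolatileModel(pf$spCal, sample(yCal), maxLV = 5L,
                          nSplits = 3L)
    val <- validateVolatileModel(m, pf$spVal, sample(yVal))
    expect_lt(val$r2, 0.5)

    # genuine signal passes under the same settings
    m2 <- fitVolatileModel(pf$spCal, yCal, maxLV = 5L, nSplits = 3L)
    val2 <- validateVolatileModel(m2, pf$spVal, yVal)
    expect_gt(val2$r2, 0.75)
})

test_that("refitting with identical inputs is deterministic", {
    pf <- .predFixture
    y <- peakAreas(pf$vtCal)[match(rownames(specMatrix(pf$spCal)),
                                   rownames(peakAreas(pf$vtCal))), 2L]
    m1 <- fitVolatileModel(pf$spCal, y)
    m2 <- fitVolatileModel(pf$spCal, y)
    expect_identical(m1@coefficients, m2@coefficients)
    expect_identical(m1@nLV, m2@nLV)
    expect_error(fitVolatileModel(pf$spCal, y, nSplits = 5L),
                 "at least 10 samples")
})

test_that("validation metrics follow their definitions", {
    obs <- c(3, 7, 1, 9, 5)
    perfect <- nirvol:::.regMetrics(obs, obs)
    expect_equal(perfect$r2, 1)
    expect_equal(perfect$nrmse, 0)
    constant <- nirvol:::.regMetrics(obs, rep(mean(obs), 5L))
    expect_equal(constant$r2, 0)
    # NRMSEP is invariant to joint affine rescaling
    pred <- obs + c(0.5, -1, 0.2, 0, 1)
    a <- nirvol:::.regMetrics(obs, pred)
    b <- nirvol:::.regMetrics(10 * obs + 3, 10 * pred + 3)
    expect_equal(a$nrmse, b$nrmse, tolerance = 1e-12)
    # zero validation range is flagged, not an error
    m <- nirvol:::.regMetrics(rep(2, 4), c(1, 2, 3, 2))
    expect_true(is.na(m$nrmse))
    # mean normalization is available and recorded
    mm <- nirvol:::.regMetrics(obs, pred, denominator = "mean")
    expect_equal(mm$denom, mean(obs))
})

test_that("reported metrics equal recomputation from saved predictions", {
    pf <- .predFixture
    rd <- as.data.frame(compoundData(fx$volatiles))
    cid <- rownames(rd)[rd$role == "trend"][2L]
    ord <- match(rownames(specMatrix(pf$spCal)),
                 rownames(peakAreas(pf$vtCal)))
    yCal <- peakAreas(pf$vtCal)[ord, cid]
    ordV <- match(rownames(specMatrix(pf$spVal)),
                  rownames(peakAreas(pf$vtVal)))
    yVal <- peakAreas(pf$vtVal)[ordV, cid]
    m <- fitVolatileModel(pf$spCal, yCal)
    val <- validateVolatileModel(m, pf$spVal, yVal)
    rmse <- sqrt(mean((yVal - val$predictions)^2))
    expect_equal(val$nrmsep, rmse / diff(range(yVal)), tolerance = 1e-12)
    expect_equal(val$r2,
                 1 - sum((yVal - val$predictions)^2) /
                     sum((yVal - mean(yVal))^2), tolerance = 1e-12)
})

test_that("screening keeps strictly-above-threshold compounds only", {
    tb <- data.frame(compound = c("a", "b", "c"), nLV = 1L,
                     r2Cal = 0.9, nrmseCal = 0.1,
                     r2Pred = c(0.92, 0.75, 0.7401),
                     nrmsep = c(0.34, 0.5, 0.6),
                     pass = c(TRUE, FALSE, FALSE))
    pm <- new("PredictionMetrics", table = tb, r2Min = 0.75,
              denominator = "range")
    sc <- screenCompounds(pm, 0.75)
    expect_identical(sc$accepted, "a")          # 0.75 exactly fails
    expect_identical(sc$report$compound, c("a", "b", "c"))
    sc2 <- screenCompounds(pm, 0.7)
    expect_identical(sort(sc2$accepted), c("a", "b", "c"))
    empty <- screenCompounds(new("PredictionMetrics",
                                 table = tb[0, ], r2Min = 0.75,
                                 denominator = "range"), 0.75)
    expect_identical(empty$accepted, character(0))
    expect_equal(nrow(empty$report), 0L)
})

test_that("per-compound metrics table mirrors the published report shape", {
    pf <- .predFixture
    rd <- as.data.frame(compoundData(fx$volatiles))
    ids <- rownames(rd)[rd$role == "trend"][1:3]
    pm <- predictVolatiles(pf$spCal, pf$vtCal, pf$spVal, pf$vtVal,
                           compounds = ids)
    expect_identical(pm@table$compound, ids)
    expect_true(all(c("nrmsep", "r2Pred", "pass") %in% names(pm@table)))
    expect_true(all(pm@table$nrmsep >= 0))
    expect_true(all(pm@table$r2Pred <= 1))
    expect_error(predictVolatiles(pf$spCal, pf$vtCal, pf$spVal, pf$vtVal,
                                  compounds = "nonexistent"), "absent")
})
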
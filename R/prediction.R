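#' Fit a per-compound PLS-R model on calibration spectra
#'
#' The LV count is chosen per compound by venetian-blinds cross-validation
#' and the parsimony rule; the response is autoscaled inside the model's
#' preprocessing state so predictions return on the raw abundance scale.
#'
#' @param spectraCal calibration [SpectraSet-class] (already scatter-
#'   corrected; typically batch-averaged and EMSC-treated)
#' @param yCal compound abundance vector aligned with the spectra
#' @param maxLV,nSplits cross-validation settings; the calibration set must
#'   hold at least `2 * nSplits` samples
#' @param selectTol parsimony tolerance for [selectNLV()]
#' @return a [PLSModel-class] with the CV summary in its `cv` slot
#' @export
fitVolatileModel <- function(spectraCal, yCal, maxLV = 5L, nSplits = 3L,
                             selectTol = 0.02) {
    X <- specMatrix(spectraCal)
    yCal <- as.numeric(yCal)
    stopifnot(length(yCal) == nrow(X))
    if (nrow(X) < 2L * nSplits)
        stop("calibration needs at least ", 2L * nSplits,
             " samples for ", nSplits, "-fold venetian blinds (got ",
             nrow(X), ")")
    Y <- matrix(yCal, ncol = 1L, dimnames = list(rownames(X), "abundance"))
    cv <- venetianBlindsCV(X, Y, maxLV = maxLV, nSplits = nSplits,
                           xScale = "center", yScale = "autoscale")
    nlv <- selectNLV(cv, selectTol)
    cv@chosenNLV <- nlv
    model <- fitPLS(X, Y, nLV = nlv, xScale = "center",
                    yScale = "autoscale")
    model@cv <- list(rmsecv = cv@rmsecv, chosenNLV = nlv,
                     nSplits = cv@splits$nSplits)
    model
}

# R2 (coefficient of determination, centered on the observed mean) and
# NRMSE (RMSE over the observed range, or mean) on the raw scale.
.regMetrics <- function(obs, pred, denominator = "range") {
    sse <- sum((obs - pred)^2)
    sst <- sum((obs - mean(obs))^2)
    r2 <- 1 - sse / sst
    denom <- switch(denominator,
                    range = diff(range(obs)),
                    mean = mean(obs),
                    stop("unknown NRMSE denominator: ", denominator))
    nrmse <- if (denom == 0) NA_real_ else sqrt(mean((obs - pred)^2)) / denom
    list(r2 = r2, nrmse = nrmse, denom = denom)
}

#' Validate a volatile model on the other origin
#'
#' Predicts the validation spectra (which must already be preprocessed with
#' the calibration states) and scores the predictions on the raw abundance
#' scale: R2pred = 1 - SSE/SST with SST centered on the validation-set mean,
#' and NRMSEP = RMSE / (max(y) - min(y)) by default.
#'
#' @param model a [PLSModel-class] from [fitVolatileModel()]
#' @param spectraVal validation [SpectraSet-class]
#' @param yVal observed abundances for the validation samples
#' @param denominator NRMSE normalization, "range" (default) or "mean"
#' @return list with `r2`, `nrmsep`, `predictions`, and `flagged` (TRUE when
#'   the validation range is zero and NRMSEP is undefined)
#' @export
validateVolatileModel <- function(model, spectraVal, yVal,
                                  denominator = "range") {
    X <- specMatrix(spectraVal)
    yVal <- as.numeric(yVal)
    stopifnot(length(yVal) == nrow(X))
    pred <- as.numeric(predict(model, X))
    m <- .regMetrics(yVal, pred, denominator)
    list(r2 = m$r2, nrmsep = m$nrmse,
         predictions = stats::setNames(pred, rownames(X)),
         flagged = is.na(m$nrmse))
}

#' Per-compound NIR-to-volatile prediction with cross-origin validation
#'
#' For every requested compound, fits a PLS-R model on the calibration
#' origin's spectra and validates it on the other origin, reporting
#' calibration R2/NRMSE and validation R2pred/NRMSEP on the raw abundance
#' scale (the shape of the published per-compound performance table).
#'
#' @param spectraCal,spectraVal calibration and validation
#'   [SpectraSet-class] objects, both preprocessed with the calibration
#'   states
#' @param volatilesCal,volatilesVal matching [VolatileTable-class] objects
#'   (samples aligned with the spectra by id)
#' @param compounds compound ids to model (default: all shared compounds)
#' @param maxLV,nSplits,selectTol per-compound CV settings
#' @param r2Min screening threshold for the pass flag
#' @param denominator NRMSE normalization, "range" or "mean"
#' @return a [PredictionMetrics-class]
#' @export
predictVolatiles <- function(spectraCal, volatilesCal, spectraVal,
                             volatilesVal,
                             compounds = rownames(volatilesCal),
                             maxLV = 5L, nSplits = 3L, selectTol = 0.02,
                             r2Min = 0.75, denominator = "range") {
    ACal <- peakAreas(volatilesCal)
    AVal <- peakAreas(volatilesVal)
    mc <- match(rownames(specMatrix(spectraCal)), rownames(ACal))
    mv <- match(rownames(specMatrix(spectraVal)), rownames(AVal))
    if (anyNA(mc) || anyNA(mv))
        stop("spectra and volatile samples do not align by id")
    missing <- setdiff(compounds, colnames(ACal))
    if (length(missing))
        stop("compound(s) absent from the volatile table: ",
             paste(missing, collapse = ", "))

    rows <- lapply(compounds, function(cid) {
        yCal <- ACal[mc, cid]
        yVal <- AVal[mv, cid]
        model <- fitVolatileModel(spectraCal, yCal, maxLV = maxLV,
                                  nSplits = nSplits,
                                  selectTol = selectTol)
        calPred <- as.numeric(predict(model, specMatrix(spectraCal)))
        cal <- .regMetrics(yCal, calPred, denominator)
        val <- validateVolatileModel(model, spectraVal, yVal, denominator)
        data.frame(compound = cid, nLV = model@nLV,
                   r2Cal = cal$r2, nrmseCal = cal$nrmse,
                   r2Pred = val$r2, nrmsep = val$nrmsep,
                   pass = !is.na(val$r2) && val$r2 > r2Min,
                   row.names = NULL)
    })
    tb <- do.call(rbind, rows)
    new("PredictionMetrics", table = tb, r2Min = r2Min,
        denominator = denominator)
}

#' Screen compounds on validation performance
#'
#' Keeps compounds whose validation R2pred lies strictly above the threshold
#' (an R2pred of exactly the threshold fails). Returns the accepted ids and
#' a report shaped like the published table (Volatile Compound, NRMSEP,
#' R2 Pred), sorted as requested.
#'
#' @param metrics a [PredictionMetrics-class]
#' @param r2Min screening threshold (study: 0.75)
#' @param sortBy order of the report: "r2Pred" (descending), "nrmsep"
#'   (ascending) or "compound"
#' @return list with `accepted` (character) and `report` (data.frame)
#' @export
screenCompounds <- function(metrics, r2Min = 0.75,
                            sortBy = c("r2Pred", "nrmsep", "compound")) {
    sortBy <- match.arg(sortBy)
    tb <- metrics@table
    if (!nrow(tb))
        return(list(accepted = character(0),
                    report = data.frame(compound = character(0),
                                        nrmsep = numeric(0),
                                        r2Pred = numeric(0))))
    tb$pass <- !is.na(tb$r2Pred) & tb$r2Pred > r2Min
    ord <- switch(sortBy,
                  r2Pred = order(-tb$r2Pred),
                  nrmsep = order(tb$nrmsep),
                  compound = order(tb$compound))
    report <- tb[ord, c("compound", "nrmsep", "r2Pred", "pass")]
    rownames(report) <- NULL
    list(accepted = tb$compound[tb$pass], report = report)
}

setMethod("show", "PredictionMetrics", function(object) {
    tb <- object@table
    cat(sprintf(
        "PredictionMetrics: %d compounds, %d passing R2pred > %.2f\n",
        nrow(tb), sum(tb$pass, na.rm = TRUE), object@r2Min))
    if (nrow(tb))
        cat(sprintf("  median validation R2 %.3f, median NRMSEP %.3f\n",
                    stats::median(tb$r2Pred, na.rm = TRUE),
                    stats::median(tb$nrmsep, na.rm = TRUE)))
})
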
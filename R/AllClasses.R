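#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.TREND_LEVELS <- c("increasing", "decreasing", "peak-at-medium", "flat")

#' Experimental design for the synthetic roast study
#'
#' Holds the layout of a two-origin, three-roast coffee study together with
#' the parameters of the volatile-abundance and spectral measurement models.
#' The defaults reproduce the scale of the real study: 2 origins x 3 roasts x
#' 3 batch replicates, 9 GC-MS readings and 27 NIR readings per roast level,
#' and 166 volatile compounds.
#'
#' @slot origins character, origin labels (first origin carries no spectral
#'   origin shift).
#' @slot roasts character, roast labels in trend order (light < medium < dark).
#' @slot batchReps integer, roasting batch replicates per origin x roast.
#' @slot gcmsReadingsPerBatch integer, GC-MS analytical readings per batch.
#' @slot nirReadingsPerBatch integer, NIR analytical readings per batch.
#' @slot nCompounds integer, number of volatile compounds.
#' @slot classTrends data.frame with columns `class`, `trend`
#'   (one of increasing, decreasing, peak-at-medium, flat) and `effect`
#'   (log-abundance span of the trend).
#' @slot noiseCV numeric, coefficient of variation of multiplicative
#'   (lognormal) replicate noise on peak areas.
#' @slot batchSD numeric, SD of the per-batch random effect on log abundance.
#' @slot flatFraction numeric, fraction of compounds with no roast trend.
#' @slot irregularFraction numeric, fraction of compounds whose areas all sit
#'   below `abundanceFloor` (fodder for the abundance filter).
#' @slot sparseFraction numeric, fraction of compounds detected in fewer than
#'   80\% of readings in every replicate group (fodder for the
#'   reproducibility filter).
#' @slot abundanceFloor numeric, area floor used for irregular compounds.
#' @slot latentRank integer, rank of the volatile-to-spectrum mixing.
#' @slot originShift numeric, SD of the additive band-weight shift applied to
#'   origins after the first.
#' @slot scatterSD numeric, SD of log multiplicative scatter factors b.
#' @slot baselineSD numeric length 3, SDs of the polynomial baseline
#'   coefficients (constant, linear, quadratic in the rescaled wavelength).
#' @slot spectralNoiseSD numeric, SD of iid absorbance noise per wavelength.
#' @slot wavelengths numeric, strictly increasing wavelength grid in nm.
#' @slot seed integer, RNG seed; identical seeds give bitwise-identical data.
#'
#' @seealso [roastDesign()], [generateVolatileTable()], [generateSpectra()]
#' @export
setClass("RoastDesign",
    representation(
        origins = "character",
        roasts = "character",
        batchReps = "integer",
        gcmsReadingsPerBatch = "integer",
        nirReadingsPerBatch = "integer",
        nCompounds = "integer",
        classTrends = "data.frame",
        noiseCV = "numeric",
        batchSD = "numeric",
        flatFraction = "numeric",
        irregularFraction = "numeric",
        sparseFraction = "numeric",
        abundanceFloor = "numeric",
        latentRank = "integer",
        originShift = "numeric",
        scatterSD = "numeric",
        baselineSD = "numeric",
        spectralNoiseSD = "numeric",
        wavelengths = "numeric",
        seed = "integer"
    )
)

setValidity("RoastDesign", function(object) {
    msg <- character()
    counts <- c(object@batchReps, object@gcmsReadingsPerBatch,
                object@nirReadingsPerBatch, object@nCompounds,
                object@latentRank)
    if (any(counts < 1L))
        msg <- c(msg, "all design counts must be >= 1")
    if (length(object@roasts) < 2L || anyDuplicated(object@roasts))
        msg <- c(msg, "roasts must be >= 2 distinct ordered labels")
    if (length(object@origins) < 1L || anyDuplicated(object@origins))
        msg <- c(msg, "origins must be distinct labels")
    if (object@noiseCV < 0 || object@batchSD < 0)
        msg <- c(msg, "noiseCV and batchSD must be >= 0")
    ct <- object@classTrends
    if (!all(c("class", "trend", "effect") %in% names(ct))) {
        msg <- c(msg, "classTrends needs columns class, trend, effect")
    } else {
        bad <- !(ct$trend %in% .TREND_LEVELS)
        if (any(bad))
            msg <- c(msg, sprintf(
                "invalid trend label for class '%s' (must be one of %s)",
                ct$class[bad][1L], paste(.TREND_LEVELS, collapse = ", ")))
    }
    fr <- c(object@flatFraction, object@irregularFraction,
            object@sparseFraction)
    if (any(fr < 0) || sum(fr) > 1)
        msg <- c(msg, "compound-role fractions must be >= 0 and sum to <= 1")
    if (length(object@baselineSD) != 3L || any(object@baselineSD < 0))
        msg <- c(msg, "baselineSD must be 3 nonnegative values")
    wl <- object@wavelengths
    if (length(wl) < 2L || any(diff(wl) <= 0))
        msg <- c(msg, "wavelengths must be a strictly increasing grid")
    if (length(msg)) msg else TRUE
})

#' Container for NIR spectra
#'
#' A [SummarizedExperiment::SummarizedExperiment] with wavelengths as rows
#' (rowData column `wavelength`, nm) and samples as columns (colData carries
#' `origin`, `roast`, `batch`, `reading`). Use [specMatrix()] for the
#' sample-by-wavelength X block that the chemometric models consume.
#'
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
    msg <- character()
    wl <- rowData(object)$wavelength
    if (is.null(wl))
        return("rowData must contain a 'wavelength' column")
    if (any(diff(wl) <= 0))
        msg <- c(msg, "wavelengths must be strictly increasing")
    a <- assay(object)
    if (anyNA(a))
        msg <- c(msg, "absorbance matrix must not contain missing values")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample ids")
    if (length(msg)) msg else TRUE
})

#' Container for GC-MS volatile peak-area tables
#'
#' A [SummarizedExperiment::SummarizedExperiment] with compounds as rows
#' (rowData carries `compoundClass` and, for synthetic data, the planted
#' `trend` and `role`) and samples as columns. Areas are nonnegative,
#' arbitrary-unit peak areas; missing values are allowed (absent peaks).
#' Use [peakAreas()] for the sample-by-compound matrix.
#'
#' @export
setClass("VolatileTable", contains = "SummarizedExperiment")

setValidity("VolatileTable", function(object) {
    msg <- character()
    a <- assay(object)
    if (any(a < 0, na.rm = TRUE))
        msg <- c(msg, "peak areas must be >= 0 or missing")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample ids")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicated compound ids")
    if (length(msg)) msg else TRUE
})

#' Column scaling state (autoscaling)
#'
#' Per-column mean and standard deviation captured when autoscaling a
#' calibration matrix, so the identical transform can be applied to new data
#' and predictions can be mapped back to the raw scale.
#'
#' @slot center numeric, per-column means.
#' @slot scale numeric, per-column standard deviations (n-1 denominator).
#' @export
setClass("ScalingState",
    representation(center = "numeric", scale = "numeric"))

setValidity("ScalingState", function(object) {
    if (length(object@center) != length(object@scale))
        return("center and scale lengths differ")
    if (any(object@scale <= 0))
        return("standard deviations must be > 0 for retained columns")
    TRUE
})

#' EMSC correction state
#'
#' @slot reference numeric, reference spectrum on the model grid.
#' @slot wavelengths numeric, the wavelength grid the state was fitted on.
#' @slot polyOrder integer, polynomial baseline order (0, 1 or 2).
#' @slot b numeric, fitted multiplicative coefficient per sample.
#' @slot baseline matrix, (polyOrder + 1) x samples polynomial coefficients.
#' @export
setClass("EMSCState",
    representation(
        reference = "numeric",
        wavelengths = "numeric",
        polyOrder = "integer",
        b = "numeric",
        baseline = "matrix"
    )
)

setValidity("EMSCState", function(object) {
    msg <- character()
    if (anyNA(object@reference))
        msg <- c(msg, "reference spectrum must not contain missing values")
    if (!object@polyOrder %in% 0:2)
        msg <- c(msg, "polyOrder must be 0, 1 or 2")
    if (length(object@b) && any(abs(object@b) < 1e-8))
        msg <- c(msg, "multiplicative coefficient b must be nonzero")
    if (length(msg)) msg else TRUE
})

#' Fitted PLS model (NIPALS)
#'
#' Latent-variable regression state: X-weights W, X-loadings P, Y-loadings Q,
#' training scores T, and the regression coefficient matrix B computed as
#' W (P'W)^-1 Q'. Preprocessing (centering/scaling of X and Y) is captured at
#' fit time so [predict()] accepts raw-scale inputs and returns raw-scale
#' predictions.
#'
#' @slot nLV integer, number of latent variables extracted.
#' @slot weights matrix, X-weights W (features x LV, unit norm columns).
#' @slot xLoadings matrix, X-loadings P (features x LV).
#' @slot yLoadings matrix, Y-loadings Q (responses x LV).
#' @slot scores matrix, training X-scores T (samples x LV).
#' @slot coefficients matrix, regression coefficients B (features x responses)
#'   on the preprocessed scale.
#' @slot xCenter,xScale numeric, X preprocessing state.
#' @slot yCenter,yScale numeric, Y preprocessing state.
#' @slot responseKind character, "continuous" or "class-dummy".
#' @slot classLevels character, class labels for discriminant models.
#' @slot featureNames character, expected X column names.
#' @slot responseNames character, response column names.
#' @slot explainedX,explainedY numeric, per-LV explained variance fractions.
#' @slot cv list, optional cross-validation summary attached by the fitting
#'   wrappers.
#' @export
setClass("PLSModel",
    representation(
        nLV = "integer",
        weights = "matrix",
        xLoadings = "matrix",
        yLoadings = "matrix",
        scores = "matrix",
        coefficients = "matrix",
        xCenter = "numeric",
        xScale = "numeric",
        yCenter = "numeric",
        yScale = "numeric",
        responseKind = "character",
        classLevels = "character",
        featureNames = "character",
        responseNames = "character",
        explainedX = "numeric",
        explainedY = "numeric",
        cv = "list"
    )
)

setValidity("PLSModel", function(object) {
    msg <- character()
    a <- object@nLV
    if (ncol(object@weights) != a || ncol(object@xLoadings) != a ||
        ncol(object@yLoadings) != a || ncol(object@scores) != a)
        msg <- c(msg, "latent-variable dimensions inconsistent")
    if (nrow(object@coefficients) != nrow(object@weights) ||
        ncol(object@coefficients) != nrow(object@yLoadings))
        msg <- c(msg, "coefficient matrix dimensions inconsistent")
    if (!object@responseKind %in% c("continuous", "class-dummy"))
        msg <- c(msg, "responseKind must be 'continuous' or 'class-dummy'")
    if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' @slot rmsecv numeric, pooled root mean squared error of cross-validation
#'   per candidate LV count (raw response scale).
#' @slot classError numeric, cross-validated misclassification rate per LV
#'   count (length 0 for continuous responses).
#' @slot explainedX,explainedY numeric, per-LV explained variance of the
#'   full-data fit.
#' @slot chosenNLV integer, LV count chosen by the parsimony rule.
#' @slot splits list, split descriptor: number of splits, fold assignment,
#'   warnings (e.g. folds losing a class), and the array of held-out
#'   predictions per LV count.
#' @export
setClass("CVResult",
    representation(
        rmsecv = "numeric",
        classError = "numeric",
        explainedX = "numeric",
        explainedY = "numeric",
        chosenNLV = "integer",
        splits = "list"
    )
)

setValidity("CVResult", function(object) {
    if (length(object@chosenNLV) == 1L && !is.na(object@chosenNLV) &&
        (object@chosenNLV < 1L || object@chosenNLV > length(object@rmsecv)))
        return("chosen nLV outside candidate range")
    TRUE
})

#' Classification performance metrics
#'
#' Per-class one-vs-rest sensitivity and specificity, overall accuracy,
#' classification error (mean over classes of the balanced error rate), the
#' coefficient of determination of the dummy-response fit, and the confusion
#' matrix.
#'
#' @export
setClass("ClassMetrics",
    representation(
        confusion = "matrix",
        sensitivity = "numeric",
        specificity = "numeric",
        accuracy = "numeric",
        classError = "numeric",
        r2 = "numeric"
    )
)

setValidity("ClassMetrics", function(object) {
    msg <- character()
    sens <- object@sensitivity[!is.na(object@sensitivity)]
    spec <- object@specificity[!is.na(object@specificity)]
    if (any(sens < 0 | sens > 1) || any(spec < 0 | spec > 1))
        msg <- c(msg, "sensitivity/specificity must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' VID (variable identification) result
#'
#' Per-compound, per-class Pearson correlations between volatile abundance
#' and the PLS-DA-predicted class membership, in [-1, 1]. Zero-variance
#' compounds are flagged rather than assigned a coefficient.
#'
#' @slot coefficients matrix, compounds x classes.
#' @slot thresholds numeric, thresholds used by the last selection call.
#' @slot selected list, per-class compound id vectors (descending |VID|).
#' @slot undefined character, compound ids with zero abundance variance.
#' @export
setClass("VIDResult",
    representation(
        coefficients = "matrix",
        thresholds = "numeric",
        selected = "list",
        undefined = "character"
    )
)

setValidity("VIDResult", function(object) {
    cc <- object@coefficients
    if (any(abs(cc) > 1 + 1e-12, na.rm = TRUE))
        return("VID coefficients must lie in [-1, 1]")
    TRUE
})

#' Per-compound prediction performance
#'
#' Mirrors the published report shape: one row per volatile compound with the
#' chosen LV count, calibration R-squared and NRMSE, validation (prediction)
#' R-squared and NRMSEP, and a pass flag for the screening rule
#' (validation R-squared strictly above the threshold).
#'
#' @slot table data.frame with columns compound, nLV, r2Cal, nrmseCal,
#'   r2Pred, nrmsep, pass.
#' @slot r2Min numeric, screening threshold.
#' @slot denominator character, NRMSE normalization ("range" or "mean").
#' @export
setClass("PredictionMetrics",
    representation(
        table = "data.frame",
        r2Min = "numeric",
        denominator = "character"
    )
)

setValidity("PredictionMetrics", function(object) {
    tb <- object@table
    need <- c("compound", "nLV", "r2Cal", "nrmseCal", "r2Pred", "nrmsep",
              "pass")
    if (!all(need %in% names(tb)))
        return(paste("table needs columns", paste(need, collapse = ", ")))
    if (any(tb$r2Pred > 1 + 1e-12, na.rm = TRUE))
        return("R-squared cannot exceed 1")
    if (any(c(tb$nrmseCal, tb$nrmsep) < 0, na.rm = TRUE))
        return("NRMSE values must be >= 0")
    ok <- !is.na(tb$r2Pred)
    if (length(object@r2Min) == 1L &&
        !identical(tb$pass[ok], tb$r2Pred[ok] > object@r2Min))
        return("pass flag must equal (validation R-squared > r2Min)")
    TRUE
})

#' End-to-end pipeline configuration
#'
#' Aggregates the study's analysis settings: quality-filter thresholds,
#' VID selection thresholds, the prediction screening rule, cross-validation
#' settings for the classification and prediction stages, preprocessing
#' flags, origins, output directory and seed.
#'
#' @export
setClass("PipelineConfig",
    representation(
        design = "RoastDesign",
        abundanceThreshold = "numeric",
        minFraction = "numeric",
        vidMarkerThreshold = "numeric",
        vidHeatmapThreshold = "numeric",
        r2Min = "numeric",
        maxLV = "integer",
        nSplits = "integer",
        predMaxLV = "integer",
        predNSplits = "integer",
        polyOrder = "integer",
        averageBy = "character",
        cropRange = "numeric",
        calibrationOrigin = "character",
        validationOrigin = "character",
        outDir = "character",
        seed = "integer"
    )
)

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (object@abundanceThreshold < 0)
        msg <- c(msg, "abundanceThreshold must be >= 0")
    if (object@minFraction <= 0 || object@minFraction > 1)
        msg <- c(msg, "minFraction must lie in (0, 1]")
    thr <- c(object@vidMarkerThreshold, object@vidHeatmapThreshold)
    if (any(thr <= 0 | thr > 1))
        msg <- c(msg, "VID thresholds must lie in (0, 1]")
    if (object@r2Min < 0 || object@r2Min > 1)
        msg <- c(msg, "r2Min must lie in [0, 1]")
    if (any(c(object@maxLV, object@nSplits, object@predMaxLV,
              object@predNSplits) < 1L))
        msg <- c(msg, "CV settings must be >= 1")
    if (!object@polyOrder %in% 0:2)
        msg <- c(msg, "polyOrder must be 0, 1 or 2")
    if (!object@averageBy %in% c("batch", "none"))
        msg <- c(msg, "averageBy must be 'batch' or 'none'")
    if (length(object@cropRange) && length(object@cropRange) != 2L)
        msg <- c(msg, "cropRange must be empty or c(lower, upper)")
    if (length(msg)) msg else TRUE
})
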
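#' Build a pipeline configuration
#'
#' Aggregates the study's analysis settings as defaults: abundance filter at
#' 50,000 area units, reproducibility rule at 80 percent, VID marker
#' threshold 0.8 (signed) and heatmap threshold |0.9|, screening at
#' validation R2 > 0.75, venetian-blinds CV, EMSC with order-2 baseline,
#' batch averaging of analytical replicates, and Ethiopia-to-Congo
#' calibration/validation.
#'
#' @param design a [RoastDesign-class] used when inputs must be simulated
#' @param abundanceThreshold,minFraction GC-MS quality-filter settings
#' @param vidMarkerThreshold,vidHeatmapThreshold VID selection thresholds
#' @param r2Min prediction screening threshold
#' @param maxLV,nSplits classification-stage CV settings
#' @param predMaxLV,predNSplits prediction-stage CV settings (batch-level
#'   calibration sets are small, hence fewer folds)
#' @param polyOrder EMSC polynomial order
#' @param averageBy "batch" to average analytical replicates, "none" to
#'   model every reading
#' @param cropRange optional c(lower, upper) wavelength window in nm
#' @param calibrationOrigin,validationOrigin origins for the prediction
#'   stage
#' @param outDir directory for serialized intermediates and reports
#' @param seed master seed; all pipeline randomness flows from it
#' @return a [PipelineConfig-class]
#' @export
pipelineConfig <- function(design = roastDesign(),
                           abundanceThreshold = 5e4,
                           minFraction = 0.8,
                           vidMarkerThreshold = 0.8,
                           vidHeatmapThreshold = 0.9,
                           r2Min = 0.75,
                           maxLV = 10L, nSplits = 5L,
                           predMaxLV = 5L, predNSplits = 3L,
                           polyOrder = 2L,
                           averageBy = "batch",
                           cropRange = numeric(0),
                           calibrationOrigin = design@origins[1L],
                           validationOrigin = design@origins[min(2L,
                               length(design@origins))],
                           outDir = tempfile("nirvol_run_"),
                           seed = 1L) {
    new("PipelineConfig", design = design,
        abundanceThreshold = abundanceThreshold,
        minFraction = minFraction,
        vidMarkerThreshold = vidMarkerThreshold,
        vidHeatmapThreshold = vidHeatmapThreshold,
        r2Min = r2Min,
        maxLV = as.integer(maxLV), nSplits = as.integer(nSplits),
        predMaxLV = as.integer(predMaxLV),
        predNSplits = as.integer(predNSplits),
        polyOrder = as.integer(polyOrder),
        averageBy = averageBy, cropRange = as.numeric(cropRange),
        calibrationOrigin = calibrationOrigin,
        validationOrigin = validationOrigin,
        outDir = outDir, seed = as.integer(seed))
}

#' Serialize / restore a pipeline configuration (JSON)
#'
#' Configurations round-trip unchanged, including the embedded design.
#'
#' @param config a [PipelineConfig-class]
#' @param file path
#' @name config-io
#' @export
writePipelineConfig <- function(config, file) {
    d <- config@design
    jsonlite::write_json(list(
        design = list(
            origins = d@origins, roasts = d@roasts,
            batchReps = d@batchReps,
            gcmsReadingsPerBatch = d@gcmsReadingsPerBatch,
            nirReadingsPerBatch = d@nirReadingsPerBatch,
            nCompounds = d@nCompounds, classTrends = d@classTrends,
            noiseCV = d@noiseCV, batchSD = d@batchSD,
            flatFraction = d@flatFraction,
            irregularFraction = d@irregularFraction,
            sparseFraction = d@sparseFraction,
            abundanceFloor = d@abundanceFloor,
            latentRank = d@latentRank, originShift = d@originShift,
            scatterSD = d@scatterSD, baselineSD = d@baselineSD,
            spectralNoiseSD = d@spectralNoiseSD,
            wavelengths = d@wavelengths, seed = d@seed),
        abundanceThreshold = config@abundanceThreshold,
        minFraction = config@minFraction,
        vidMarkerThreshold = config@vidMarkerThreshold,
        vidHeatmapThreshold = config@vidHeatmapThreshold,
        r2Min = config@r2Min, maxLV = config@maxLV,
        nSplits = config@nSplits, predMaxLV = config@predMaxLV,
        predNSplits = config@predNSplits, polyOrder = config@polyOrder,
        averageBy = config@averageBy, cropRange = config@cropRange,
        calibrationOrigin = config@calibrationOrigin,
        validationOrigin = config@validationOrigin,
        outDir = config@outDir, seed = config@seed),
        file, digits = NA, auto_unbox = TRUE)
    invisible(file)
}

#' @rdname config-io
#' @export
readPipelineConfig <- function(file) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    d <- x$design
    design <- roastDesign(
        origins = d$origins, roasts = d$roasts, batchReps = d$batchReps,
        gcmsReadingsPerBatch = d$gcmsReadingsPerBatch,
        nirReadingsPerBatch = d$nirReadingsPerBatch,
        nCompounds = d$nCompounds,
        classTrends = as.data.frame(d$classTrends),
        noiseCV = d$noiseCV, batchSD = d$batchSD,
        flatFraction = d$flatFraction,
        irregularFraction = d$irregularFraction,
        sparseFraction = d$sparseFraction,
        abundanceFloor = d$abundanceFloor, latentRank = d$latentRank,
        originShift = d$originShift, scatterSD = d$scatterSD,
        baselineSD = d$baselineSD, spectralNoiseSD = d$spectralNoiseSD,
        wavelengths = d$wavelengths, seed = d$seed)
    pipelineConfig(design = design,
        abundanceThreshold = x$abundanceThreshold,
        minFraction = x$minFraction,
        vidMarkerThreshold = x$vidMarkerThreshold,
        vidHeatmapThreshold = x$vidHeatmapThreshold,
        r2Min = x$r2Min, maxLV = x$maxLV, nSplits = x$nSplits,
        predMaxLV = x$predMaxLV, predNSplits = x$predNSplits,
        polyOrder = x$polyOrder, averageBy = x$averageBy,
        cropRange = as.numeric(x$cropRange %||% numeric(0)),
        calibrationOrigin = x$calibrationOrigin,
        validationOrigin = x$validationOrigin,
        outDir = x$outDir, seed = x$seed)
}

.writeTable <- function(df, dir, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.subsetOrigin <- function(x, origin) {
    keep <- colData(x)$origin == origin
    if (!any(keep)) stop("no samples for origin '", origin, "'")
    x[, keep]
}

#' Run the classification stage
#'
#' Executes the GC-MS branch (abundance filter, reproducibility filter,
#' autoscaled PCA and PLS-DA, VID selection, heatmap matrix) and the NIR
#' branch (replicate averaging, EMSC, mean-centered PLS-DA, LV1 loadings)
#' separately per origin, writing score tables, loadings, cross-validated
#' metrics, VID tables, drop logs and a config echo to `config@outDir`.
#' When `volatiles`/`spectra` are NULL they are simulated from the config's
#' design with the config's seed.
#'
#' @param config a [PipelineConfig-class]
#' @param volatiles optional [VolatileTable-class]
#' @param spectra optional [SpectraSet-class]
#' @return (invisibly) a per-origin list of stage results: filtered tables,
#'   fitted models, CV results, cross-validated [ClassMetrics-class], VID
#'   results, selections and heatmap matrices
#' @export
runClassification <- function(config, volatiles = NULL, spectra = NULL) {
    validObject(config)
    design <- config@design
    design@seed <- config@seed
    if (is.null(volatiles)) volatiles <- generateVolatileTable(design)
    if (is.null(spectra)) spectra <- generateSpectra(design, volatiles)
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    writePipelineConfig(config, file.path(config@outDir, "config.json"))

    origins <- unique(as.character(colData(volatiles)$origin))
    bundle <- list()
    for (org in origins) {
        vt <- .subsetOrigin(volatiles, org)
        af <- abundanceFilter(vt, config@abundanceThreshold)
        rf <- reproducibilityFilter(af$table, config@minFraction)
        filtered <- zeroMissing(rf$table)
        writeLines(c(sprintf("# dropped by abundance filter (< %g):",
                             config@abundanceThreshold),
                     af$dropped,
                     sprintf("# dropped by reproducibility filter (< %g):",
                             config@minFraction),
                     rf$dropped),
                   file.path(config@outDir,
                             sprintf("gcms_drop_log_%s.txt", org)))

        Xv <- peakAreas(filtered)
        scaled <- autoscale(Xv)
        pcaRes <- pca(scaled$scaled, nPC = min(3L, dim(Xv) - 1L))
        roast <- as.character(colData(filtered)$roast)
        gfit <- plsdaFit(Xv, roast, maxLV = config@maxLV,
                         nSplits = config@nSplits, xScale = "autoscale")
        gMetrics <- .cvMetrics(gfit, roast)
        .writeTable(data.frame(sample_id = rownames(pcaRes$scores),
                               pcaRes$scores,
                               roast = roast, row.names = NULL),
                    config@outDir, sprintf("gcms_pca_scores_%s.tsv", org))
        .writeTable(data.frame(sample_id = rownames(gfit$model@scores),
                               gfit$model@scores, roast = roast,
                               row.names = NULL),
                    config@outDir, sprintf("gcms_plsda_scores_%s.tsv", org))
        .writeTable(.classMetricsTable(gMetrics), config@outDir,
                    sprintf("gcms_plsda_metrics_%s.tsv", org))

        yhatCal <- predict(gfit$model, Xv)
        vid <- vidScores(filtered, yhatCal)
        markers <- selectDiscriminant(vid, config@vidMarkerThreshold,
                                      signed = TRUE)
        heatSel <- selectDiscriminant(vid, config@vidHeatmapThreshold,
                                      signed = FALSE)
        .writeTable(vidTable(attr(markers, "vid")), config@outDir,
                    sprintf("vid_%s.tsv", org))
        hm <- NULL
        if (any(lengths(heatSel))) {
            hm <- heatmapMatrix(filtered, heatSel)
            .writeTable(data.frame(compound = rownames(hm),
                                   memberClass = attr(hm, "memberClass"),
                                   hm, row.names = NULL),
                        config@outDir, sprintf("heatmap_%s.tsv", org))
        }

        sp <- .subsetOrigin(spectra, org)
        if (length(config@cropRange) == 2L)
            sp <- cropWavelengths(sp, config@cropRange[1L],
                                  config@cropRange[2L])
        if (config@averageBy == "batch")
            sp <- averageReplicates(sp, c("origin", "roast", "batch"))
        em <- emsc(sp, "mean", config@polyOrder)
        Xs <- specMatrix(em$spectra)
        roastS <- as.character(colData(em$spectra)$roast)
        nfit <- plsdaFit(Xs, roastS, maxLV = config@maxLV,
                         nSplits = config@nSplits, xScale = "center")
        nMetrics <- .cvMetrics(nfit, roastS)
        .writeTable(.classMetricsTable(nMetrics), config@outDir,
                    sprintf("nir_plsda_metrics_%s.tsv", org))
        .writeTable(data.frame(wavelength = wavelengths(em$spectra),
                               loadingLV1 = nfit$model@xLoadings[, 1L],
                               weightLV1 = nfit$model@weights[, 1L],
                               row.names = NULL),
                    config@outDir, sprintf("nir_lv1_loadings_%s.tsv", org))
        .writeTable(data.frame(sample_id = rownames(nfit$model@scores),
                               nfit$model@scores, roast = roastS,
                               row.names = NULL),
                    config@outDir, sprintf("nir_plsda_scores_%s.tsv", org))

        bundle[[org]] <- list(
            filtered = filtered,
            droppedAbundance = af$dropped, droppedRepro = rf$dropped,
            pca = pcaRes, gcmsFit = gfit, gcmsMetrics = gMetrics,
            vid = attr(markers, "vid"), markers = markers,
            heatmapSelection = heatSel, heatmap = hm,
            emscState = em$state, nirSpectra = em$spectra,
            nirFit = nfit, nirMetrics = nMetrics)
    }
    bundle$inputs <- list(volatiles = volatiles, spectra = spectra)
    invisible(bundle)
}

# Cross-validated metrics at the chosen LV count.
.cvMetrics <- function(fit, truth) {
    cv <- fit$cv
    preds <- cv@splits$predictions[, , cv@chosenNLV]
    assigned <- plsdaAssign(preds, classLevels = fit$model@classLevels)
    classificationMetrics(truth, assigned, preds)
}

#' Run the prediction stage
#'
#' Requires classification outputs (the calibration origin's VID table under
#' `config@outDir`, or an in-memory bundle). Collapses spectra and volatile
#' tables to batch level, corrects calibration spectra by EMSC and applies
#' the stored state to the validation origin, fits one PLS-R model per
#' VID-selected compound on the calibration origin, validates on the other
#' origin, and writes the per-compound performance report and pass list.
#'
#' @param config a [PipelineConfig-class]
#' @param bundle optional result of [runClassification()] (avoids re-reading
#'   from disk); its inputs are reused
#' @param volatiles,spectra optional inputs when `bundle` is NULL; the VID
#'   table is then read from `config@outDir`
#' @return (invisibly) list with `metrics` ([PredictionMetrics-class]),
#'   `screen` (accepted ids + report), `compounds` (the modelled ids) and
#'   the batch-level objects used
#' @export
runPrediction <- function(config, bundle = NULL, volatiles = NULL,
                          spectra = NULL) {
    validObject(config)
    calOrg <- config@calibrationOrigin
    valOrg <- config@validationOrigin
    if (!is.null(bundle)) {
        volatiles <- bundle$inputs$volatiles
        spectra <- bundle$inputs$spectra
        markers <- bundle[[calOrg]]$markers
    } else {
        vidPath <- file.path(config@outDir,
                             sprintf("vid_%s.tsv", calOrg))
        if (is.null(volatiles) || is.null(spectra))
            stop("runPrediction needs the input tables (or a bundle)")
        if (!file.exists(vidPath))
            stop("no VID table at ", vidPath,
                 "; run the classification stage first")
        vt <- utils::read.delim(vidPath)
        markers <- split(vt$compound[vt$selected], vt$class[vt$selected])
    }
    compounds <- unique(unlist(markers, use.names = FALSE))
    if (!length(compounds))
        stop("no VID-selected compounds to model")

    vtB <- averageReplicates(volatiles, c("origin", "roast", "batch"))
    spB <- averageReplicates(spectra, c("origin", "roast", "batch"))
    spCal <- .subsetOrigin(spB, calOrg)
    spVal <- .subsetOrigin(spB, valOrg)
    vtCal <- .subsetOrigin(vtB, calOrg)
    vtVal <- .subsetOrigin(vtB, valOrg)
    em <- emsc(spCal, "mean", config@polyOrder)
    emVal <- applyEMSC(em$state, spVal)

    compounds <- intersect(compounds, rownames(vtCal))
    metrics <- predictVolatiles(em$spectra, vtCal, emVal$spectra, vtVal,
                                compounds = compounds,
                                maxLV = config@predMaxLV,
                                nSplits = config@predNSplits,
                                r2Min = config@r2Min)
    screen <- screenCompounds(metrics, config@r2Min)
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    .writeTable(metrics@table, config@outDir, "prediction_metrics.tsv")
    .writeTable(screen$report, config@outDir, "prediction_report.tsv")
    writeLines(screen$accepted,
               file.path(config@outDir, "prediction_pass_list.txt"))
    invisible(list(metrics = metrics, screen = screen,
                   compounds = compounds,
                   spectraCal = em$spectra, spectraVal = emVal$spectra,
                   volatilesCal = vtCal, volatilesVal = vtVal))
}
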
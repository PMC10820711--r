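#' Default roast trends by chemical class
#'
#' The classes and directions follow the known behaviour of roasting
#' chemistry: Maillard/caramelization products (furans, ketones, phenols,
#' pyrroles, esters, pyridines, pyranones, acids, alcohols) accumulate
#' towards dark roasts; imidazoles peak at medium roast; green-bean volatiles
#' (alkanes, aldehydes, alkadienes) are highest in light roasts; an "other"
#' class is trend-free. `effect` is the log-abundance span of the trend
#' across the roast order.
#'
#' @return data.frame with columns `class`, `trend`, `effect`
#' @export
defaultClassTrends <- function() {
    data.frame(
        class = c("furans", "ketones", "phenols", "pyrroles", "esters",
                  "pyridines", "pyranones", "acids", "alcohols",
                  "imidazoles", "alkanes", "aldehydes", "alkadienes",
                  "other"),
        trend = c(rep("increasing", 9L), "peak-at-medium",
                  rep("decreasing", 3L), "flat"),
        effect = c(rep(1.0, 9L), 1.2, rep(1.0, 3L), 0),
        stringsAsFactors = FALSE
    )
}

#' Create a RoastDesign
#'
#' Defaults reproduce the real study's layout: 2 origins x 3 roasts x 3 batch
#' replicates; 3 GC-MS readings per batch (nine per roast level) and 9 NIR
#' readings per batch (27 per roast level, 162 spectra in total); 166
#' volatile compounds; wavelength grid 400-2500 nm at 2 nm.
#'
#' @param origins,roasts,batchReps,gcmsReadingsPerBatch,nirReadingsPerBatch
#'   study layout; roasts must be in trend order (light < medium < dark).
#' @param nCompounds number of volatile compounds.
#' @param classTrends data.frame mapping compound class to roast trend and
#'   effect size; see [defaultClassTrends()].
#' @param noiseCV coefficient of variation of lognormal replicate noise on
#'   peak areas.
#' @param batchSD SD of the per-batch random effect on log abundance.
#' @param flatFraction fraction of compounds with no roast trend.
#' @param irregularFraction fraction of compounds whose areas all fall below
#'   `abundanceFloor` (removed by the abundance filter).
#' @param sparseFraction fraction of compounds detected in under 80 percent
#'   of readings in every replicate group (removed by the reproducibility
#'   filter).
#' @param abundanceFloor area floor for irregular compounds (the filter
#'   threshold of the real study).
#' @param latentRank rank of the volatile-to-spectrum mixing.
#' @param originShift SD of the additive band-weight shift for origins after
#'   the first (mild, so cross-origin transfer remains possible).
#' @param scatterSD SD of the log multiplicative scatter factor b.
#' @param baselineSD SDs of the polynomial baseline coefficients
#'   (constant, linear, quadratic).
#' @param spectralNoiseSD SD of iid absorbance noise per wavelength.
#' @param wavelengths wavelength grid in nm.
#' @param seed RNG seed.
#' @return a [RoastDesign-class]
#' @export
roastDesign <- function(origins = c("Ethiopia", "Congo"),
                        roasts = c("light", "medium", "dark"),
                        batchReps = 3L,
                        gcmsReadingsPerBatch = 3L,
                        nirReadingsPerBatch = 9L,
                        nCompounds = 166L,
                        classTrends = defaultClassTrends(),
                        noiseCV = 0.08,
                        batchSD = 0.03,
                        flatFraction = 0.20,
                        irregularFraction = 0.05,
                        sparseFraction = 0.05,
                        abundanceFloor = 5e4,
                        latentRank = 3L,
                        originShift = 2e-4,
                        scatterSD = 0.05,
                        baselineSD = c(0.02, 0.01, 0.005),
                        spectralNoiseSD = 5e-4,
                        wavelengths = seq(400, 2500, by = 2),
                        seed = 1L) {
    new("RoastDesign",
        origins = origins, roasts = roasts,
        batchReps = as.integer(batchReps),
        gcmsReadingsPerBatch = as.integer(gcmsReadingsPerBatch),
        nirReadingsPerBatch = as.integer(nirReadingsPerBatch),
        nCompounds = as.integer(nCompounds),
        classTrends = classTrends,
        noiseCV = noiseCV, batchSD = batchSD,
        flatFraction = flatFraction,
        irregularFraction = irregularFraction,
        sparseFraction = sparseFraction,
        abundanceFloor = abundanceFloor,
        latentRank = as.integer(latentRank),
        originShift = originShift, scatterSD = scatterSD,
        baselineSD = baselineSD, spectralNoiseSD = spectralNoiseSD,
        wavelengths = as.numeric(wavelengths),
        seed = as.integer(seed))
}

setMethod("show", "RoastDesign", function(object) {
    cat(sprintf(
        "RoastDesign: %d origins x %d roasts x %d batches; %d compounds\n",
        length(object@origins), length(object@roasts), object@batchReps,
        object@nCompounds))
    cat(sprintf("  GC-MS readings/batch: %d; NIR readings/batch: %d\n",
                object@gcmsReadingsPerBatch, object@nirReadingsPerBatch))
    cat(sprintf("  noiseCV %.2f, batchSD %.2f, latent rank %d, seed %d\n",
                object@noiseCV, object@batchSD, object@latentRank,
                object@seed))
})

# Sample layout tables. Order is origin-slowest, then roast, batch, reading,
# which is the stored sample order all venetian-blinds splits refer to.
.sampleLayout <- function(design, readingsPerBatch) {
    g <- expand.grid(reading = seq_len(readingsPerBatch),
                     batch = seq_len(design@batchReps),
                     roast = design@roasts,
                     origin = design@origins,
                     stringsAsFactors = FALSE)
    g <- g[, c("origin", "roast", "batch", "reading")]
    g$roast <- factor(g$roast, levels = design@roasts)
    rownames(g) <- sprintf("%s_%s_b%d_r%d", g$origin, g$roast, g$batch,
                           g$reading)
    g
}

# Centered trend offsets across the roast order, one row per trend type.
.trendOffsets <- function(trend, effect, nRoast) {
    idx <- seq_len(nRoast)
    base <- switch(trend,
        "increasing" = (idx - (nRoast + 1) / 2) / ((nRoast - 1) / 2),
        "decreasing" = -(idx - (nRoast + 1) / 2) / ((nRoast - 1) / 2),
        "peak-at-medium" = {
            mid <- ceiling(nRoast / 2)
            v <- ifelse(idx == mid, 1, -0.5)
            v - mean(v)
        },
        "flat" = rep(0, nRoast),
        stop("invalid trend label: ", trend))
    base * effect
}

#' Generate a synthetic volatile peak-area table
#'
#' Each compound is assigned a chemical class and a role: `trend` compounds
#' follow their class's roast trend on the log-abundance scale; `flat`
#' compounds carry no roast signal; `sub_threshold` compounds never rise
#' above the design's abundance floor (work for the abundance filter); and
#' `sparse` compounds are detected in under 80 percent of the readings of
#' every (origin x roast) group (work for the reproducibility filter).
#' Replicate noise is multiplicative lognormal with the design's coefficient
#' of variation; batches share a lognormal batch effect.
#'
#' @param design a [RoastDesign-class]
#' @return a [VolatileTable-class]; compound metadata records the planted
#'   class, trend, role and effect for ground-truth tests.
#' @export
generateVolatileTable <- function(design) {
    validObject(design)
    withSeed(design@seed, {
        meta <- .sampleLayout(design, design@gcmsReadingsPerBatch)
        n <- nrow(meta)
        nC <- design@nCompounds
        nRoast <- length(design@roasts)
        ct <- design@classTrends

        nIrr <- round(design@irregularFraction * nC)
        nSparse <- round(design@sparseFraction * nC)
        nFlat <- round(design@flatFraction * nC)
        role <- rep("trend", nC)
        pos <- sample.int(nC)
        if (nIrr) role[pos[seq_len(nIrr)]] <- "sub_threshold"
        if (nSparse) role[pos[nIrr + seq_len(nSparse)]] <- "sparse"
        if (nFlat) role[pos[nIrr + nSparse + seq_len(nFlat)]] <- "flat"

        trendClasses <- ct[ct$trend != "flat", , drop = FALSE]
        flatClasses <- ct[ct$trend == "flat", , drop = FALSE]
        if (!nrow(flatClasses))
            flatClasses <- data.frame(class = "other", trend = "flat",
                                      effect = 0)
        cls <- character(nC)
        isFlat <- role == "flat"
        cls[isFlat] <- sample(flatClasses$class, sum(isFlat),
                              replace = TRUE)
        # stratify trend-type coverage: cycling over the trend types keeps
        # the latent roast geometry two-dimensional (monotone + quadratic),
        # the regime in which a middle roast class is linearly separable
        idxT <- which(!isFlat)
        typeOf <- rep(unique(trendClasses$trend),
                      length.out = length(idxT))
        cls[idxT] <- vapply(typeOf, function(tp) {
            pool <- trendClasses$class[trendClasses$trend == tp]
            if (length(pool) == 1L) pool else sample(pool, 1L)
        }, character(1))
        trend <- ct$trend[match(cls, ct$class)]
        effect <- ct$effect[match(cls, ct$class)]
        trend[isFlat] <- "flat"
        effect[isFlat] <- 0

        baseLog <- stats::runif(nC, log(1e5), log(2e6))
        offsets <- t(vapply(seq_len(nC),
            function(i) .trendOffsets(trend[i], effect[i], nRoast),
            numeric(nRoast)))
        colnames(offsets) <- design@roasts

        batchKey <- interaction(meta$origin, meta$roast, meta$batch,
                                drop = TRUE, lex.order = TRUE)
        batchKey <- factor(batchKey, levels = unique(as.character(batchKey)))
        nBatch <- nlevels(batchKey)
        batchEff <- matrix(stats::rnorm(nBatch * nC, 0, design@batchSD),
                           nBatch, nC)

        sigma <- sqrt(log(1 + design@noiseCV^2))
        roastIdx <- as.integer(factor(meta$roast, levels = design@roasts))
        mu <- matrix(baseLog, n, nC, byrow = TRUE) +
            t(offsets)[roastIdx, , drop = FALSE] +
            batchEff[as.integer(batchKey), , drop = FALSE]
        areas <- exp(mu + matrix(stats::rnorm(n * nC, 0, sigma), n, nC))

        # sub-threshold compounds: never rise above the abundance floor
        for (j in which(role == "sub_threshold"))
            areas[, j] <- stats::runif(n, 0.02 * design@abundanceFloor,
                                       0.8 * design@abundanceFloor)

        # sparse compounds: ~70% presence, forced below 80% in every
        # (origin x roast) replicate group
        groupKey <- interaction(meta$origin, meta$roast, drop = TRUE,
                                lex.order = TRUE)
        for (j in which(role == "sparse")) {
            for (g in levels(groupKey)) {
                idx <- which(groupKey == g)
                nPresent <- max(1L, floor(0.7 * length(idx)))
                absent <- sample(idx, length(idx) - nPresent)
                areas[absent, j] <- 0
            }
        }

        ids <- sprintf("cmpd%03d_%s", seq_len(nC), cls)
        colnames(areas) <- ids
        rownames(areas) <- rownames(meta)
        compoundData <- data.frame(compoundClass = cls, trend = trend,
                                   role = role, effect = effect,
                                   row.names = ids)
        VolatileTable(areas, compoundData, meta)
    })
}

# Fixed NIR band library: narrow Gaussian component bands, several centred
# in the 500-1000 nm region where roast discrimination concentrates, plus
# overtone/combination positions. Bands are deliberately narrow so the
# chemical signal is spectrally distinct from the broad multiplicative and
# polynomial-baseline artifacts EMSC removes.
.bandLibrary <- function(wl) {
    centers <- c(550, 620, 850, 950, 1060, 1600, 2060, 2420)
    widths <- c(25, 28, 28, 25, 32, 38, 35, 35)
    G <- vapply(seq_along(centers),
                function(k) exp(-0.5 * ((wl - centers[k]) / widths[k])^2),
                numeric(length(wl)))
    list(G = G, centers = centers, widths = widths)
}

# Deterministic mean absorbance spectrum: a gentle slope plus sharp
# water/C-H absorption features, so the multiplicative reference is well
# separated from the low-order polynomial baseline.
.meanSpectrum <- function(wl) {
    0.35 +
        0.05 * (wl - min(wl)) / diff(range(wl)) +
        0.60 * exp(-0.5 * ((wl - 1940) / 50)^2) +
        0.50 * exp(-0.5 * ((wl - 1450) / 50)^2) +
        0.25 * exp(-0.5 * ((wl - 1200) / 45)^2) +
        0.22 * exp(-0.5 * ((wl - 2280) / 50)^2) +
        0.15 * exp(-0.5 * ((wl - 760) / 50)^2)
}

#' Generate synthetic NIR spectra linked to a volatile table
#'
#' Each sample's raw spectrum is built as
#' `b * (m + G w) + polynomial baseline + noise`: a multiplicative scatter
#' factor `b > 0` drawn per sample, a fixed mean spectrum `m`, Gaussian
#' component bands `G` whose weights `w` are linear in a rank-limited
#' projection of the sample's batch-mean log volatile abundances (so spectra
#' genuinely carry the volatile information), an order-2 polynomial baseline
#' in the rescaled wavelength coordinate, and iid noise. Origins after the
#' first receive a mild additive band-weight shift. The true `b`, baseline
#' coefficients, mixing matrices and artifact-free spectra are stored in
#' `metadata(x)$truth` for oracle tests.
#'
#' @param design the [RoastDesign-class] the volatile table was built from
#' @param volatiles the matching [VolatileTable-class]
#' @return a [SpectraSet-class] with ground truth in its metadata
#' @export
generateSpectra <- function(design, volatiles) {
    validObject(design)
    gmeta <- .sampleLayout(design, design@gcmsReadingsPerBatch)
    cd <- as.data.frame(colData(volatiles))
    if (nrow(cd) != nrow(gmeta) ||
        !identical(paste(cd$origin, cd$roast, cd$batch),
                   paste(gmeta$origin, gmeta$roast, gmeta$batch)))
        stop("volatile table does not match the design's sample layout")
    if (nrow(volatiles) != design@nCompounds)
        stop("volatile table compound count does not match the design")

    withSeed(design@seed + 1L, {
        wl <- design@wavelengths
        nw <- length(wl)
        meta <- .sampleLayout(design, design@nirReadingsPerBatch)
        n <- nrow(meta)

        # batch-mean log abundances from the table itself: the latent link.
        # Irregular detections (sub-threshold, sparse presence/absence) are
        # instrument artifacts, not constituent chemistry, so they carry no
        # spectral signature.
        role <- rowData(volatiles)$role
        real <- if (is.null(role)) rep(TRUE, nrow(volatiles)) else
            role %in% c("trend", "flat")
        logA <- log1p(peakAreas(volatiles)[, real, drop = FALSE])
        gKey <- factor(paste(cd$origin, cd$roast, cd$batch, sep = "_"),
                       levels = unique(paste(cd$origin, cd$roast, cd$batch,
                                             sep = "_")))
        bm <- rowsum(logA, gKey) / as.vector(table(gKey))

        r <- design@latentRank
        L <- matrix(stats::rnorm(r * ncol(bm)), r) / sqrt(ncol(bm))
        z <- bm %*% t(L)
        zCenter <- colMeans(z)
        zScale <- apply(z, 2L, stats::sd)
        zScale[zScale == 0] <- 1
        zs <- sweep(sweep(z, 2L, zCenter), 2L, zScale, "/")

        bands <- .bandLibrary(wl)
        K <- ncol(bands$G)
        M <- matrix(stats::rnorm(K * r, 0, 0.003), K, r)
        shifts <- matrix(0, length(design@origins), K,
                         dimnames = list(design@origins, NULL))
        if (length(design@origins) > 1L)
            for (o in design@origins[-1L])
                shifts[o, ] <- stats::rnorm(K, 0, design@originShift)

        m <- .meanSpectrum(wl)
        batchOf <- paste(meta$origin, meta$roast, meta$batch, sep = "_")
        zRow <- match(batchOf, rownames(bm))
        if (anyNA(zRow))
            stop("NIR layout contains batches absent from the volatile table")
        W <- zs[zRow, , drop = FALSE] %*% t(M) +
            shifts[meta$origin, , drop = FALSE]
        pure <- matrix(m, n, nw, byrow = TRUE) + W %*% t(bands$G)

        b <- exp(stats::rnorm(n, 0, design@scatterSD))
        lamTilde <- 2 * (wl - min(wl)) / diff(range(wl)) - 1
        Pb <- cbind(1, lamTilde, lamTilde^2)
        baseCoef <- rbind(stats::rnorm(n, 0, design@baselineSD[1L]),
                          stats::rnorm(n, 0, design@baselineSD[2L]),
                          stats::rnorm(n, 0, design@baselineSD[3L]))
        noise <- matrix(stats::rnorm(n * nw, 0, design@spectralNoiseSD),
                        n, nw)
        raw <- pure * b + t(Pb %*% baseCoef) + noise
        rownames(raw) <- rownames(meta)

        out <- SpectraSet(raw, wl, meta)
        metadata(out)$truth <- list(
            b = stats::setNames(b, rownames(meta)),
            baseline = baseCoef,
            pure = pure,
            mixing = list(L = L, M = M, zCenter = zCenter, zScale = zScale,
                          bandCenters = bands$centers,
                          bandWidths = bands$widths,
                          originShift = shifts),
            meanSpectrum = m)
        out
    })
}

#' A small fixed-seed worked dataset
#'
#' Two origins x three roasts x three batches, 12 compounds, 200 wavelengths,
#' 3 GC-MS and 3 NIR readings per batch. Used throughout the tests and
#' documentation; calling it twice gives identical objects.
#'
#' @return list with elements `design`, `volatiles`, `spectra`
#' @export
workedFixture <- function() {
    design <- roastDesign(
        nCompounds = 12L,
        gcmsReadingsPerBatch = 3L,
        nirReadingsPerBatch = 3L,
        flatFraction = 0.25,
        irregularFraction = 1 / 12,
        sparseFraction = 1 / 12,
        wavelengths = seq(400, 2500, length.out = 200),
        seed = 20240318L)
    volatiles <- generateVolatileTable(design)
    spectra <- generateSpectra(design, volatiles)
    list(design = design, volatiles = volatiles, spectra = spectra)
}
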
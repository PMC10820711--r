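# Shared fixtures, built once per test run.

fx <- workedFixture()

# A fully deterministic design: no replicate noise, no batch effects, no
# spectral artifacts. The volatile -> spectrum map is then exactly linear.
noiselessDesign <- function(originShift = 0) {
    d <- fx$design
    d@noiseCV <- 0
    d@batchSD <- 0
    d@scatterSD <- 0
    d@baselineSD <- c(0, 0, 0)
    d@spectralNoiseSD <- 0
    d@originShift <- originShift
    d
}

# Small hand-built volatile table: areas is samples x compounds, metadata
# spans origins x roasts x batches evenly over the rows.
toyVolatileTable <- function(areas, origins = "Ethiopia",
                             roasts = c("light", "medium", "dark"),
                             batches = 1L) {
    n <- nrow(areas)
    grid <- expand.grid(batch = seq_len(batches), roast = roasts,
                        origin = origins, stringsAsFactors = FALSE)
    reps <- n / nrow(grid)
    stopifnot(reps == round(reps))
    meta <- grid[rep(seq_len(nrow(grid)), each = reps), ]
    meta$reading <- sequence(rep(reps, nrow(grid)))
    rownames(meta) <- sprintf("%s_%s_b%d_r%d", meta$origin, meta$roast,
                              meta$batch, meta$reading)
    rownames(areas) <- rownames(meta)
    if (is.null(colnames(areas)))
        colnames(areas) <- sprintf("c%02d", seq_len(ncol(areas)))
    cd <- data.frame(compoundClass = rep("other", ncol(areas)),
                     row.names = colnames(areas))
    VolatileTable(areas, cd, meta[, c("origin", "roast", "batch",
                                      "reading")])
}

# Spectra with EMSC-friendly structure: reference plus known artifacts.
toySpectraSet <- function(absorbance, wavelengths = seq(400, 2500,
                                                        length.out =
                                                            ncol(absorbance))) {
    n <- nrow(absorbance)
    meta <- data.frame(origin = "Ethiopia",
                       roast = rep_len(c("light", "medium", "dark"), n),
                       batch = 1L, reading = seq_len(n))
    rownames(meta) <- rownames(absorbance) <- sprintf("s%02d", seq_len(n))
    SpectraSet(absorbance, wavelengths, meta)
}
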
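#' Construct a SpectraSet
#'
#' @param absorbance samples x wavelengths numeric matrix; rownames are
#'   sample ids.
#' @param wavelengths strictly increasing numeric grid in nm.
#' @param sampleData data.frame or DataFrame of sample metadata (origin,
#'   roast, batch, reading), one row per sample.
#' @return a [SpectraSet-class]
#' @examples
#' wl <- seq(400, 2500, by = 100)
#' a <- matrix(runif(3 * length(wl)), 3,
#'             dimnames = list(c("s1", "s2", "s3"), NULL))
#' md <- data.frame(origin = "Ethiopia", roast = c("light", "medium", "dark"),
#'                  batch = 1L, reading = 1L)
#' ss <- SpectraSet(a, wl, md)
#' @export
SpectraSet <- function(absorbance, wavelengths, sampleData) {
    absorbance <- as.matrix(absorbance)
    stopifnot(ncol(absorbance) == length(wavelengths))
    a <- t(absorbance)
    rownames(a) <- sprintf("wl%08.2f", wavelengths)
    cd <- S4Vectors::DataFrame(sampleData)
    rownames(cd) <- rownames(absorbance)
    se <- SummarizedExperiment(
        assays = list(absorbance = a),
        rowData = S4Vectors::DataFrame(wavelength = wavelengths),
        colData = cd)
    new("SpectraSet", se)
}

#' Construct a VolatileTable
#'
#' @param peakAreas samples x compounds numeric matrix of nonnegative peak
#'   areas (NA allowed); rownames are sample ids, colnames compound ids.
#' @param compoundData data.frame of compound metadata (at least
#'   `compoundClass`), one row per compound.
#' @param sampleData data.frame of sample metadata, one row per sample.
#' @return a [VolatileTable-class]
#' @export
VolatileTable <- function(peakAreas, compoundData, sampleData) {
    peakAreas <- as.matrix(peakAreas)
    stopifnot(nrow(compoundData) == ncol(peakAreas),
              nrow(sampleData) == nrow(peakAreas))
    a <- t(peakAreas)
    rd <- S4Vectors::DataFrame(compoundData)
    rownames(rd) <- colnames(peakAreas)
    cd <- S4Vectors::DataFrame(sampleData)
    rownames(cd) <- rownames(peakAreas)
    se <- SummarizedExperiment(assays = list(areas = a),
                               rowData = rd, colData = cd)
    new("VolatileTable", se)
}

#' @rdname SpectraSet-class
setMethod("wavelengths", "SpectraSet",
    function(x) rowData(x)$wavelength)

#' @rdname SpectraSet-class
setMethod("specMatrix", "SpectraSet", function(x) t(assay(x)))

#' @rdname VolatileTable-class
#' @param x a VolatileTable
setMethod("peakAreas", "VolatileTable", function(x) t(assay(x)))

#' @rdname VolatileTable-class
setMethod("compoundData", "VolatileTable", function(x) rowData(x))

#' @rdname SpectraSet-class
setMethod("sampleData", "SummarizedExperiment", function(x) colData(x))

setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("SpectraSet: %d spectra x %d wavelengths (%g-%g nm)\n",
                ncol(object), nrow(object), min(wl), max(wl)))
    cat("sample metadata:", paste(names(colData(object)), collapse = ", "),
        "\n")
})

setMethod("show", "VolatileTable", function(object) {
    cat(sprintf("VolatileTable: %d compounds x %d samples\n",
                nrow(object), ncol(object)))
    cls <- compoundData(object)$compoundClass
    if (!is.null(cls)) {
        tab <- sort(table(cls), decreasing = TRUE)
        cat("classes:", paste(sprintf("%s (%d)", names(tab), tab),
                              collapse = ", "), "\n")
    }
})

.averageSE <- function(x, by) {
    cd <- as.data.frame(colData(x))
    missing <- setdiff(by, names(cd))
    if (length(missing))
        stop("grouping key(s) not in sample metadata: ",
             paste(missing, collapse = ", "))
    key <- interaction(cd[by], drop = TRUE, sep = "_", lex.order = TRUE)
    key <- factor(key, levels = unique(as.character(key)))
    a <- assay(x)
    sums <- t(rowsum(t(a), key))
    n <- as.vector(table(key)[colnames(sums)])
    avg <- sweep(sums, 2L, n, "/")
    first <- match(levels(key), as.character(key))
    newCD <- S4Vectors::DataFrame(cd[first, by, drop = FALSE])
    newCD$nAveraged <- n
    rownames(newCD) <- colnames(avg) <- levels(key)
    se <- SummarizedExperiment(assays = stats::setNames(list(avg),
                                                        assayNames(x)[1L]),
                               rowData = rowData(x), colData = newCD)
    new(class(x), se)
}

#' @rdname averageReplicates
setMethod("averageReplicates", "SpectraSet",
    function(x, by = c("origin", "roast", "batch"), ...) .averageSE(x, by))

#' @rdname averageReplicates
setMethod("averageReplicates", "VolatileTable",
    function(x, by = c("origin", "roast", "batch"), ...) .averageSE(x, by))

#' Restrict spectra to a wavelength window
#'
#' Optional crop supporting analyses restricted to a sub-region of the grid
#' (for example the 500-1000 nm region where roast-degree loadings
#' concentrate).
#'
#' @param spectra a [SpectraSet-class]
#' @param lower,upper window bounds in nm (inclusive)
#' @return a SpectraSet on the restricted grid
#' @export
cropWavelengths <- function(spectra, lower, upper) {
    keep <- wavelengths(spectra) >= lower & wavelengths(spectra) <= upper
    if (!any(keep))
        stop("no wavelengths inside [", lower, ", ", upper, "] nm")
    spectra[keep, ]
}

#' Replace missing peak areas by zero
#'
#' Absence of a peak is informative (the compound was not detected), so the
#' analysis carries absent peaks as zero abundance before autoscaling.
#'
#' @param table a [VolatileTable-class]
#' @return the table with NA areas set to 0
#' @export
zeroMissing <- function(table) {
    a <- assay(table)
    a[is.na(a)] <- 0
    assay(table) <- a
    table
}

## ---- delimited-text I/O ----------------------------------------------------

#' Read/write SpectraSet and VolatileTable as delimited text
#'
#' The main table is tab-delimited with `sample_id` as first column and one
#' column per wavelength (`wl<nm>`) or compound; sample metadata lives in a
#' sidecar tab-delimited file keyed by `sample_id`, compound metadata (for
#' volatile tables) in a second sidecar keyed by `compound_id`.
#'
#' @param x object to write
#' @param file main table path
#' @param sampleFile sample-metadata sidecar path
#' @param compoundFile compound-metadata sidecar path (volatile tables)
#' @return `readSpectraSet`/`readVolatileTable` return the reconstructed
#'   object; the writers return `file` invisibly.
#' @name spectra-io
NULL

#' @rdname spectra-io
#' @export
writeSpectraSet <- function(x, file, sampleFile) {
    m <- specMatrix(x)
    df <- data.frame(sample_id = rownames(m),
                     m, check.names = FALSE, row.names = NULL)
    names(df)[-1L] <- sprintf("wl%.15g", wavelengths(x))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    md <- data.frame(sample_id = rownames(m),
                     as.data.frame(colData(x)), row.names = NULL)
    utils::write.table(md, sampleFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname spectra-io
#' @export
readSpectraSet <- function(file, sampleFile) {
    df <- utils::read.delim(file, check.names = FALSE)
    md <- utils::read.delim(sampleFile)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$sample_id
    wl <- as.numeric(sub("^wl", "", colnames(m)))
    md <- md[match(df$sample_id, md$sample_id), , drop = FALSE]
    SpectraSet(m, wl, md[setdiff(names(md), "sample_id")])
}

#' @rdname spectra-io
#' @export
writeVolatileTable <- function(x, file, sampleFile, compoundFile) {
    m <- peakAreas(x)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     row.names = NULL)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    md <- data.frame(sample_id = rownames(m),
                     as.data.frame(colData(x)), row.names = NULL)
    utils::write.table(md, sampleFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- data.frame(compound_id = colnames(m),
                     as.data.frame(rowData(x)), row.names = NULL)
    utils::write.table(cd, compoundFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname spectra-io
#' @export
readVolatileTable <- function(file, sampleFile, compoundFile) {
    df <- utils::read.delim(file, check.names = FALSE)
    md <- utils::read.delim(sampleFile)
    cd <- utils::read.delim(compoundFile)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$sample_id
    md <- md[match(df$sample_id, md$sample_id), , drop = FALSE]
    cd <- cd[match(colnames(m), cd$compound_id), , drop = FALSE]
    rownames(cd) <- cd$compound_id
    VolatileTable(m, cd[setdiff(names(cd), "compound_id")],
                  md[setdiff(names(md), "sample_id")])
}
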
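#' VID scores: correlate volatile abundances with predicted class membership
#'
#' The variable identification coefficient of compound c for class k is the
#' Pearson correlation between c's abundance vector and the PLS-DA model's
#' continuous predicted membership column for class k, computed on the
#' calibration samples. Compounds with zero abundance variance cannot be
#' correlated and are flagged rather than given a coefficient.
#'
#' @param volatiles a [VolatileTable-class] (calibration samples)
#' @param predictedMembership samples x classes matrix of continuous
#'   PLS-DA predictions, rows aligned with the table's samples
#' @return a [VIDResult-class]
#' @export
vidScores <- function(volatiles, predictedMembership) {
    P <- as.matrix(predictedMembership)
    X <- peakAreas(volatiles)
    if (nrow(X) != nrow(P))
        stop("sample rows of the volatile table (", nrow(X),
             ") and the membership matrix (", nrow(P), ") do not match")
    X[is.na(X)] <- 0
    sds <- colSds(X)
    undefined <- colnames(X)[sds == 0]
    cc <- suppressWarnings(stats::cor(X, P))
    cc[sds == 0, ] <- NA_real_
    new("VIDResult", coefficients = cc, thresholds = numeric(0),
        selected = list(), undefined = undefined)
}

#' Select discriminant compounds from VID scores
#'
#' Signed mode keeps compounds with VID strictly above the threshold (the
#' 0.8 marker rule); magnitude mode keeps |VID| strictly above it (the
#' |0.9| heatmap rule). An exact hit at the threshold is admitted within
#' 1e-12 so boundary values such as VID = 1 at threshold 1 are kept.
#' Per-class lists are sorted by descending |VID|.
#'
#' @param vid a [VIDResult-class]
#' @param threshold selection threshold in (0, 1]
#' @param signed logical; TRUE keeps VID > threshold, FALSE keeps
#'   |VID| > threshold
#' @return named list (one element per class) of compound id vectors; the
#'   input object with `selected` and `thresholds` filled is attached as
#'   attribute `vid`
#' @export
selectDiscriminant <- function(vid, threshold = 0.8, signed = TRUE) {
    stopifnot(threshold > 0, threshold <= 1)
    cc <- vid@coefficients
    eps <- 1e-12
    sel <- lapply(colnames(cc), function(k) {
        v <- cc[, k]
        keep <- if (signed) v > threshold - eps else abs(v) > threshold - eps
        keep[is.na(keep)] <- FALSE
        ids <- rownames(cc)[keep]
        ids[order(abs(v[keep]), decreasing = TRUE)]
    })
    names(sel) <- colnames(cc)
    if (all(!lengths(sel)))
        warning("no compound passed the VID threshold ", threshold)
    vid@selected <- sel
    vid@thresholds <- threshold
    structure(sel, vid = vid)
}

setMethod("show", "VIDResult", function(object) {
    cat(sprintf("VIDResult: %d compounds x %d classes\n",
                nrow(object@coefficients), ncol(object@coefficients)))
    if (length(object@undefined))
        cat("  zero-variance compounds:",
            paste(object@undefined, collapse = ", "), "\n")
    if (length(object@selected))
        cat("  selected:",
            paste(sprintf("%s (%d)", names(object@selected),
                          lengths(object@selected)), collapse = ", "), "\n")
})

#' Long-format VID table for reports
#'
#' @param vid a [VIDResult-class] (after [selectDiscriminant()] if selection
#'   flags are wanted)
#' @return data.frame with columns compound, class, vid, selected
#' @export
vidTable <- function(vid) {
    cc <- vid@coefficients
    out <- data.frame(
        compound = rep(rownames(cc), times = ncol(cc)),
        class = rep(colnames(cc), each = nrow(cc)),
        vid = as.vector(cc), row.names = NULL)
    out$selected <- FALSE
    for (k in names(vid@selected))
        out$selected[out$class == k &
                     out$compound %in% vid@selected[[k]]] <- TRUE
    out
}

#' Class-mean scaled-intensity matrix for heatmaps
#'
#' For each selected compound, the roast-class means of its autoscaled
#' abundance. Rows are ordered by class membership (the class under which a
#' compound was selected, in class order) and then by descending |VID|,
#' matching the published heatmap layout; compounds selected under several
#' classes appear once, under the first.
#'
#' @param volatiles a [VolatileTable-class]
#' @param selection per-class compound lists from [selectDiscriminant()]
#' @param classColumn sample-metadata column holding the class (default
#'   "roast")
#' @return matrix, selected compounds x classes, with attribute
#'   `memberClass` recording each row's selection class
#' @export
heatmapMatrix <- function(volatiles, selection, classColumn = "roast") {
    ids <- unlist(selection, use.names = FALSE)
    member <- rep(names(selection), lengths(selection))
    keep <- !duplicated(ids)
    ids <- ids[keep]; member <- member[keep]
    if (!length(ids))
        stop("empty selection: nothing to plot")
    X <- peakAreas(volatiles)[, ids, drop = FALSE]
    X[is.na(X)] <- 0
    Z <- autoscale(X)$scaled
    cls <- as.data.frame(colData(volatiles))[[classColumn]]
    cls <- if (is.factor(cls)) droplevels(cls) else
        factor(cls, levels = unique(cls))
    means <- rowsum(Z, cls) / as.vector(table(cls))
    out <- t(means)                        # compounds x classes
    attr(out, "memberClass") <- stats::setNames(member, ids)
    out
}
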
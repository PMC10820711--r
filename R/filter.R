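#' Abundance filter for volatile peak tables
#'
#' Drops a compound when its maximum observed area across all samples falls
#' below the threshold, i.e. peaks that never rise above instrument noise.
#' The sample set is unchanged and compound order is preserved.
#'
#' @param table a [VolatileTable-class]
#' @param threshold area threshold (the study used 50,000 arbitrary units)
#' @return list with `table` (the filtered [VolatileTable-class]) and
#'   `dropped` (character, removed compound ids)
#' @examples
#' fx <- workedFixture()
#' res <- abundanceFilter(fx$volatiles, 5e4)
#' res$dropped
#' @export
abundanceFilter <- function(table, threshold = 5e4) {
    stopifnot(threshold >= 0)
    a <- assay(table)
    maxArea <- apply(a, 1L, max, na.rm = TRUE)
    keep <- maxArea >= threshold
    if (!any(keep))
        warning("abundance filter removed every compound")
    list(table = table[keep, ], dropped = rownames(table)[!keep])
}

#' Reproducibility filter for volatile peak tables
#'
#' A peak is "present" in a reading when its area is non-missing and
#' positive. A compound is retained iff, in at least one (origin x roast)
#' replicate group, it is present in at least `minFraction` of that group's
#' readings. The any-group rule keeps markers that are genuinely absent at
#' other roast degrees.
#'
#' @param table a [VolatileTable-class] whose sample metadata has `origin`
#'   and `roast` columns
#' @param minFraction required presence fraction within a group (study: 0.8)
#' @return list with `table` and `dropped` as in [abundanceFilter()]
#' @export
reproducibilityFilter <- function(table, minFraction = 0.8) {
    stopifnot(minFraction > 0, minFraction <= 1)
    cd <- as.data.frame(colData(table))
    if (!all(c("origin", "roast") %in% names(cd)))
        stop("sample metadata must contain 'origin' and 'roast'")
    # factor inputs keep their declared levels, so a declared-but-absent
    # replicate group errors out rather than being silently skipped
    org <- if (is.factor(cd$origin)) cd$origin else factor(cd$origin)
    rst <- if (is.factor(cd$roast)) cd$roast else factor(cd$roast)
    counts <- table(org, rst)
    if (any(counts == 0)) {
        bad <- which(counts == 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("replicate group '%s x %s' has no readings",
                     rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
    }
    key <- factor(paste(org, rst, sep = "_"))
    a <- assay(table)
    present <- !is.na(a) & a > 0
    # per-compound presence count within each group
    cnt <- t(rowsum(t(present) * 1, key))      # compounds x groups
    size <- as.vector(table(key)[colnames(cnt)])
    frac <- sweep(cnt, 2L, size, "/")
    keep <- apply(frac, 1L, function(fr) any(fr >= minFraction))
    if (!any(keep))
        warning("reproducibility filter removed every compound")
    list(table = table[keep, ], dropped = rownames(table)[!keep])
}

#' Autoscale a sample-by-feature matrix
#'
#' Mean centering followed by standardization: each column ends with mean 0
#' and standard deviation 1 (n-1 denominator). The returned
#' [ScalingState-class] applies the identical transform to new data and
#' inverts predictions back to the raw scale.
#'
#' @param m numeric matrix, samples x features, no missing values
#' @return list with `scaled` (matrix) and `state` ([ScalingState-class])
#' @examples
#' autoscale(cbind(a = c(2, 4, 6)))$scaled
#' @export
autoscale <- function(m) {
    m <- as.matrix(m)
    if (anyNA(m))
        stop("missing values must be imputed (see zeroMissing) before ",
             "autoscaling")
    center <- colMeans(m)
    s <- colSds(m)
    if (any(s <= 0)) {
        bad <- colnames(m)[which(s <= 0)[1L]]
        if (is.null(bad)) bad <- which(s <= 0)[1L]
        stop("zero-variance column: ", bad)
    }
    scaled <- sweep(sweep(m, 2L, center), 2L, s, "/")
    list(scaled = scaled, state = new("ScalingState", center = center,
                                      scale = s))
}

#' @rdname autoscale
#' @param state a [ScalingState-class]
#' @export
applyScaling <- function(state, m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == length(state@center))
    sweep(sweep(m, 2L, state@center), 2L, state@scale, "/")
}

#' @rdname autoscale
#' @export
revertScaling <- function(state, m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == length(state@center))
    sweep(sweep(m, 2L, state@scale, "*"), 2L, state@center, "+")
}
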
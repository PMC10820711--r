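# Polynomial basis in the wavelength coordinate rescaled to [-1, 1].
.polyBasis <- function(wl, polyOrder) {
    lam <- 2 * (wl - min(wl)) / diff(range(wl)) - 1
    vapply(0:polyOrder, function(k) lam^k, numeric(length(wl)))
}

.emscCore <- function(X, wl, reference, polyOrder) {
    Pb <- .polyBasis(wl, polyOrder)
    D <- cbind(reference, Pb)
    fit <- stats::lm.fit(D, t(X))
    coefs <- as.matrix(fit$coefficients)        # (1 + polyOrder + 1) x n
    b <- coefs[1L, ]
    low <- abs(b) < 1e-8
    if (any(low))
        stop("EMSC multiplicative coefficient below 1e-8 for sample(s): ",
             paste(rownames(X)[low], collapse = ", "))
    baseline <- t(Pb %*% coefs[-1L, , drop = FALSE])   # n x wavelengths
    corrected <- (X - baseline) / b
    dimnames(corrected) <- dimnames(X)
    list(corrected = corrected, b = b,
         baseline = coefs[-1L, , drop = FALSE])
}

#' Extended multiplicative signal correction
#'
#' Fits each spectrum x as `x ~ b * r + sum_k c_k p_k(lambda)` by least
#' squares, where r is the reference spectrum and p_k are polynomials in the
#' wavelength coordinate rescaled to [-1, 1], then returns the corrected
#' spectrum `(x - sum_k c_k p_k) / b`. Removes multiplicative scatter and
#' additive baseline curvature while preserving chemical signal relative to
#' the reference.
#'
#' @param spectra a [SpectraSet-class]
#' @param reference `"mean"` (the mean of the input spectra, standard EMSC
#'   practice for a calibration set) or a numeric spectrum on the same grid
#' @param polyOrder polynomial baseline order, 0-2 (default 2: curvature)
#' @return list with `spectra` (corrected [SpectraSet-class]) and `state`
#'   (an [EMSCState-class]); apply the state to validation spectra with
#'   [applyEMSC()] so they are corrected against the calibration reference.
#' @export
emsc <- function(spectra, reference = "mean", polyOrder = 2L) {
    polyOrder <- as.integer(polyOrder)
    stopifnot(polyOrder %in% 0:2)
    X <- specMatrix(spectra)
    wl <- wavelengths(spectra)
    r <- if (identical(reference, "mean")) colMeans(X) else {
        if (length(reference) != length(wl))
            stop("reference spectrum not on the same wavelength grid")
        as.numeric(reference)
    }
    res <- .emscCore(X, wl, r, polyOrder)
    out <- SpectraSet(res$corrected, wl, colData(spectra))
    metadata(out) <- metadata(spectra)
    state <- new("EMSCState", reference = r, wavelengths = wl,
                 polyOrder = polyOrder, b = res$b, baseline = res$baseline)
    list(spectra = out, state = state)
}

#' @rdname emsc
#' @param state an [EMSCState-class] fitted on the calibration set
#' @export
applyEMSC <- function(state, spectra) {
    wl <- wavelengths(spectra)
    if (length(wl) != length(state@wavelengths) ||
        max(abs(wl - state@wavelengths)) > 1e-8)
        stop("spectra are not on the EMSC state's wavelength grid")
    res <- .emscCore(specMatrix(spectra), wl, state@reference,
                     state@polyOrder)
    out <- SpectraSet(res$corrected, wl, colData(spectra))
    metadata(out) <- metadata(spectra)
    list(spectra = out,
         state = new("EMSCState", reference = state@reference,
                     wavelengths = wl, polyOrder = state@polyOrder,
                     b = res$b, baseline = res$baseline))
}

#' Mean-center spectra per wavelength
#'
#' @param spectra a [SpectraSet-class]
#' @param means optional stored column means (from a calibration set); when
#'   NULL the means of `spectra` are used
#' @return list with `spectra` (centered) and `means` (numeric vector to
#'   apply to validation spectra)
#' @export
meanCenter <- function(spectra, means = NULL) {
    X <- specMatrix(spectra)
    if (is.null(means)) means <- colMeans(X)
    stopifnot(length(means) == ncol(X))
    out <- SpectraSet(sweep(X, 2L, means), wavelengths(spectra),
                      colData(spectra))
    metadata(out) <- metadata(spectra)
    list(spectra = out, means = means)
}

#' Serialize / restore an EMSC state as structured text (JSON)
#'
#' @param state an [EMSCState-class]
#' @param file path
#' @name emsc-io
#' @export
writeEMSCState <- function(state, file) {
    jsonlite::write_json(
        list(reference = unname(state@reference),
             wavelengths = state@wavelengths,
             polyOrder = state@polyOrder, b = as.list(state@b),
             baseline = state@baseline),
        file, digits = NA, auto_unbox = TRUE)
    invisible(file)
}

#' @rdname emsc-io
#' @export
readEMSCState <- function(file) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    new("EMSCState", reference = as.numeric(x$reference),
        wavelengths = as.numeric(x$wavelengths),
        polyOrder = as.integer(x$polyOrder),
        b = stats::setNames(as.numeric(x$b), names(x$b)),
        baseline = as.matrix(x$baseline))
}
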
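#' @rdname SpectraSet-class
#' @param x a SpectraSet or VolatileTable
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectraSet-class
#' @export
setGeneric("specMatrix", function(x) standardGeneric("specMatrix"))

#' @rdname VolatileTable-class
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))

#' @rdname VolatileTable-class
#' @export
setGeneric("compoundData", function(x) standardGeneric("compoundData"))

#' @rdname SpectraSet-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' Collapse analytical replicates by group means
#'
#' @param x a SpectraSet or VolatileTable
#' @param by character, metadata columns defining the replicate groups
#' @param ... unused
#' @return an object of the same class with one column per group, the
#'   arithmetic mean of the group's readings; collapsed metadata keeps the
#'   grouping columns and records the group size in `nAveraged`.
#' @export
setGeneric("averageReplicates",
    function(x, by = c("origin", "roast", "batch"), ...)
        standardGeneric("averageReplicates"))

#' @rdname PLSModel-class
#' @param object a PLSModel
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
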
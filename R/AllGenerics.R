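#' @rdname indexToWavelength
#' @export
setGeneric("indexToWavelength", function(i, grid) standardGeneric("indexToWavelength"))

#' @rdname indexToWavelength
#' @export
setGeneric("wavelengthToIndex", function(nm, grid) standardGeneric("wavelengthToIndex"))

#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname absorbances
#' @export
setGeneric("absorbances", function(x) standardGeneric("absorbances"))

#' @rdname absorbances
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname absorbances
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))

#' @rdname averageReplicates
#' @export
setGeneric("averageReplicates", function(x) standardGeneric("averageReplicates"))

#' @rdname applyAutoscale
#' @export
setGeneric("applyAutoscale", function(X, params) standardGeneric("applyAutoscale"))

#' @rdname applyAutoscale
#' @export
setGeneric("invertAutoscale", function(X, params) standardGeneric("invertAutoscale"))

#' @rdname selectionTable
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @rdname coefficientsRaw
#' @export
setGeneric("coefficientsRaw", function(object) standardGeneric("coefficientsRaw"))

#' @rdname modelReport
#' @export
setGeneric("modelReport", function(object, stats) standardGeneric("modelReport"))

#' @rdname looStats
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
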
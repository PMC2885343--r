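#' @rdname GenomeBuild-class
#' @param x,object a `GenomeBuild`, `CGHExperiment`, `WindowCalls` or
#'   `ExpressionMatrix` as documented per method.
#' @export
setGeneric("chromTable", function(x) standardGeneric("chromTable"))

#' @rdname GenomeBuild-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeBuild-class
#' @export
setGeneric("telomerePad", function(x) standardGeneric("telomerePad"))

#' @rdname GenomeBuild-class
#' @export
setGeneric("autosomeNames", function(x) standardGeneric("autosomeNames"))

#' @rdname CGHExperiment-class
#' @export
setGeneric("lrMatrix", function(x) standardGeneric("lrMatrix"))

#' @rdname CGHExperiment-class
#' @export
setGeneric("probeRanges", function(x) standardGeneric("probeRanges"))

#' @rdname WindowCalls-class
#' @export
setGeneric("callStates", function(x) standardGeneric("callStates"))

#' @rdname WindowCalls-class
#' @export
setGeneric("callMeans", function(x) standardGeneric("callMeans"))

#' @rdname WindowCalls-class
#' @export
setGeneric("windowRanges", function(x) standardGeneric("windowRanges"))

#' @rdname WindowCalls-class
#' @export
setGeneric("thresholdsOf", function(x) standardGeneric("thresholdsOf"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("linearExpr", function(x) standardGeneric("linearExpr"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("centeredLogExpr", function(x) standardGeneric("centeredLogExpr"))
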
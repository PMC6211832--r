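#' @rdname MeltCurve-class
#' @param x,object a \code{MeltCurve} (or other object with a well identifier)
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname MeltCurve-class
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @rdname MeltCurve-class
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))

#' @rdname MeltCurve-class
#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))

#' @rdname TmCall-class
#' @export
setGeneric("tmValue", function(x) standardGeneric("tmValue"))

#' @rdname TmCall-class
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname ScreenReport-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname ScreenReport-class
#' @export
setGeneric("reportMetadata", function(x) standardGeneric("reportMetadata"))
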
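#' @importFrom methods setGeneric setMethod new validObject is as show
NULL

#' @rdname countsByClass
#' @export
setGeneric("countsByClass", function(x) standardGeneric("countsByClass"))

#' @rdname snpIds
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname chromClass
#' @export
setGeneric("chromClass", function(x) standardGeneric("chromClass"))

#' @rdname panel-accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @rdname panel-accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))

#' @rdname panel-accessors
#' @export
setGeneric("isProvisional", function(x) standardGeneric("isProvisional"))

#' @rdname GenotypeCalls-accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname GenotypeCalls-accessors
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))

#' @rdname DiagnosticSet-accessors
#' @export
setGeneric("diagnosticLoci", function(x) standardGeneric("diagnosticLoci"))

#' @rdname DiagnosticSet-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname DiagnosticSet-accessors
#' @export
setGeneric("donorLabel", function(x) standardGeneric("donorLabel"))

#' @rdname DiagnosticSet-accessors
#' @export
setGeneric("recipientLabel", function(x) standardGeneric("recipientLabel"))
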
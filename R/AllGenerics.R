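#' @rdname UniqueReadSet-class
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))

#' @rdname UniqueReadSet-class
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname CascadeResult-class
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname CascadeResult-class
#' @export
setGeneric("unassignedReads", function(x) standardGeneric("unassignedReads"))

#' @rdname CascadeResult-class
#' @export
setGeneric("stageSummary", function(x) standardGeneric("stageSummary"))

#' @rdname FoldResult-class
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname FoldResult-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname FoldResult-class
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))
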
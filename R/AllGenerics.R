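#' @rdname TranscriptSet
#' @param x a \code{TranscriptSet} or \code{ReactivitySet}
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptSet
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TranscriptSet
#' @export
setGeneric("regionLengths", function(x) standardGeneric("regionLengths"))

#' @rdname TranscriptSet
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname TranscriptSet
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ReactivitySet
#' @export
setGeneric("reactivityValues", function(x) standardGeneric("reactivityValues"))

#' @rdname ReactivitySet
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' Scan a transcript set for motif occurrences
#'
#' @param x a [TranscriptSet]
#' @param ... passed to methods
#' @export
setGeneric("scanMotifs", function(x, ...) standardGeneric("scanMotifs"))
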
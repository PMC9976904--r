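#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges NumericList
#' @importFrom Biostrings DNAStringSet width
NULL

#' Annotated transcript set
#'
#' Container for a transcriptome of DNA-alphabet transcript sequences with
#' 5'UTR/CDS/3'UTR region annotation and an abundance estimate per
#' transcript. Sequences are stored as a \link[Biostrings]{DNAStringSet};
#' the annotation is a \link[S4Vectors]{DataFrame} with one row per
#' transcript carrying \code{gene_id}, the three region lengths in
#' nucleotides (\code{len_5utr}, \code{len_cds}, \code{len_3utr}) and
#' \code{abundance} (arbitrary expression units).
#'
#' The class enforces that the three region lengths sum to the sequence
#' length for every transcript, that transcript identifiers are unique, and
#' that sequences contain only A/C/G/T (RNA input is normalised with U
#' mapped to T on construction).
#'
#' @slot sequences \link[Biostrings]{DNAStringSet}, one entry per transcript,
#'   named by transcript id.
#' @slot anno \link[S4Vectors]{DataFrame} with columns \code{gene_id},
#'   \code{len_5utr}, \code{len_cds}, \code{len_3utr}, \code{abundance};
#'   row names are the transcript ids in the same order as \code{sequences}.
#'
#' @seealso [TranscriptSet()] for the constructor, [scanMotifs()],
#'   [selectPrimaryTranscripts()]
#' @aliases TranscriptSet-class
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  representation(sequences = "DNAStringSet", anno = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all sequences must be named by transcript id")
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate transcript ids: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  need <- c("gene_id", "len_5utr", "len_cds", "len_3utr", "abundance")
  miss <- setdiff(need, colnames(object@anno))
  if (length(miss))
    msg <- c(msg, paste0("annotation lacks column(s): ", paste(miss, collapse = ", ")))
  if (nrow(object@anno) != length(object@sequences))
    msg <- c(msg, "annotation row count differs from sequence count")
  if (!length(msg)) {
    if (!identical(rownames(object@anno), ids))
      msg <- c(msg, "annotation row names must match sequence names in order")
    lens <- object@anno$len_5utr + object@anno$len_cds + object@anno$len_3utr
    bad <- which(lens != Biostrings::width(object@sequences))
    if (length(bad))
      msg <- c(msg, paste0("region lengths do not sum to sequence length for: ",
                           paste(utils::head(ids[bad], 5), collapse = ", ")))
    if (any(object@anno$len_5utr < 0 | object@anno$len_cds < 0 |
            object@anno$len_3utr < 0))
      msg <- c(msg, "region lengths must be non-negative")
    if (any(object@anno$abundance < 0))
      msg <- c(msg, "abundance must be non-negative")
    freq <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
    if (any(freq[, "other"] > 0))
      msg <- c(msg, paste0("sequences contain non-ACGT characters: ",
                           paste(utils::head(ids[freq[, "other"] > 0], 5), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Per-nucleotide DMS reactivity profiles
#'
#' One reactivity value per nucleotide per transcript for a single probing
#' condition. DMS methylates unpaired A and C bases only, so positions whose
#' base is G or T carry \code{NA} ("undefined"); defined values are
#' non-negative, with high reactivity indicating single-strandedness.
#' Optional per-transcript \code{coverage} and \code{five_prime_coverage}
#' columns support configurable quality filters.
#'
#' @slot values \link[IRanges]{NumericList} of per-nucleotide reactivities,
#'   named by transcript id; \code{NA} marks undefined (G/T) positions.
#' @slot condition single string, e.g. \code{"control"} or \code{"treated"}.
#' @slot coverage,five_prime_coverage numeric vectors parallel to
#'   \code{values} (may be \code{NA} when unknown).
#'
#' @seealso [ReactivitySet()], [validateReactivity()], [motifWindowDelta()]
#' @aliases ReactivitySet-class
#' @exportClass ReactivitySet
setClass("ReactivitySet",
  representation(values = "NumericList", condition = "character",
                 coverage = "numeric", five_prime_coverage = "numeric"))

setValidity("ReactivitySet", function(object) {
  msg <- character()
  if (length(object@condition) != 1L || is.na(object@condition))
    msg <- c(msg, "condition must be a single non-NA string")
  ids <- names(object@values)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "profiles must be uniquely named by transcript id")
  v <- unlist(object@values, use.names = FALSE)
  if (length(v) && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "defined reactivity values must be >= 0")
  if (length(object@coverage) != length(object@values) ||
      length(object@five_prime_coverage) != length(object@values))
    msg <- c(msg, "coverage vectors must be parallel to the profiles")
  if (length(msg)) msg else TRUE
})
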
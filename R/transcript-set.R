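#' Construct a TranscriptSet
#'
#' @param sequences named character vector or \link[Biostrings]{DNAStringSet}
#'   of transcript sequences (DNA or RNA alphabet; U is mapped to T and
#'   lower case is raised).
#' @param anno data.frame (or DataFrame) with columns \code{transcript_id},
#'   \code{gene_id}, \code{len_5utr}, \code{len_cds}, \code{len_3utr} and
#'   \code{abundance}. Region lengths are nucleotides and must sum to the
#'   transcript length.
#'
#' @return a validated [TranscriptSet-class] object ordered as \code{anno}.
#' @examples
#' ts <- TranscriptSet(
#'   c(t1 = paste(rep("ACGT", 60), collapse = "")),
#'   data.frame(transcript_id = "t1", gene_id = "g1",
#'              len_5utr = 120, len_cds = 90, len_3utr = 30, abundance = 1))
#' regionLengths(ts)
#' @export
TranscriptSet <- function(sequences, anno) {
  if (is.character(sequences)) {
    sequences <- chartr("uU", "tT", sequences)
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (!is(sequences, "DNAStringSet"))
    stop("'sequences' must be a character vector or DNAStringSet")
  anno <- as.data.frame(anno)
  if (!"transcript_id" %in% colnames(anno))
    stop("annotation must carry a 'transcript_id' column")
  if (anyDuplicated(anno$transcript_id))
    stop("duplicate transcript_id in annotation")
  missing_seq <- setdiff(anno$transcript_id, names(sequences))
  if (length(missing_seq))
    stop("no sequence for transcript(s): ",
         paste(utils::head(missing_seq, 5), collapse = ", "))
  sequences <- sequences[anno$transcript_id]
  df <- S4Vectors::DataFrame(
    gene_id = as.character(anno$gene_id),
    len_5utr = as.integer(anno$len_5utr),
    len_cds = as.integer(anno$len_cds),
    len_3utr = as.integer(anno$len_3utr),
    abundance = as.numeric(anno$abundance),
    row.names = anno$transcript_id)
  new("TranscriptSet", sequences = sequences, anno = df)
}

#' @rdname TranscriptSet
#' @export
setMethod("transcriptIds", "TranscriptSet", function(x) names(x@sequences))

#' @rdname TranscriptSet
#' @export
setMethod("geneIds", "TranscriptSet",
  function(x) stats::setNames(x@anno$gene_id, rownames(x@anno)))

#' @rdname TranscriptSet
#' @export
setMethod("regionLengths", "TranscriptSet", function(x)
  as.data.frame(x@anno[, c("len_5utr", "len_cds", "len_3utr")]))

#' @rdname TranscriptSet
#' @export
setMethod("abundance", "TranscriptSet",
  function(x) stats::setNames(x@anno$abundance, rownames(x@anno)))

#' @rdname TranscriptSet
#' @export
setMethod("sequences", "TranscriptSet", function(x) x@sequences)

#' @rdname TranscriptSet
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@sequences))

#' @rdname TranscriptSet
#' @param i index (id, position or logical) to subset transcripts
#' @param j,drop ignored
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  new("TranscriptSet", sequences = x@sequences[i], anno = x@anno[i, , drop = FALSE])
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts,",
      length(unique(object@anno$gene_id)), "genes\n")
  w <- Biostrings::width(object@sequences)
  if (length(w))
    cat("  length range:", min(w), "-", max(w), "nt;",
        "5'UTR > 100 nt:", sum(object@anno$len_5utr > 100), "\n")
})

#' Region boundaries in 1-based transcript coordinates
#'
#' Returns, for one transcript, the inclusive 1-based start/end of the
#' 5'UTR, CDS and 3'UTR. Empty regions have end < start.
#'
#' @param x a [TranscriptSet]
#' @param id transcript id
#' @return data.frame with columns region, start, end
#' @export
regionBounds <- function(x, id) {
  stopifnot(is(x, "TranscriptSet"))
  a <- x@anno[id, ]
  if (nrow(a) != 1L || is.na(a$len_5utr)) stop("unknown transcript id: ", id)
  l5 <- a$len_5utr; lc <- a$len_cds; l3 <- a$len_3utr
  data.frame(
    region = c("5UTR", "CDS", "3UTR"),
    start = c(1L, l5 + 1L, l5 + lc + 1L),
    end = c(l5, l5 + lc, l5 + lc + l3),
    stringsAsFactors = FALSE)
}
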
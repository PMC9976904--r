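#' Construct a ReactivitySet
#'
#' @param values named list (or \link[IRanges]{NumericList}) of per-nucleotide
#'   reactivity vectors; \code{NA} marks undefined positions (bases G/T,
#'   which DMS does not probe).
#' @param condition single string naming the probing condition
#'   (conventionally \code{"control"} or \code{"treated"}).
#' @param coverage,five_prime_coverage optional numeric vectors parallel to
#'   \code{values}; default \code{NA} (unknown, passes any pass-through
#'   filter).
#' @return a validated [ReactivitySet-class]
#' @export
ReactivitySet <- function(values, condition,
                          coverage = rep(NA_real_, length(values)),
                          five_prime_coverage = rep(NA_real_, length(values))) {
  if (!is(values, "NumericList")) values <- IRanges::NumericList(values)
  new("ReactivitySet", values = values, condition = as.character(condition),
      coverage = as.numeric(coverage),
      five_prime_coverage = as.numeric(five_prime_coverage))
}

#' @rdname ReactivitySet
#' @param x a ReactivitySet
#' @export
setMethod("reactivityValues", "ReactivitySet", function(x) x@values)

#' @rdname ReactivitySet
#' @export
setMethod("condition", "ReactivitySet", function(x) x@condition)

#' @rdname ReactivitySet
#' @export
setMethod("transcriptIds", "ReactivitySet", function(x) names(x@values))

#' @rdname ReactivitySet
#' @export
setMethod("length", "ReactivitySet", function(x) length(x@values))

setMethod("show", "ReactivitySet", function(object) {
  v <- unlist(object@values, use.names = FALSE)
  cat("ReactivitySet (", object@condition, ") with ", length(object),
      " profiles, ", length(v), " positions (",
      round(100 * mean(is.na(v)), 1), "% undefined)\n", sep = "")
})

#' Check reactivity profiles against their transcripts
#'
#' Verifies that each profile has one value per nucleotide of the matching
#' transcript and that values are undefined (\code{NA}) exactly where the
#' base is not A or C.
#'
#' @param rs a [ReactivitySet]
#' @param ts a [TranscriptSet] carrying all profiled transcripts
#' @return invisibly \code{TRUE}; stops with an informative error otherwise
#' @export
validateReactivity <- function(rs, ts) {
  stopifnot(is(rs, "ReactivitySet"), is(ts, "TranscriptSet"))
  ids <- transcriptIds(rs)
  missing_t <- setdiff(ids, transcriptIds(ts))
  if (length(missing_t))
    stop("profiles without transcript: ", paste(utils::head(missing_t, 5), collapse = ", "))
  for (id in ids) {
    v <- rs@values[[id]]
    s <- as.character(ts@sequences[[id]])
    if (length(v) != nchar(s))
      stop("profile length ", length(v), " != transcript length ", nchar(s),
           " for ", id)
    ac <- strsplit(s, "", fixed = TRUE)[[1]] %in% c("A", "C")
    if (any(is.na(v) & ac) || any(!is.na(v) & !ac))
      stop("undefined positions do not match G/T bases for ", id)
  }
  invisible(TRUE)
}
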
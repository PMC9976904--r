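#' Read transcript sequences from FASTA
#'
#' Reads a standard FASTA file, uppercases the sequences and maps U to T so
#' that the in-package alphabet is DNA. Duplicate ids, empty sequences and
#' characters outside A/C/G/T(/U) are errors; for illegal characters the
#' message names the offending record and first offending position.
#'
#' @param path path to a FASTA file
#' @return named character vector of sequences, in file order
#' @export
readTranscriptFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGT]", seqs[[i]])
    if (bad > 0L)
      stop("illegal character '", substr(seqs[[i]], bad, bad), "' in record '",
           ids[[i]], "' at position ", bad)
  }
  stats::setNames(seqs, ids)
}

#' Read/write the transcript region annotation table
#'
#' Tab-separated with header; required columns \code{transcript_id},
#' \code{len_5utr}, \code{len_cds}, \code{len_3utr}, \code{gene_id},
#' \code{abundance}.
#'
#' @param path file path
#' @return data.frame
#' @export
readRegionTable <- function(path) {
  readTsv(path, required = c("transcript_id", "gene_id", "len_5utr",
                             "len_cds", "len_3utr", "abundance"))
}

#' Read per-nucleotide reactivity files
#'
#' The react dialect has two lines per record: line 1 is the transcript id,
#' line 2 the tab-separated per-nucleotide values with the literal token
#' \code{NA} at undefined (G/T) positions.
#'
#' @param path react file path
#' @param condition condition label attached to the returned set
#' @param transcripts optional [TranscriptSet]; when supplied every profile
#'   is checked for length and undefined-position agreement via
#'   [validateReactivity()]
#' @return a [ReactivitySet]
#' @export
readReact <- function(path, condition = "control", transcripts = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 2L != 0L)
    stop("react file must contain an even number of non-empty lines")
  ids <- lines[seq(1L, length(lines), by = 2L)]
  vals <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    lineno <- 2L * i
    toks <- strsplit(lines[[lineno]], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(toks))
    bad <- which(is.na(v) & toks != "NA")
    if (length(bad))
      stop("non-numeric token '", toks[bad[1]], "' on line ", lineno,
           " of ", path)
    vals[[i]] <- v
  }
  names(vals) <- ids
  rs <- ReactivitySet(vals, condition = condition)
  if (!is.null(transcripts)) validateReactivity(rs, transcripts)
  rs
}

#' @rdname readReact
#' @param rs a [ReactivitySet] to write
#' @param digits significant digits written (round-trip safe default)
#' @export
writeReact <- function(rs, path, digits = 17) {
  stopifnot(is(rs, "ReactivitySet"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in transcriptIds(rs)) {
    v <- rs@values[[id]]
    toks <- ifelse(is.na(v), "NA", formatC(v, digits = digits, format = "g"))
    writeLines(c(id, paste(toks, collapse = "\t")), con)
  }
  invisible(path)
}

#' Read/write TSV tables with header
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()]
#' enforcing a documented schema: \code{readTsv} errors when a required
#' column is missing, \code{writeTsv} writes tab-separated with header and
#' no quoting or row names. All transcript coordinates in package output
#' tables are 0-based half-open.
#'
#' @param path file path
#' @param required character vector of required column names
#' @export
readTsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, colnames(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname readTsv
#' @param df data.frame to write
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default analysis parameters
#'
#' All tunable thresholds of the two analysis arms with their default
#' values: the motif-window offsets (31..50 nt, inclusive distances from the
#' motif edge), the 50-nt region-boundary exclusion, the 10-nt motif length
#' with composition cap 7, the 20-nt/10-nt random sliding-window geometry,
#' the strict \code{>100} nt 5'UTR filter, the pulsed-SILAC fit-quality
#' cut-off (p < 0.1) and dependence FDR thresholds (0.1 / 0.7), and
#' pass-through coverage thresholds.
#'
#' @return named list of parameters
#' @export
defaultConfig <- function() {
  list(
    window_offsets = c(31L, 50L),
    min_edge_distance = 50L,
    motif_length = 10L,
    composition_cap = 7L,
    random_window_len = 20L,
    random_step = 10L,
    min_defined = 5L,
    min_5utr_len = 100L,
    min_coverage = -Inf,
    min_five_prime_coverage = -Inf,
    p_cut = 0.1,
    fdr_dependent = 0.1,
    fdr_independent = 0.7,
    peptide_protein_operator = "sum",
    difference_test = "z",
    seed = 1L)
}

#' Load and validate a YAML configuration
#'
#' Unknown keys are rejected; missing keys fall back to [defaultConfig()]
#' (fallbacks are reported via \code{message}). Window offsets must be a
#' non-negative, non-decreasing pair.
#'
#' @param path YAML file path, or \code{NULL}/a list of overrides
#' @return merged, validated parameter list
#' @export
loadConfig <- function(path = NULL) {
  defaults <- defaultConfig()
  user <- if (is.null(path)) list()
          else if (is.list(path)) path
          else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing_keys <- setdiff(names(defaults), names(user))
  if (length(user) && length(missing_keys))
    message("config: using defaults for ", paste(missing_keys, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  off <- cfg$window_offsets
  if (length(off) != 2L || any(off < 0) || off[1] > off[2])
    stop("window_offsets must be a non-negative, non-decreasing pair")
  for (k in c("min_edge_distance", "motif_length", "composition_cap",
              "random_window_len", "random_step", "min_defined", "min_5utr_len"))
    if (cfg[[k]] < 0) stop(k, " must be non-negative")
  for (k in c("p_cut", "fdr_dependent", "fdr_independent"))
    if (cfg[[k]] < 0 || cfg[[k]] > 1) stop(k, " must be in [0,1]")
  if (!cfg$peptide_protein_operator %in% c("sum", "median"))
    stop("peptide_protein_operator must be 'sum' or 'median'")
  if (!cfg$difference_test %in% c("z", "welch"))
    stop("difference_test must be 'z' or 'welch'")
  cfg
}
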
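# md5 of the serialized config (hashing a temp file via tools::md5sum)
.configHash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

.writeManifest <- function(out_dir, stage, cfg, inputs, counts) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("agmotif")),
    config = cfg,
    config_hash = .configHash(cfg),
    seed = cfg$seed,
    input_checksums = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    counts = as.list(counts),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# pair i-th motif with i-th random window inside each transcript x region
.pairStats <- function(motif_stats, random_stats) {
  key <- function(d) paste(d$transcript_id, d$region, d$side)
  m <- motif_stats[order(key(motif_stats), motif_stats$motif_start), ]
  r <- random_stats[order(key(random_stats), random_stats$motif_start), ]
  m$pair <- stats::ave(seq_len(nrow(m)), key(m), FUN = seq_along)
  r$pair <- stats::ave(seq_len(nrow(r)), key(r), FUN = seq_along)
  mk <- paste(key(m), m$pair); rk <- paste(key(r), r$pair)
  shared <- intersect(mk, rk)
  m <- m[match(shared, mk), ]; r <- r[match(shared, rk), ]
  ok <- m$valid & r$valid & is.finite(m$delta) & is.finite(r$delta)
  list(motif = m[ok, ], random = r[ok, ])
}

#' Run the motif-anchored structure analysis end to end
#'
#' Stage order: most-abundant-transcript selection (5'UTR > 100 nt,
#' coverage thresholds) -> non-overlapping motif scan per region ->
#' up-/downstream offset-window reactivity deltas -> matched random
#' sliding-window controls -> paired two-sided Wilcoxon motif-vs-random
#' test per region and side -> structure gain/loss classification -> and,
#' when a translation-rate table is supplied, the structure/translation
#' association join. Writes \code{motifs.tsv}, \code{window_stats.tsv},
#' \code{test_summary.tsv}, optionally \code{association.tsv}, and a
#' \code{manifest.json} recording configuration, seed, input checksums and
#' the counts at every filter step. All coordinates in output tables are
#' 0-based half-open.
#'
#' @param out_dir output directory (created if needed)
#' @param transcripts a [TranscriptSet], or \code{NULL} to read from
#'   \code{fasta} + \code{regions}
#' @param ctrl,treat [ReactivitySet]s, or \code{NULL} to read from
#'   \code{react_ctrl}/\code{react_treat}
#' @param fasta,regions,react_ctrl,react_treat input file paths (used when
#'   the corresponding object is \code{NULL})
#' @param rate_table optional data.frame with \code{gene_id} and
#'   \code{log2fc} (e.g. from [runPsilacPipeline()]) for the association
#' @param config \code{NULL}, a YAML path or a named list of overrides
#'   (see [defaultConfig()])
#' @param motif_class motif class to scan ("R10" or "GC5")
#' @param regions_scanned annotated regions to analyse
#' @return invisibly, a list with the main tables and the manifest
#' @export
runStructurePipeline <- function(out_dir, transcripts = NULL, ctrl = NULL,
                                 treat = NULL, fasta = NULL, regions = NULL,
                                 react_ctrl = NULL, react_treat = NULL,
                                 rate_table = NULL, config = NULL,
                                 motif_class = "R10",
                                 regions_scanned = c("5UTR", "CDS", "3UTR")) {
  cfg <- loadConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  if (is.null(transcripts)) {
    inputs <- c(inputs, fasta, regions)
    seqs <- readTranscriptFasta(fasta)
    anno <- readRegionTable(regions)
    transcripts <- TranscriptSet(seqs, anno)
  }
  if (is.null(ctrl)) { inputs <- c(inputs, react_ctrl)
    ctrl <- readReact(react_ctrl, "control", transcripts) }
  if (is.null(treat)) { inputs <- c(inputs, react_treat)
    treat <- readReact(react_treat, "treated", transcripts) }
  counts <- c(transcripts_input = length(transcripts))

  primary <- selectPrimaryTranscripts(
    transcripts, ctrl, treat, min_5utr_len = cfg$min_5utr_len,
    min_coverage = cfg$min_coverage,
    min_five_prime_coverage = cfg$min_five_prime_coverage)
  counts["transcripts_primary"] <- length(primary)
  message("structure: ", counts["transcripts_input"], " transcripts in, ",
          counts["transcripts_primary"], " primary retained")

  hits <- scanMotifs(primary, motif_class = motif_class,
                     motif_length = cfg$motif_length,
                     composition_cap = cfg$composition_cap,
                     min_edge_distance = cfg$min_edge_distance,
                     regions = regions_scanned)
  for (r in regions_scanned)
    counts[paste0("motifs_", r)] <- sum(S4Vectors::mcols(hits)$region == r)
  message("structure: ", length(hits), " ", motif_class, " motifs (",
          paste(regions_scanned, counts[paste0("motifs_", regions_scanned)],
                sep = ": ", collapse = ", "), ")")

  rand <- matchedRandomWindows(primary, hits,
                               window_len = cfg$random_window_len,
                               step = cfg$random_step,
                               min_edge_distance = cfg$min_edge_distance,
                               seed = cfg$seed)
  ms <- motifWindowDelta(ctrl, treat, hits, side = "both",
                         offsets = cfg$window_offsets,
                         min_defined = cfg$min_defined)
  rsx <- motifWindowDelta(ctrl, treat, rand, side = "both",
                          offsets = cfg$window_offsets,
                          min_defined = cfg$min_defined)
  counts["windows_motif_valid"] <- sum(ms$valid & is.finite(ms$delta))
  counts["windows_random_valid"] <- sum(rsx$valid & is.finite(rsx$delta))

  summ <- list()
  for (r in unique(ms$region)) for (sd in unique(ms$side)) {
    pr <- .pairStats(ms[ms$region == r & ms$side == sd, ],
                     rsx[rsx$region == r & rsx$side == sd, ])
    if (nrow(pr$motif) < 3L) next
    tst <- tryCatch(compareMotifVsRandom(pr$motif, pr$random, paired = TRUE),
                    error = function(e) NULL)
    if (is.null(tst)) next
    summ[[length(summ) + 1L]] <- data.frame(
      region = r, side = sd, n_pairs = tst$n_motif, p = tst$p,
      median_motif_delta = tst$median_motif,
      median_random_delta = tst$median_random, stringsAsFactors = FALSE)
  }
  test_summary <- if (length(summ)) do.call(rbind, summ) else
    data.frame(region = character(), side = character(), n_pairs = integer(),
               p = numeric(), median_motif_delta = numeric(),
               median_random_delta = numeric())

  motifs_df <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(hits)),
    gene_id = S4Vectors::mcols(hits)$gene_id,
    region = S4Vectors::mcols(hits)$region,
    start = GenomicRanges::start(hits) - 1L,       # 0-based half-open
    end = GenomicRanges::end(hits),
    motif_class = S4Vectors::mcols(hits)$motif_class,
    seq = S4Vectors::mcols(hits)$seq, stringsAsFactors = FALSE)
  writeTsv(motifs_df, file.path(out_dir, "motifs.tsv"))
  ws_all <- rbind(ms, rsx)
  ws_all$structure_class <- classifyStructureChange(ws_all$delta)
  writeTsv(ws_all, file.path(out_dir, "window_stats.tsv"))
  writeTsv(test_summary, file.path(out_dir, "test_summary.tsv"))

  assoc <- NULL
  if (!is.null(rate_table)) {
    down <- ms[ms$side == "downstream", ]
    assoc <- joinStructureTranslation(down, rate_table)
    counts["association_records"] <- nrow(assoc$records)
    counts["association_genes_dropped"] <- assoc$n_dropped
    writeTsv(assoc$records, file.path(out_dir, "association.tsv"))
  }
  manifest <- .writeManifest(out_dir, "structure", cfg, inputs, counts)
  invisible(list(motifs = motifs_df, window_stats = ws_all,
                 test_summary = test_summary, association = assoc,
                 manifest = manifest))
}

#' Run the pulsed-SILAC translation-rate analysis end to end
#'
#' Stage order: (optional) peptide-to-protein aggregation -> fraction
#' heavy -> per-protein, per-condition log-linear rate fit -> fit-quality
#' filter (F-test p < 0.1 in both conditions) -> condition comparison
#' (difference, log2 fold change, FDR) -> dependence classification
#' (FDR < 0.1 dependent, > 0.7 independent). Writes \code{rates.tsv},
#' \code{dependence.tsv} and \code{manifest.json} with the input /
#' passing-filter / dependent / independent counts.
#'
#' @param out_dir output directory
#' @param data long-format intensity data.frame (columns \code{protein_id}
#'   [, \code{peptide_seq}], \code{condition}, \code{time_h},
#'   \code{replicate}, \code{intensity_light}, \code{intensity_heavy}) or a
#'   TSV path
#' @param config \code{NULL}, a YAML path or a named list of overrides
#' @return invisibly, a list with rates, the labelled dependence table and
#'   the manifest
#' @export
runPsilacPipeline <- function(out_dir, data, config = NULL) {
  cfg <- loadConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  if (is.character(data)) {
    inputs <- data
    data <- readTsv(data, required = c("protein_id", "condition", "time_h",
                                       "replicate", "intensity_light",
                                       "intensity_heavy"))
  }
  n_excl <- 0L
  if ("peptide_seq" %in% colnames(data)) {
    agg <- aggregatePeptidesToProteins(data,
                                       operator = cfg$peptide_protein_operator)
    data <- agg$table
    n_excl <- agg$n_excluded_peptides
  }
  data$f_h <- fractionHeavy(data$intensity_heavy, data$intensity_light)
  fitCond <- function(cond) {
    d <- data[data$condition == cond, ]
    sp <- split(d, d$protein_id)
    lapply(sp, function(x) fitTurnoverRate(x$time_h, x$f_h))
  }
  fits_ctrl <- fitCond("control")
  fits_treat <- fitCond("treated")
  filt <- filterByFitQuality(fits_ctrl, fits_treat, p_cut = cfg$p_cut)
  message("psilac: input ", filt$counts[["input"]], " proteins, p < ",
          cfg$p_cut, " in both conditions: ", filt$counts[["retained"]],
          ", removed: ", filt$counts[["removed"]])
  records <- compareConditions(fits_ctrl, fits_treat,
                               proteins = filt$retained,
                               method = cfg$difference_test)
  records <- classifyDependence(records,
                                fdr_dependent = cfg$fdr_dependent,
                                fdr_independent = cfg$fdr_independent)
  counts <- c(filt$counts, excluded_peptides = n_excl,
              dependent = sum(records$label == "dependent"),
              independent = sum(records$label == "independent"),
              unclassified = sum(records$label == "unclassified"))
  message("psilac: dependent ", counts[["dependent"]], ", independent ",
          counts[["independent"]], " (FDR thresholds ", cfg$fdr_dependent,
          "/", cfg$fdr_independent, ")")
  rates <- do.call(rbind, lapply(names(fits_ctrl), function(id) {
    rbind(
      data.frame(protein_id = id, condition = "control",
                 k_per_h = fits_ctrl[[id]]$k, offset = fits_ctrl[[id]]$offset,
                 p_slope = fits_ctrl[[id]]$p_slope,
                 n_points = fits_ctrl[[id]]$n_points_used,
                 stringsAsFactors = FALSE),
      if (id %in% names(fits_treat))
        data.frame(protein_id = id, condition = "treated",
                   k_per_h = fits_treat[[id]]$k, offset = fits_treat[[id]]$offset,
                   p_slope = fits_treat[[id]]$p_slope,
                   n_points = fits_treat[[id]]$n_points_used,
                   stringsAsFactors = FALSE))
  }))
  writeTsv(rates, file.path(out_dir, "rates.tsv"))
  dep_out <- records
  dep_out$gene_id <- dep_out$protein_id   # one protein group per gene here
  writeTsv(dep_out, file.path(out_dir, "dependence.tsv"))
  manifest <- .writeManifest(out_dir, "psilac", cfg, inputs, counts)
  invisible(list(rates = rates, dependence = dep_out, manifest = manifest))
}
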
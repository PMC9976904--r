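#' @importFrom GenomicRanges GRanges seqnames start end width
NULL

# inclusive 1-based scan limits for one region under an edge-distance rule
.scanLimits <- function(rstart, rend, edge, len) {
  c(lo = rstart + edge, hi = rend - edge - len + 1L)
}

# step-grid candidate starts (anchored at the region start) within the limits
.gridCandidates <- function(rstart, rend, window_len, step, edge) {
  lim <- .scanLimits(rstart, rend, edge, as.integer(window_len))
  if (lim[["lo"]] > lim[["hi"]]) return(integer(0))
  k0 <- ceiling((lim[["lo"]] - rstart) / step)
  k1 <- (lim[["hi"]] - rstart) %/% step
  if (k1 < k0) integer(0) else as.integer(rstart + step * (k0:k1))
}

#' Keep the most abundant transcript per gene, with quality filters
#'
#' Retains, per gene, the single most abundant transcript (ties broken by
#' lexicographically smallest transcript id), then filters to transcripts
#' whose 5'UTR is strictly longer than \code{min_5utr_len} nt and which pass
#' the coverage thresholds in both reactivity conditions (thresholds default
#' to pass-through; profiles with unknown coverage always pass).
#'
#' @param x a [TranscriptSet]
#' @param ctrl,treat optional [ReactivitySet]s; when given, transcripts must
#'   be present in both and pass coverage thresholds
#' @param min_5utr_len minimum 5'UTR length, strict inequality (default 100)
#' @param min_coverage,min_five_prime_coverage coverage thresholds
#'   (default \code{-Inf} = no filter)
#' @return filtered [TranscriptSet]
#' @export
selectPrimaryTranscripts <- function(x, ctrl = NULL, treat = NULL,
                                     min_5utr_len = 100L,
                                     min_coverage = -Inf,
                                     min_five_prime_coverage = -Inf) {
  stopifnot(is(x, "TranscriptSet"))
  ids <- transcriptIds(x)
  ab <- abundance(x)
  gene <- geneIds(x)
  ord <- order(gene, -ab, ids)           # per gene: abundance desc, id asc
  keep_primary <- ids[ord][!duplicated(gene[ord])]
  keep <- intersect(ids, keep_primary)   # restore original order
  keep <- keep[x@anno[keep, "len_5utr"] > min_5utr_len]
  passCov <- function(rs, id) {
    i <- match(id, transcriptIds(rs))
    if (anyNA(i)) return(!is.na(i))
    cov <- rs@coverage[i]; f5 <- rs@five_prime_coverage[i]
    (is.na(cov) | cov >= min_coverage) &
      (is.na(f5) | f5 >= min_five_prime_coverage)
  }
  if (!is.null(ctrl)) keep <- keep[passCov(ctrl, keep)]
  if (!is.null(treat)) keep <- keep[passCov(treat, keep)]
  x[keep]
}

#' @describeIn scanMotifs Greedy non-overlapping motif scan on a
#'   [TranscriptSet].
#'
#' Scans each annotated region left to right for fixed-length windows over
#' the motif alphabet: class \code{"R10"} requires all bases in \{A,G\}
#' (purines) with at most \code{composition_cap} A's and at most
#' \code{composition_cap} G's (default 7/10, excluding near-homopolymers);
#' class \code{"GC5"} is the analogous window over \{G,C\}. Accepted windows
#' are non-overlapping (greedy left-to-right within each region) and must
#' lie at least \code{min_edge_distance} nt from the region's boundaries,
#' which for terminal regions includes the transcript ends.
#'
#' @param motif_class "R10" (purine) or "GC5" (G/C)
#' @param motif_length window length (default 10)
#' @param composition_cap maximum count of either single base within the
#'   window (default 7; the rule is count(A) <= cap AND count(G) <= cap for
#'   R10, analogously for GC5)
#' @param min_edge_distance minimum distance from region boundaries and
#'   transcript ends (default 50 nt)
#' @param regions which annotated regions to scan
#' @return \link[GenomicRanges]{GRanges} in 1-based transcript coordinates
#'   (seqnames = transcript id) with metadata columns \code{gene_id},
#'   \code{region}, \code{motif_class} and \code{seq}
#' @export
setMethod("scanMotifs", "TranscriptSet",
function(x, motif_class = c("R10", "GC5"), motif_length = 10L,
         composition_cap = 7L, min_edge_distance = 50L,
         regions = c("5UTR", "CDS", "3UTR")) {
  motif_class <- match.arg(motif_class)
  alpha <- if (motif_class == "R10") c("A", "G") else c("G", "C")
  L <- as.integer(motif_length)
  out <- list()
  gene <- geneIds(x)
  for (id in transcriptIds(x)) {
    s <- strsplit(as.character(x@sequences[[id]]), "", fixed = TRUE)[[1]]
    inA <- cumsum(c(0L, s %in% alpha))
    cnt1 <- cumsum(c(0L, s == alpha[1]))           # A for R10, G for GC5
    windowOK <- function(p) {
      if (inA[p + L] - inA[p] != L) return(FALSE)
      c1 <- cnt1[p + L] - cnt1[p]
      c1 <= composition_cap && (L - c1) <= composition_cap
    }
    rb <- regionBounds(x, id)
    for (r in seq_len(nrow(rb))) {
      if (!rb$region[r] %in% regions) next
      lim <- .scanLimits(rb$start[r], rb$end[r], min_edge_distance, L)
      p <- lim[["lo"]]
      while (p <= lim[["hi"]]) {
        if (windowOK(p)) {
          out[[length(out) + 1L]] <- data.frame(
            transcript_id = id, start = p, region = rb$region[r],
            seq = paste(s[p:(p + L - 1L)], collapse = ""),
            stringsAsFactors = FALSE)
          p <- p + L
        } else p <- p + 1L
      }
    }
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = character(), region = character(),
      motif_class = character(), seq = character())
    return(gr)
  }
  df <- do.call(rbind, out)
  GenomicRanges::GRanges(
    seqnames = factor(df$transcript_id, levels = transcriptIds(x)),
    ranges = IRanges::IRanges(start = df$start, width = L),
    gene_id = unname(gene[df$transcript_id]), region = df$region,
    motif_class = motif_class, seq = df$seq)
})

#' Sample random control windows from one transcript region
#'
#' Candidate windows lie on a step grid anchored at the region start
#' (start offsets divisible by \code{step}), are \code{window_len} nt long,
#' and respect the same \code{min_edge_distance} boundary rule as the motif
#' scan. \code{n} windows are drawn uniformly without replacement; if fewer
#' candidates exist, all are returned with a warning.
#'
#' @param x a [TranscriptSet]
#' @param transcript_id transcript to sample from
#' @param n number of windows requested
#' @param region region to sample within
#' @param window_len,step window geometry (defaults 20 nt / 10 nt)
#' @param min_edge_distance boundary exclusion (default 50 nt)
#' @param seed optional integer; when given, sampling is seeded locally and
#'   reproducible
#' @return \link[GenomicRanges]{GRanges} with \code{motif_class = "random"}
#' @export
sampleRandomWindows <- function(x, transcript_id, n, region = "5UTR",
                                window_len = 20L, step = 10L,
                                min_edge_distance = 50L, seed = NULL) {
  stopifnot(is(x, "TranscriptSet"))
  rb <- regionBounds(x, transcript_id)
  rb <- rb[rb$region == region, ]
  if (nrow(rb) != 1L) stop("unknown region: ", region)
  cand <- .gridCandidates(rb$start, rb$end, window_len, step,
                          min_edge_distance)
  if (length(cand) < n) {
    warning("only ", length(cand), " eligible windows for ", transcript_id,
            " ", region, "; returning all")
    pick <- cand
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    pick <- sort(sample(cand, n))
  }
  if (!length(pick)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = character(), region = character(),
      motif_class = character(), seq = character())
    return(gr)
  }
  seqs <- substring(as.character(x@sequences[[transcript_id]]),
                    pick, pick + window_len - 1L)
  GenomicRanges::GRanges(
    seqnames = factor(transcript_id, levels = transcriptIds(x)),
    ranges = IRanges::IRanges(start = pick, width = as.integer(window_len)),
    gene_id = unname(geneIds(x)[transcript_id]), region = region,
    motif_class = "random", seq = seqs)
}

#' Random windows matched in number to a motif hit set
#'
#' For every (transcript, region) present in \code{hits}, draws the same
#' number of random windows from that transcript and region via
#' [sampleRandomWindows()]. One seed controls the whole draw.
#'
#' @param x a [TranscriptSet]
#' @param hits GRanges of motif hits from [scanMotifs()]
#' @inheritParams sampleRandomWindows
#' @return GRanges of random windows
#' @export
matchedRandomWindows <- function(x, hits, window_len = 20L, step = 10L,
                                 min_edge_distance = 50L, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  key <- paste(GenomicRanges::seqnames(hits), S4Vectors::mcols(hits)$region)
  counts <- table(key)
  anno <- as.data.frame(x@anno)
  gene <- geneIds(x)
  tid_out <- reg_out <- character(0); start_out <- integer(0)
  for (k in names(counts)) {
    sp <- strsplit(k, " ", fixed = TRUE)[[1]]
    tid <- sp[1]; reg <- sp[2]
    a <- anno[tid, ]
    rs <- switch(reg, "5UTR" = 1L, "CDS" = a$len_5utr + 1L,
                 "3UTR" = a$len_5utr + a$len_cds + 1L)
    re <- switch(reg, "5UTR" = a$len_5utr, "CDS" = a$len_5utr + a$len_cds,
                 "3UTR" = a$len_5utr + a$len_cds + a$len_3utr)
    cand <- .gridCandidates(rs, re, window_len, step, min_edge_distance)
    n <- counts[[k]]
    pick <- if (length(cand) < n) {
      warning("only ", length(cand), " eligible windows for ", tid, " ", reg,
              "; returning all")
      cand
    } else sort(sample(cand, n))
    tid_out <- c(tid_out, rep(tid, length(pick)))
    reg_out <- c(reg_out, rep(reg, length(pick)))
    start_out <- c(start_out, pick)
  }
  seqs <- character(length(start_out))
  for (tid in unique(tid_out)) {
    i <- tid_out == tid
    seqs[i] <- substring(as.character(x@sequences[[tid]]), start_out[i],
                         start_out[i] + window_len - 1L)
  }
  GenomicRanges::GRanges(
    seqnames = factor(tid_out, levels = transcriptIds(x)),
    ranges = IRanges::IRanges(start = start_out,
                              width = as.integer(window_len)),
    gene_id = unname(gene[tid_out]), region = reg_out,
    motif_class = "random", seq = seqs)
}

#' Mean reactivity over a window
#'
#' Arithmetic mean of the defined (A/C) reactivities inside a window given
#' in 0-based half-open transcript coordinates (the package's external
#' coordinate convention). Returns \code{NA} when fewer than
#' \code{min_defined} positions are defined.
#'
#' @param rs a [ReactivitySet]
#' @param transcript_id transcript
#' @param start,end 0-based half-open window
#' @param min_defined minimum number of defined positions (default 5)
#' @return mean reactivity, or \code{NA}
#' @export
windowMeanReactivity <- function(rs, transcript_id, start, end, min_defined = 5L) {
  stopifnot(is(rs, "ReactivitySet"))
  v <- rs@values[[transcript_id]]
  if (is.null(v)) stop("no profile for ", transcript_id)
  if (start < 0 || end <= start || end > length(v))
    stop("window [", start, ",", end, ") out of range for ", transcript_id)
  w <- v[(start + 1L):end]
  nd <- sum(!is.na(w))
  if (nd < min_defined) return(NA_real_)
  mean(w, na.rm = TRUE)
}

#' Differential reactivity in offset windows flanking motifs
#'
#' For each motif (or random window) computes the mean control and treated
#' reactivity in a window at inclusive nucleotide distances
#' \code{offsets[1]..offsets[2]} from the motif edge — downstream of the
#' last base and/or upstream of the first base — and their difference
#' \code{delta = mean_treat - mean_ctrl}. Negative delta means reduced DMS
#' reactivity, i.e. gain of structure. Windows extending beyond the
#' transcript are flagged invalid (\code{valid = FALSE}) rather than
#' dropped.
#'
#' @param ctrl,treat [ReactivitySet]s for the two conditions
#' @param hits GRanges from [scanMotifs()] / [sampleRandomWindows()]
#' @param side "downstream", "upstream" or "both"
#' @param offsets inclusive distance window from the motif edge
#'   (default c(31, 50), a 20-nt window)
#' @param min_defined minimum defined A/C positions per window (default 5)
#' @return data.frame with one row per (motif, side): ids, 0-based motif
#'   coordinates, side, 0-based half-open window, \code{mean_ctrl},
#'   \code{mean_treat}, \code{delta}, \code{n_defined}, \code{valid}
#' @export
motifWindowDelta <- function(ctrl, treat, hits,
                             side = c("downstream", "upstream", "both"),
                             offsets = c(31L, 50L), min_defined = 5L) {
  side <- match.arg(side)
  sides <- if (side == "both") c("upstream", "downstream") else side
  n <- length(hits)
  ids <- as.character(GenomicRanges::seqnames(hits))
  s1 <- GenomicRanges::start(hits)                  # 1-based inclusive
  e1 <- GenomicRanges::end(hits)
  mc_hits <- S4Vectors::mcols(hits)
  valsC <- valsT <- list()                          # per-transcript cache
  for (id in unique(ids)) {
    valsC[[id]] <- ctrl@values[[id]]
    valsT[[id]] <- treat@values[[id]]
  }
  out <- vector("list", length(sides))
  for (si in seq_along(sides)) {
    sd <- sides[si]
    if (sd == "downstream") {                       # 0-based half-open window
      w0 <- e1 + offsets[1] - 1L; w1 <- e1 + offsets[2]
    } else {
      w0 <- s1 - 1L - offsets[2]; w1 <- s1 - offsets[1]
    }
    mc <- mt <- rep(NA_real_, n)
    nd <- rep(NA_integer_, n)
    ok <- logical(n)
    for (i in seq_len(n)) {
      vC <- valsC[[ids[i]]]
      ok[i] <- w0[i] >= 0 && w1[i] <= length(vC)
      if (!ok[i]) next
      wc <- vC[(w0[i] + 1L):w1[i]]
      wt <- valsT[[ids[i]]][(w0[i] + 1L):w1[i]]
      def <- !is.na(wc) & !is.na(wt)
      nd[i] <- sum(def)
      if (nd[i] >= min_defined) { mc[i] <- mean(wc[def]); mt[i] <- mean(wt[def]) }
    }
    out[[si]] <- data.frame(
      transcript_id = ids, gene_id = mc_hits$gene_id, region = mc_hits$region,
      motif_class = mc_hits$motif_class,
      motif_start = s1 - 1L, motif_end = e1,        # 0-based half-open
      side = sd, win_start = w0, win_end = w1,
      mean_ctrl = mc, mean_treat = mt, delta = mt - mc,
      n_defined = nd, valid = ok, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  # original interleaved order (per hit: upstream then downstream)
  if (length(sides) == 2L)
    res <- res[order(rep(seq_len(n), times = 2L),
                     rep(seq_along(sides), each = n)), ]
  rownames(res) <- NULL
  res
}

#' Compare motif-window deltas against matched random windows
#'
#' Two-sided Wilcoxon test (paired by default, following the matched-random
#' design) of the motif-window reactivity changes against the random-window
#' changes. Invalid or undefined windows are removed; in paired mode the
#' two groups are paired by row order after per-transcript matching and
#' must have equal sizes.
#'
#' @param motif_stats,random_stats data.frames from [motifWindowDelta()]
#' @param paired use the paired signed-rank test (default TRUE)
#' @return list with \code{p}, group medians, group sizes and the mode
#' @export
compareMotifVsRandom <- function(motif_stats, random_stats, paired = TRUE) {
  mm <- motif_stats[motif_stats$valid & is.finite(motif_stats$delta), ]
  rr <- random_stats[random_stats$valid & is.finite(random_stats$delta), ]
  if (!nrow(mm) || !nrow(rr)) stop("empty group after removing invalid windows")
  if (paired) {
    if (nrow(mm) != nrow(rr))
      stop("paired comparison requires equal group sizes (",
           nrow(mm), " vs ", nrow(rr), ")")
    wt <- wilcoxonTest(mm$delta, rr$delta, mode = "paired")
  } else {
    wt <- wilcoxonTest(mm$delta, rr$delta, mode = "unpaired")
  }
  list(p = wt$p, median_motif = stats::median(mm$delta),
       median_random = stats::median(rr$delta),
       n_motif = nrow(mm), n_random = nrow(rr),
       mode = if (paired) "paired" else "unpaired")
}

#' Classify a reactivity change as structure gain or loss
#'
#' DMS reactivity measures single-strandedness, so a drop in reactivity
#' (delta < 0) is a gain of structure and a rise (delta > 0) a loss;
#' exactly zero is excluded.
#'
#' @param delta numeric vector of reactivity changes (treated - control)
#' @return character vector: "gain", "loss" or "excluded"
#' @export
classifyStructureChange <- function(delta) {
  out <- rep(NA_character_, length(delta))
  out[delta < 0] <- "gain"
  out[delta > 0] <- "loss"
  out[delta == 0] <- "excluded"
  out
}

#' Join motif-window structure changes with translation-rate changes
#'
#' Inner join of per-gene window statistics with a translation-rate table
#' (e.g. the output of [classifyDependence()]), producing one association
#' record per (gene, motif window) with the structure class and the log2
#' fold change of the translation rate. Genes absent from the rate table
#' are dropped and counted in the join report.
#'
#' @param window_stats data.frame from [motifWindowDelta()] (valid
#'   downstream windows are typically pre-selected by the caller)
#' @param rate_table data.frame with columns \code{gene_id} and
#'   \code{log2fc}
#' @return list with \code{records} (the association table),
#'   \code{summary} (median log2fc per structure class) and
#'   \code{n_dropped}
#' @export
joinStructureTranslation <- function(window_stats, rate_table) {
  ws <- window_stats[window_stats$valid & is.finite(window_stats$delta), ]
  ws$structure_class <- classifyStructureChange(ws$delta)
  ws <- ws[ws$structure_class %in% c("gain", "loss"), ]
  hit <- ws$gene_id %in% rate_table$gene_id
  rec <- merge(ws[hit, c("gene_id", "transcript_id", "motif_start", "side",
                         "delta", "structure_class")],
               rate_table[, c("gene_id", "log2fc")], by = "gene_id")
  if (!nrow(rec)) stop("join produced zero rows: no shared gene identifiers")
  summ <- stats::aggregate(log2fc ~ structure_class, data = rec, FUN = stats::median)
  names(summ)[2] <- "median_log2fc"
  list(records = rec, summary = summ, n_dropped = sum(!hit))
}
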
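# transcript with a given 5'UTR payload centred between poly-C flanks
flanked_tx <- function(payload, flank = 55L, cds = 60L, utr3 = 60L) {
  seqs <- paste0(strrep("C", flank), payload, strrep("C", flank),
                 strrep("C", cds), strrep("C", utr3))
  l5 <- 2L * flank + nchar(payload)
  TranscriptSet(c(tx = seqs),
    data.frame(transcript_id = "tx", gene_id = "gx", len_5utr = l5,
               len_cds = cds, len_3utr = utr3, abundance = 1))
}

test_that("primary-transcript selection keeps the most abundant isoform", {
  mk <- function(id, gene, ab, l5 = 150L) {
    data.frame(transcript_id = id, gene_id = gene, len_5utr = l5,
               len_cds = 30L, len_3utr = 20L, abundance = ab)
  }
  seqs <- c(setNames(rep(strrep("A", 200), 2), c("tA", "tB")),
            tC = strrep("A", 150), tD = strrep("A", 200))
  ts <- TranscriptSet(seqs, rbind(
    mk("tA", "g1", 5), mk("tB", "g1", 10),
    mk("tC", "g2", 3, l5 = 100L),          # exactly 100 nt: excluded
    mk("tD", "g3", 2)))
  keep <- selectPrimaryTranscripts(ts)
  expect_setequal(transcriptIds(keep), c("tB", "tD"))

  # abundance tie: lexicographically smallest transcript id wins
  ts2 <- TranscriptSet(seqs[1:2], rbind(mk("tA", "g1", 5), mk("tB", "g1", 5)))
  expect_identical(transcriptIds(selectPrimaryTranscripts(ts2)), "tA")
})

test_that("coverage thresholds filter primary transcripts when configured", {
  seqs <- setNames(rep(strrep("A", 200), 2), c("t1", "t2"))
  ts <- TranscriptSet(seqs, data.frame(
    transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"), len_5utr = 150L,
    len_cds = 30L, len_3utr = 20L, abundance = 1))
  prof <- lapply(setNames(1:2, c("t1", "t2")), function(i) rep(0.5, 200))
  rs <- ReactivitySet(prof, "control", coverage = c(10, 2),
                      five_prime_coverage = c(5, 5))
  expect_setequal(transcriptIds(selectPrimaryTranscripts(ts, rs, rs)),
                  c("t1", "t2"))   # pass-through default
  expect_identical(
    transcriptIds(selectPrimaryTranscripts(ts, rs, rs, min_coverage = 5)),
    "t1")
})

test_that("motif scan applies alphabet, composition cap and edge rules", {
  hits <- scanMotifs(flanked_tx("AAGGAGAGGA"))
  expect_length(hits, 1L)
  expect_identical(S4Vectors::mcols(hits)$seq, "AAGGAGAGGA")
  expect_identical(S4Vectors::mcols(hits)$region, "5UTR")
  expect_equal(GenomicRanges::start(hits), 56L)   # 1-based, after 55-nt flank

  # 8 A's exceeds the 7/10 cap
  expect_length(scanMotifs(flanked_tx("AAAAAAAAGG")), 0L)
  # cap is configurable
  expect_length(scanMotifs(flanked_tx("AAAAAAAAGG"), composition_cap = 8L), 1L)

  # a 15-nt pure-purine run yields exactly one greedy non-overlapping hit
  expect_length(scanMotifs(flanked_tx(strrep("AG", 8))), 1L)

  # motif too close to the 5' end is rejected
  near_end <- flanked_tx("AAGGAGAGGA", flank = 30L)
  expect_length(scanMotifs(near_end), 0L)
})

test_that("scanner equals the brute-force oracle on seeded transcripts", {
  for (seed in 1:40) {
    ts <- random_transcript_set(seed)
    hits <- scanMotifs(ts)
    orc <- oracle_scan(ts, "tx")
    if (is.null(orc)) {
      expect_length(hits, 0L)
    } else {
      expect_identical(unname(GenomicRanges::start(hits)), orc$start)
      expect_identical(S4Vectors::mcols(hits)$region, orc$region)
    }
    # no retained motif within 50 nt of any region boundary (exhaustive)
    if (length(hits)) {
      rb <- regionBounds(ts, "tx")
      for (i in seq_along(hits)) {
        b <- rb[rb$region == S4Vectors::mcols(hits)$region[i], ]
        expect_gte(GenomicRanges::start(hits)[i] - b$start, 50)
        expect_gte(b$end - GenomicRanges::end(hits)[i], 50)
      }
    }
  }
})

test_that("window means average defined positions only", {
  ts <- flanked_tx("AAGGAGAGGA")
  n <- sum(regionLengths(ts)[1, ])
  set.seed(2)
  s <- strsplit(as.character(sequences(ts)[[1]]), "")[[1]]
  v <- ifelse(s %in% c("A", "C"), runif(n), NA)
  rs <- ReactivitySet(list(tx = v), "control")

  prof <- ReactivitySet(list(tx = c(0.2, 0.4, NA, NA)), "control")
  expect_equal(windowMeanReactivity(prof, "tx", 0, 2, min_defined = 2), 0.3)
  expect_true(is.na(windowMeanReactivity(prof, "tx", 2, 4, min_defined = 1)))

  # seeded window vs direct mean oracle
  for (i in 1:20) {
    a <- sample(0:(n - 30), 1); b <- a + sample(10:30, 1)
    w <- v[(a + 1):b]
    expected <- if (sum(!is.na(w)) >= 5) mean(w, na.rm = TRUE) else NA_real_
    expect_equal(windowMeanReactivity(rs, "tx", a, b), expected,
                 tolerance = 1e-12)
  }
  expect_error(windowMeanReactivity(rs, "tx", -1, 10), "out of range")
  expect_error(windowMeanReactivity(rs, "tx", 10, 10), "out of range")
})

test_that("offset-window deltas use the documented geometry and sign", {
  len <- 220L
  ts <- TranscriptSet(c(tx = strrep("A", len)),
    data.frame(transcript_id = "tx", gene_id = "g", len_5utr = len,
               len_cds = 0L, len_3utr = 0L, abundance = 1))
  hit <- GenomicRanges::GRanges(seqnames = "tx",
    ranges = IRanges::IRanges(start = 61, end = 70),
    gene_id = "g", region = "5UTR", motif_class = "R10", seq = strrep("A", 10))
  ctrl <- ReactivitySet(list(tx = rep(0.5, len)), "control")
  treat <- ReactivitySet(list(tx = rep(0.3, len)), "treated")

  d <- motifWindowDelta(ctrl, treat, hit, side = "both")
  down <- d[d$side == "downstream", ]
  up <- d[d$side == "upstream", ]
  expect_equal(down$win_start, 100); expect_equal(down$win_end, 120)
  expect_equal(up$win_start, 10); expect_equal(up$win_end, 30)
  expect_equal(down$delta, -0.2)              # reactivity drop = gain
  expect_equal(down$n_defined, 20L)

  same <- motifWindowDelta(ctrl, ctrl, hit, side = "downstream")
  expect_equal(same$delta, 0)

  # window past the transcript end is flagged invalid, not dropped
  short <- TranscriptSet(c(tx = strrep("A", 110L)),
    data.frame(transcript_id = "tx", gene_id = "g", len_5utr = 110L,
               len_cds = 0L, len_3utr = 0L, abundance = 1))
  cs <- ReactivitySet(list(tx = rep(0.5, 110)), "control")
  inv <- motifWindowDelta(cs, cs, hit, side = "downstream")
  expect_false(inv$valid)
  expect_true(is.na(inv$delta))
  expect_equal(nrow(inv), 1L)
})

test_that("random windows respect the grid and boundary constraints", {
  ts <- random_transcript_set(99, len5 = 280L)
  w <- sampleRandomWindows(ts, "tx", 5, region = "5UTR", seed = 4)
  expect_length(w, 5L)
  starts <- GenomicRanges::start(w)
  rb <- regionBounds(ts, "tx")
  b <- rb[rb$region == "5UTR", ]
  expect_true(all((starts - b$start) %% 10 == 0))
  expect_true(all(starts - b$start >= 50))
  expect_true(all(b$end - (starts + 19) >= 50))

  w2 <- sampleRandomWindows(ts, "tx", 5, region = "5UTR", seed = 4)
  expect_identical(GenomicRanges::start(w2), starts)   # same seed, same draw

  expect_warning(few <- sampleRandomWindows(ts, "tx", 500, region = "5UTR"),
                 "returning all")
  expect_true(length(few) < 500)
})

test_that("matched random windows mirror per-transcript motif counts", {
  sim <- simulateTranscriptome(simulationSpec(n_genes = 10), seed = 5)
  hits <- scanMotifs(sim$transcripts)
  rand <- matchedRandomWindows(sim$transcripts, hits, seed = 5)
  key <- function(gr) table(paste(GenomicRanges::seqnames(gr),
                                  S4Vectors::mcols(gr)$region))
  expect_identical(key(rand), key(hits))
  expect_true(all(S4Vectors::mcols(rand)$motif_class == "random"))
})

test_that("motif vs random comparison flags degenerate input and finds planted effects", {
  spec <- simulationSpec(n_genes = 40, cds_range = c(120L, 160L),
                         utr3_range = c(120L, 160L),
                         plant_per_region = c("5UTR" = 1L))
  sim <- simulateTranscriptome(spec, seed = 13)
  rp <- simulateReactivityPair(sim$transcripts, sim$truth, spec, seed = 14)
  hits <- truth_granges(sim$truth)
  rand <- matchedRandomWindows(sim$transcripts, hits, seed = 15)
  ms <- motifWindowDelta(rp$ctrl, rp$treat, hits, side = "downstream")
  rs <- motifWindowDelta(rp$ctrl, rp$treat, rand, side = "downstream")
  out <- compareMotifVsRandom(ms, rs, paired = TRUE)
  expect_lt(out$p, 0.01)
  expect_lt(out$median_motif, out$median_random)
  expect_equal(out$n_motif, out$n_random)

  expect_error(compareMotifVsRandom(ms, ms, paired = TRUE),
               "all differences zero")
})

test_that("structure-change classification follows the DMS sign convention", {
  expect_identical(classifyStructureChange(c(-0.1, 0.1, 0)),
                   c("gain", "loss", "excluded"))
})

test_that("structure/translation join reports drops and group summaries", {
  ws <- data.frame(
    transcript_id = paste0("t", 1:4), gene_id = paste0("g", 1:4),
    region = "5UTR", motif_class = "R10", motif_start = 60L, motif_end = 70L,
    side = "downstream", win_start = 100L, win_end = 120L,
    mean_ctrl = 0.5, mean_treat = c(0.3, 0.2, 0.7, 0.6),
    delta = c(-0.2, -0.3, 0.2, 0.1), n_defined = 20L, valid = TRUE)
  rt <- data.frame(gene_id = c("g1", "g2", "g3"),
                   log2fc = c(-1.2, -0.8, -0.1))
  out <- joinStructureTranslation(ws, rt)
  expect_equal(nrow(out$records), 3L)
  expect_equal(out$n_dropped, 1L)   # g4 absent from the rate table
  gain <- out$summary$median_log2fc[out$summary$structure_class == "gain"]
  loss <- out$summary$median_log2fc[out$summary$structure_class == "loss"]
  expect_lt(gain, loss)

  expect_error(joinStructureTranslation(ws, data.frame(gene_id = "zz", log2fc = 1)),
               "zero rows")
})
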
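# Independent small-instance oracles and fixture builders used across the
# suite. These deliberately avoid the package's code paths.

# OLS via the normal equations, written out by hand
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, rss = rss)
}

# Benjamini-Hochberg by the step-up formula, written out by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# exact paired signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
}

# exact rank-sum p by enumerating all assignments of ranks to group 1
oracle_rank_sum <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  combos <- utils::combn(n + m, n)
  Ws <- apply(combos, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
}

# Welch two-sample t-test p from the closed-form statistic
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# brute-force non-overlapping motif scan: enumerate every constraint-passing
# start, then greedily resolve overlaps from the left
oracle_scan <- function(ts, id, motif_class = "R10", L = 10L, cap = 7L,
                        edge = 50L) {
  s <- strsplit(as.character(sequences(ts)[[id]]), "", fixed = TRUE)[[1]]
  alpha <- if (motif_class == "R10") c("A", "G") else c("G", "C")
  rb <- regionBounds(ts, id)
  out <- NULL
  for (r in seq_len(nrow(rb))) {
    lo <- rb$start[r] + edge; hi <- rb$end[r] - edge - L + 1L
    if (hi < lo) next
    cand <- Filter(function(p) {
      w <- s[p:(p + L - 1L)]
      all(w %in% alpha) && sum(w == alpha[1]) <= cap && sum(w == alpha[2]) <= cap
    }, lo:hi)
    starts <- integer()
    while (length(cand)) {
      p <- min(cand)
      starts <- c(starts, p)
      cand <- cand[cand >= p + L]
    }
    if (length(starts))
      out <- rbind(out, data.frame(region = rb$region[r], start = starts))
  }
  out
}

# random annotated transcript for scanner stress tests (purine-enriched so
# spurious motifs are common)
random_transcript_set <- function(seed, len5 = NULL, purine_bias = TRUE) {
  set.seed(seed)
  l5 <- if (is.null(len5)) sample(120:300, 1) else len5
  lc <- sample(150:500, 1); l3 <- sample(120:300, 1)
  prob <- if (purine_bias) c(A = .3, C = .2, G = .3, T = .2) else rep(.25, 4)
  s <- paste(sample(c("A", "C", "G", "T"), l5 + lc + l3, TRUE, prob = prob),
             collapse = "")
  TranscriptSet(c(tx = s),
    data.frame(transcript_id = "tx", gene_id = "gx", len_5utr = l5,
               len_cds = lc, len_3utr = l3, abundance = 1))
}

# GRanges for a planted-motif truth table (1-based internal coordinates)
truth_granges <- function(truth) {
  GenomicRanges::GRanges(
    seqnames = truth$transcript_id,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    gene_id = truth$gene_id, region = truth$region,
    motif_class = "R10", seq = truth$seq)
}

# key strings for comparing hit sets
hit_keys <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
        S4Vectors::mcols(gr)$region)
}

# joint pair filter for matched motif/random window stats (1 pair per row)
paired_delta_p <- function(ms, rs) {
  ok <- ms$valid & rs$valid & is.finite(ms$delta) & is.finite(rs$delta)
  compareMotifVsRandom(ms[ok, ], rs[ok, ], paired = TRUE)$p
}
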
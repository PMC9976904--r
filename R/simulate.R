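# truncated-at-zero normal via inverse CDF (exact, vectorized)
.rtnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Simulation parameters for the synthetic-data generators
#'
#' Bundles, with defaults, everything the generators need: transcriptome
#' geometry (gene count, region-length ranges, planted motifs per region),
#' the localized structure-gain effect (mean downstream reactivity drop
#' 0.15 restricted to the 31-50 nt downstream window, noise sd 0.1), and
#' the pulsed-SILAC design (4 replicates at 0/2/4/8 h, 10% intensity CV,
#' labelling rates U(0.05, 0.3) per hour, a 25% dependent subset with the
#' treated rate halved). The effect is applied downstream of planted motifs
#' only, never upstream, mirroring the asymmetry of the motif-anchored
#' window analysis.
#'
#' @param n_genes number of genes (one transcript each)
#' @param len5_range,cds_range,utr3_range inclusive region-length ranges (nt)
#' @param plant_per_region named integer vector: planted motifs per region
#' @param effect mean downstream reactivity drop for planted motifs
#' @param reactivity_noise_sd per-condition reactivity noise sd
#' @param base_mean,base_sd distribution of per-position baseline
#'   reactivity at A/C positions (truncated-at-zero normal)
#' @param offsets downstream effect window (inclusive distances from the
#'   motif's last base)
#' @param motif_length,composition_cap,min_edge_distance scanner rules the
#'   planted motifs must satisfy
#' @param psilac list of pulsed-SILAC generator settings (see Details)
#' @return validated list of class \code{"agmotif_sim_spec"}
#' @export
simulationSpec <- function(n_genes = 300L,
                           len5_range = c(150L, 400L),
                           cds_range = c(300L, 900L),
                           utr3_range = c(150L, 400L),
                           plant_per_region = c("5UTR" = 1L, "CDS" = 1L, "3UTR" = 1L),
                           effect = 0.15,
                           reactivity_noise_sd = 0.1,
                           base_mean = 0.5, base_sd = 0.15,
                           offsets = c(31L, 50L),
                           motif_length = 10L, composition_cap = 7L,
                           min_edge_distance = 50L,
                           psilac = list()) {
  ps <- utils::modifyList(list(
    n_proteins = 100L, k_range = c(0.05, 0.3),
    dependent_fraction = 0.25, dependent_multiplier = 0.5,
    cv = 0.1, times = c(0, 2, 4, 8), replicates = 4L,
    mode = "loglinear", f0_meanlog = log(0.1), f0_sdlog = 0.2,
    intensity_meanlog = log(1e6), intensity_sdlog = 0.5), psilac)
  spec <- list(n_genes = as.integer(n_genes), len5_range = len5_range,
               cds_range = cds_range, utr3_range = utr3_range,
               plant_per_region = plant_per_region, effect = effect,
               reactivity_noise_sd = reactivity_noise_sd,
               base_mean = base_mean, base_sd = base_sd, offsets = offsets,
               motif_length = as.integer(motif_length),
               composition_cap = as.integer(composition_cap),
               min_edge_distance = as.integer(min_edge_distance),
               psilac = ps)
  if (spec$n_genes < 1) stop("n_genes must be >= 1")
  if (ps$dependent_fraction < 0 || ps$dependent_fraction > 1)
    stop("dependent_fraction must be in [0,1]")
  if (ps$dependent_multiplier <= 0) stop("dependent_multiplier must be > 0")
  if (!ps$mode %in% c("loglinear", "mechanistic"))
    stop("psilac mode must be 'loglinear' or 'mechanistic'")
  if (spec$reactivity_noise_sd < 0 || spec$effect < 0) stop("negative noise/effect")
  class(spec) <- "agmotif_sim_spec"
  spec
}

# one planted motif sequence under the composition cap (both counts 3..7)
.plantMotifSeq <- function(len, cap) {
  nA <- sample((len - cap):cap, 1L)
  sample(c(rep("A", nA), rep("G", len - nA)))
}

#' Simulate a transcriptome with planted purine motifs
#'
#' Generates one transcript per gene with uniform-composition background
#' sequence and plants, per region, the configured number of R10 motifs at
#' recorded positions. Planted motifs satisfy every scanner rule
#' (all-purine, composition cap, edge distance) and are flanked by forced
#' pyrimidines so they cannot merge with background purine runs; background
#' sequence still yields a low but nonzero density of spurious motifs.
#'
#' @param spec a [simulationSpec()]
#' @param seed integer seed; fixed seed gives identical output
#' @return list with \code{transcripts} (a [TranscriptSet]) and
#'   \code{truth} (data.frame of planted motifs, 0-based half-open starts)
#' @export
simulateTranscriptome <- function(spec = simulationSpec(), seed = 1L) {
  set.seed(seed)
  L <- spec$motif_length; edge <- spec$min_edge_distance
  seqs <- character(spec$n_genes)
  anno <- vector("list", spec$n_genes)
  truth <- list()
  for (g in seq_len(spec$n_genes)) {
    tid <- sprintf("t%04d", g); gid <- sprintf("g%04d", g)
    l5 <- sample(spec$len5_range[1]:spec$len5_range[2], 1L)
    lc <- sample(spec$cds_range[1]:spec$cds_range[2], 1L)
    l3 <- sample(spec$utr3_range[1]:spec$utr3_range[2], 1L)
    len <- l5 + lc + l3
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    bounds <- data.frame(region = c("5UTR", "CDS", "3UTR"),
                         start = c(1L, l5 + 1L, l5 + lc + 1L),
                         end = c(l5, l5 + lc, l5 + lc + l3))
    for (r in seq_len(nrow(bounds))) {
      nplant <- if (bounds$region[r] %in% names(spec$plant_per_region))
        spec$plant_per_region[[bounds$region[r]]] else 0L
      if (nplant < 1) next
      lo <- bounds$start[r] + edge; hi <- bounds$end[r] - edge - L + 1L
      if (hi < lo) {
        if (nplant > 0) stop("region ", bounds$region[r], " of ", tid,
                             " too short to plant a motif")
        next
      }
      # equal slots keep planted motifs (and their forced flanks) apart
      cuts <- floor(seq(lo, hi + 1L, length.out = nplant + 1L))
      for (m in seq_len(nplant)) {
        slo <- cuts[m] + (m > 1) * 2L; shi <- cuts[m + 1L] - 1L
        if (shi < slo) stop("not enough room for ", nplant, " motifs in ",
                            bounds$region[r], " of ", tid)
        p <- if (shi > slo) sample(slo:shi, 1L) else slo
        s[p:(p + L - 1L)] <- .plantMotifSeq(L, spec$composition_cap)
        if (p > 1L) s[p - 1L] <- sample(c("C", "T"), 1L)
        if (p + L <= len) s[p + L] <- sample(c("C", "T"), 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, region = bounds$region[r],
          start = p - 1L, end = p + L - 1L,    # 0-based half-open
          seq = paste(s[p:(p + L - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    seqs[g] <- paste(s, collapse = "")
    anno[[g]] <- data.frame(transcript_id = tid, gene_id = gid,
                            len_5utr = l5, len_cds = lc, len_3utr = l3,
                            abundance = stats::rlnorm(1, log(10), 1),
                            stringsAsFactors = FALSE)
  }
  anno <- do.call(rbind, anno)
  names(seqs) <- anno$transcript_id
  list(transcripts = TranscriptSet(seqs, anno),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(transcript_id = character(), gene_id = character(),
                    region = character(), start = integer(), end = integer(),
                    seq = character()))
}

#' Simulate paired control/treated reactivity profiles
#'
#' Baseline reactivity is drawn per A/C position from a truncated-at-zero
#' normal; control and treated values add independent truncated-normal
#' noise around that baseline, and the treated condition additionally
#' subtracts the planted effect (default 0.15) at A/C positions inside the
#' downstream offset window (default 31-50 nt past the motif's last base)
#' of every planted motif. Upstream windows carry no systematic change.
#' G/T positions are undefined (NA) in both conditions.
#'
#' @param transcripts a [TranscriptSet] from [simulateTranscriptome()]
#' @param truth the planted-motif truth table
#' @param spec a [simulationSpec()]
#' @param seed integer seed
#' @return list with \code{ctrl} and \code{treat} ([ReactivitySet]s)
#' @export
simulateReactivityPair <- function(transcripts, truth,
                                   spec = simulationSpec(), seed = 1L) {
  set.seed(seed)
  off <- spec$offsets
  ids <- transcriptIds(transcripts)
  vC <- vT <- vector("list", length(ids)); names(vC) <- names(vT) <- ids
  for (id in ids) {
    s <- strsplit(as.character(sequences(transcripts)[[id]]), "", fixed = TRUE)[[1]]
    ac <- s %in% c("A", "C")
    n <- length(s)
    eff <- numeric(n)
    tt <- truth[truth$transcript_id == id, , drop = FALSE]
    for (m in seq_len(nrow(tt))) {
      e1 <- tt$end[m]                        # 0-based exclusive = 1-based end
      w <- (e1 + off[1]):(e1 + off[2])       # 1-based positions downstream
      w <- w[w >= 1 & w <= n]
      eff[w] <- spec$effect
    }
    base <- .rtnorm0(sum(ac), spec$base_mean, spec$base_sd)
    ctrl <- treat <- rep(NA_real_, n)
    ctrl[ac] <- .rtnorm0(sum(ac), base, spec$reactivity_noise_sd)
    treat[ac] <- .rtnorm0(sum(ac), base - eff[ac], spec$reactivity_noise_sd)
    vC[[id]] <- ctrl; vT[[id]] <- treat
  }
  list(ctrl = ReactivitySet(vC, "control"),
       treat = ReactivitySet(vT, "treated"))
}

#' Simulate a pulsed-SILAC TMT cohort
#'
#' Draws per-protein labelling rates from the configured range, halves the
#' treated rate for a dependent subset, and produces heavy/light channel
#' intensities over the time course with multiplicative lognormal noise at
#' the configured CV. Two generation modes: \code{"loglinear"} (default)
#' makes \code{ln F_H = k t + offset} hold exactly, matching the fitted
#' model; \code{"mechanistic"} uses first-order labelling
#' \code{F_H = 1 - exp(-k t)} (zero at t = 0), whose linearisation is only
#' approximate.
#'
#' @param spec a [simulationSpec()] (fields under \code{psilac})
#' @param seed integer seed
#' @return list with \code{data} (long-format intensity table with columns
#'   protein_id, condition, time_h, replicate, intensity_light,
#'   intensity_heavy) and \code{truth} (protein_id, k_ctrl, k_treat,
#'   dependent)
#' @export
simulatePsilac <- function(spec = simulationSpec(), seed = 1L) {
  set.seed(seed)
  ps <- spec$psilac
  n <- ps$n_proteins
  sdlog <- sqrt(log(1 + ps$cv^2))
  ids <- sprintf("P%04d", seq_len(n))
  k_ctrl <- stats::runif(n, ps$k_range[1], ps$k_range[2])
  dep <- stats::runif(n) < ps$dependent_fraction
  k_treat <- ifelse(dep, ps$dependent_multiplier * k_ctrl, k_ctrl)
  offset <- stats::rnorm(n, ps$f0_meanlog, ps$f0_sdlog)
  # keep loglinear F_H < 1 over the time course
  offset <- pmin(offset, -k_ctrl * max(ps$times) - 0.05)
  i0 <- stats::rlnorm(n, ps$intensity_meanlog, ps$intensity_sdlog)
  grid <- expand.grid(replicate = seq_len(ps$replicates), time_h = ps$times,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    for (cond in c("control", "treated")) {
      k <- if (cond == "control") k_ctrl[i] else k_treat[i]
      fh <- if (ps$mode == "loglinear") exp(offset[i] + k * grid$time_h)
            else 1 - exp(-k * grid$time_h)
      m <- nrow(grid)
      heavy <- fh * i0[i] * stats::rlnorm(m, 0, sdlog)
      light <- (1 - fh) * i0[i] * stats::rlnorm(m, 0, sdlog)
      rows[[2L * (i - 1L) + (cond == "treated") + 1L]] <- data.frame(
        protein_id = ids[i], condition = cond, time_h = grid$time_h,
        replicate = grid$replicate, intensity_light = light,
        intensity_heavy = heavy, stringsAsFactors = FALSE)
    }
  }
  list(data = do.call(rbind, rows),
       truth = data.frame(protein_id = ids, k_ctrl = k_ctrl,
                          k_treat = k_treat, dependent = dep,
                          stringsAsFactors = FALSE))
}

#' Simulate enzymology curve fixtures
#'
#' Generates one fixture per curve family from its stated kinetic model —
#' unwinding progress (single exponential to amplitude), Hill titration,
#' single-exponential decay, wt/dead-subunit mixing, and a coupled-ATPase
#' absorbance trace — together with the generating parameters. With
#' \code{noise = 0} the fixtures are exact and round-trip through the
#' fitters.
#'
#' @param seed integer seed
#' @param noise relative Gaussian noise level (default 0)
#' @param progress,hill,decay,mixing,atpase generating parameters per
#'   family (lists; see defaults in the function signature)
#' @return named list of fixtures, each with \code{curve} (data.frame) and
#'   \code{truth} (generating parameters)
#' @export
simulateEnzymology <- function(seed = 1L, noise = 0,
    progress = list(A = 0.8, k = 0.05, times = seq(0, 60, by = 2)),
    hill = list(y_max = 1, k_half = 2, h = 2,
                conc = 2 * 10^seq(-1.5, 1.5, length.out = 8)),
    decay = list(A = 1, rate = 0.1, times = seq(0, 40, by = 2)),
    mixing = list(n = 3L, f = seq(0, 0.9, by = 0.1)),
    atpase = list(rate_mM_min = 0.1, epsilon = 0.62, a0 = 0.9,
                  times = 0:10)) {
  set.seed(seed)
  jitter <- function(y) y + stats::rnorm(length(y), 0, noise * max(abs(y), 1e-12))
  list(
    progress = list(
      curve = data.frame(time = progress$times,
        signal = jitter(progress$A * (1 - exp(-progress$k * progress$times)))),
      truth = progress),
    hill = list(
      curve = data.frame(conc = hill$conc,
        response = jitter(hill$y_max * hill$conc^hill$h /
                          (hill$k_half^hill$h + hill$conc^hill$h))),
      truth = hill),
    decay = list(
      curve = data.frame(time = decay$times,
        signal = jitter(decay$A * exp(-decay$rate * decay$times))),
      truth = decay),
    mixing = list(
      curve = data.frame(f_inactive = mixing$f,
        rel_activity = jitter((1 - mixing$f)^mixing$n)),
      truth = mixing),
    atpase = list(
      curve = data.frame(time = atpase$times,
        a340 = jitter(atpase$a0 - atpase$epsilon * atpase$rate_mM_min * atpase$times)),
      truth = atpase))
}
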
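#' Fit a duplex-unwinding progress curve
#'
#' Exponential mode fits \code{F(t) = A * (1 - exp(-k_obs * t))} by
#' nonlinear least squares, returning the amplitude (total fraction
#' unwound), the observed rate and the initial rate \code{A * k_obs}.
#' Linear mode instead fits an ordinary least-squares line to the first
#' \code{early_n} points and returns its slope as the initial rate. Flat
#' traces short-circuit to a zero-rate result flagged \code{converged =
#' FALSE}. Raw fluorescence should be normalised to fraction unwound
#' beforehand (see [normalizeProgressSignal()]).
#'
#' @param time,signal progress curve; time strictly increasing (minutes)
#' @param mode "exponential" or "linear_initial"
#' @param early_n number of early points for linear mode (default 5)
#' @return list with \code{amplitude}, \code{k_obs}, \code{initial_rate},
#'   \code{rss}, \code{converged}, \code{mode}
#' @export
fitProgressCurve <- function(time, signal,
                             mode = c("exponential", "linear_initial"),
                             early_n = 5L) {
  mode <- match.arg(mode)
  if (length(time) != length(signal)) stop("time and signal lengths differ")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (mode == "linear_initial") {
    if (length(time) < 2L) stop("need at least 2 early points")
    n <- min(early_n, length(time))
    fit <- olsFit(time[seq_len(n)], signal[seq_len(n)])
    return(list(amplitude = NA_real_, k_obs = NA_real_,
                initial_rate = fit$slope, rss = fit$rss, converged = TRUE,
                mode = mode))
  }
  if (length(time) < 4L) stop("exponential fit needs at least 4 points")
  if (diff(range(signal)) < 1e-10)
    return(list(amplitude = mean(signal), k_obs = 0, initial_rate = 0,
                rss = sum((signal - mean(signal))^2), converged = FALSE,
                mode = mode))
  a0 <- max(signal)
  k0 <- {                                  # rate guess from earliest rise
    i <- which(signal > 0.5 * a0)[1]
    if (is.na(i) || time[i] <= 0) 1 / max(time) else log(2) / time[i]
  }
  fit <- minpack.lm::nlsLM(signal ~ A * (1 - exp(-k * time)),
                           start = list(A = a0, k = k0),
                           lower = c(A = 0, k = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(amplitude = unname(cf["A"]), k_obs = unname(cf["k"]),
       initial_rate = unname(cf["A"] * cf["k"]),
       rss = sum(stats::residuals(fit)^2), converged = TRUE, mode = mode)
}

#' Normalise raw fluorescence to fraction unwound
#'
#' Linear rescaling using user-supplied 0% and 100% unwound control
#' readings.
#'
#' @param signal raw readings
#' @param zero,full control readings for 0% and 100% unwound
#' @return fraction-unwound values
#' @export
normalizeProgressSignal <- function(signal, zero, full) {
  if (full == zero) stop("0% and 100% controls are equal")
  (signal - zero) / (full - zero)
}

#' Fit the Hill equation to a titration
#'
#' Least-squares fit of \code{y = y_max * c^h / (k_half^h + c^h)} with
#' initial values y_max = max(response), k_half = concentration at
#' half-maximal response by interpolation, h = 1; h is bounded to (0, 6]
#' and k_half to the tested concentration range times [0.01, 100]. The
#' fitted curve passes y_max/2 at c = k_half by construction. \code{h_fixed}
#' fixes the Hill coefficient (h = 1 reduces to a hyperbolic binding
#' isotherm).
#'
#' @param conc non-negative concentrations (>= 5 distinct values)
#' @param response responses parallel to \code{conc}
#' @param h_fixed optional fixed Hill coefficient
#' @return list with \code{y_max}, \code{k_half}, \code{h}, standard errors
#'   \code{se} (named vector), \code{rss}
#' @export
hillFit <- function(conc, response, h_fixed = NULL) {
  if (length(conc) != length(response)) stop("conc and response lengths differ")
  if (any(conc < 0)) stop("negative concentrations")
  if (length(unique(conc)) < 5L) stop("need >= 5 distinct concentrations")
  if (diff(range(response)) < 1e-12) stop("all responses equal; nothing to fit")
  ymax0 <- max(response)
  pos <- conc > 0
  k0 <- stats::approx(response[pos], conc[pos], xout = ymax0 / 2,
                      ties = mean)$y
  if (is.na(k0) || k0 <= 0) k0 <- stats::median(conc[pos])
  kr <- range(conc[pos])
  low <- c(y_max = 0, k_half = kr[1] * 0.01)
  upp <- c(y_max = Inf, k_half = kr[2] * 100)
  if (is.null(h_fixed)) {
    fit <- minpack.lm::nlsLM(
      response ~ y_max * conc^h / (k_half^h + conc^h),
      start = list(y_max = ymax0, k_half = k0, h = 1),
      lower = c(low, h = 1e-6), upper = c(upp, h = 6),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    h <- h_fixed
    fit <- minpack.lm::nlsLM(
      response ~ y_max * conc^h / (k_half^h + conc^h),
      start = list(y_max = ymax0, k_half = k0),
      lower = low, upper = upp,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  list(y_max = unname(cf["y_max"]), k_half = unname(cf["k_half"]),
       h = if (is.null(h_fixed)) unname(cf["h"]) else h_fixed,
       se = se, rss = sum(stats::residuals(fit)^2))
}

#' Predicted Hill-equation response
#'
#' @param conc concentrations
#' @param fit a fit from [hillFit()] (or any list with y_max, k_half, h)
#' @return predicted responses
#' @export
hillPredict <- function(conc, fit) {
  fit$y_max * conc^fit$h / (fit$k_half^fit$h + conc^fit$h)
}

#' Fit a single-exponential decay
#'
#' Fits \code{y = A * exp(-rate * t)} and reports the half-life
#' \code{ln(2)/rate}. A constant trace returns rate 0 (half-life infinite)
#' flagged \code{converged = FALSE}.
#'
#' @param time,signal decay trace
#' @return list with \code{amplitude}, \code{rate}, \code{half_life},
#'   \code{rss}, \code{converged}
#' @export
expDecayFit <- function(time, signal) {
  if (length(time) != length(signal)) stop("time and signal lengths differ")
  if (diff(range(signal)) < 1e-12)
    return(list(amplitude = mean(signal), rate = 0, half_life = Inf,
                rss = 0, converged = FALSE))
  a0 <- max(signal)
  pos <- signal > 0 & time > 0
  k0 <- if (any(pos)) max(1e-6, stats::median(-log(signal[pos] / a0) / time[pos]))
        else 1e-3
  fit <- minpack.lm::nlsLM(signal ~ A * exp(-k * time),
                           start = list(A = a0, k = k0),
                           lower = c(A = 0, k = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(amplitude = unname(cf["A"]), rate = unname(cf["k"]),
       half_life = log(2) / unname(cf["k"]),
       rss = sum(stats::residuals(fit)^2), converged = TRUE)
}

#' ATPase rate from a coupled NADH absorbance trace
#'
#' In the pyruvate-kinase/lactate-dehydrogenase coupled assay one NADH is
#' oxidised per ATP hydrolysed, so the ATPase rate equals the NADH
#' consumption rate: \code{-slope(A340 vs time) / epsilon_nadh}, in mM
#' NADH (= mM ATP) per time unit. An increasing trace yields a negative
#' (signed) rate with a warning.
#'
#' @param time minutes
#' @param a340 absorbance at 340 nm
#' @param epsilon_nadh instrument-specific NADH extinction (absorbance per
#'   mM; default 0.62)
#' @return rate in mM/min
#' @export
atpaseRate <- function(time, a340, epsilon_nadh = 0.62) {
  fit <- olsFit(time, a340)
  if (fit$slope > 0) warning("absorbance trace increases; signed rate returned")
  -fit$slope / epsilon_nadh
}

#' Relative FRET from corrected donor/acceptor intensities
#'
#' \code{FRET = F_665 / (F_565 + F_665)} on spectrally corrected
#' intensities (see [correctFretSpectrum()]).
#'
#' @param f_565,f_665 corrected fluorescence at the Cy3 (565 nm) and Cy5
#'   (665 nm) peaks; non-negative, not both zero
#' @return relative FRET in [0, 1]
#' @export
fretEfficiency <- function(f_565, f_665) {
  if (any(f_565 < 0 | f_665 < 0)) stop("intensities must be >= 0")
  tot <- f_565 + f_665
  if (any(tot == 0)) stop("both intensities zero")
  f_665 / tot
}

#' Spectral correction for FRET emission scans
#'
#' Subtracts the acceptor-only (Cy5) emission spectrum and normalises to
#' the donor (Cy3) peak at 565 nm, the documented preprocessing for
#' [fretEfficiency()].
#'
#' @param wavelength_nm wavelengths of the scan
#' @param emission raw emission intensities
#' @param cy5_only acceptor-only emission, same wavelengths
#' @param donor_peak_nm wavelength of the donor peak (default 565)
#' @return corrected, donor-normalised spectrum
#' @export
correctFretSpectrum <- function(wavelength_nm, emission, cy5_only,
                                donor_peak_nm = 565) {
  corr <- emission - cy5_only
  i <- which.min(abs(wavelength_nm - donor_peak_nm))
  if (corr[i] <= 0) stop("non-positive donor peak after correction")
  corr / corr[i]
}

#' Expected relative activity of wt/inactive-subunit mixtures
#'
#' Null model for subunit-poisoning experiments in which active enzyme is
#' mixed with a catalytically dead variant at inactive fraction f. A
#' monomeric or multimeric enzyme without subunit cooperativity follows the
#' line \code{1 - f} (x + y = 1); an obligate n-subunit enzyme in which a
#' single dead subunit poisons the complex follows \code{(1 - f)^n}
#' (random assembly). n = 1 reduces to the noncooperative line.
#'
#' @param f_inactive fraction of inactive subunits in [0, 1]
#' @param model "noncooperative" or "poisoned_n"
#' @param n number of obligate subunits (>= 1) for "poisoned_n"
#' @return expected activity relative to f = 0
#' @export
mixingModel <- function(f_inactive, model = c("noncooperative", "poisoned_n"),
                        n = 1L) {
  model <- match.arg(model)
  if (any(f_inactive < 0 | f_inactive > 1)) stop("f_inactive must be in [0,1]")
  if (model == "poisoned_n" && n < 1) stop("n must be >= 1")
  if (model == "noncooperative") 1 - f_inactive else (1 - f_inactive)^n
}

#' Fit the subunit-poisoning model to a mixing series
#'
#' Selects the integer number of obligate subunits n in \code{(1 - f)^n}
#' by least squares over n = 1..n_max and reports the per-n residual sums
#' of squares. n = 1 is the noncooperative (x + y = 1) null.
#'
#' @param f_inactive,rel_activity mixing series, activity normalised to
#'   f = 0
#' @param n_max largest n considered (default 6)
#' @return list with \code{n} (best), \code{model} ("noncooperative" when
#'   n = 1, else "poisoned_n"), \code{rss} for the best n and
#'   \code{comparison} (data.frame of n vs rss)
#' @export
fitMixing <- function(f_inactive, rel_activity, n_max = 6L) {
  if (length(f_inactive) != length(rel_activity)) stop("lengths differ")
  if (any(f_inactive < 0 | f_inactive > 1)) stop("f_inactive must be in [0,1]")
  rss <- vapply(seq_len(n_max), function(n)
    sum((rel_activity - (1 - f_inactive)^n)^2), numeric(1))
  best <- which.min(rss)
  list(n = best,
       model = if (best == 1L) "noncooperative" else "poisoned_n",
       rss = rss[best],
       comparison = data.frame(n = seq_len(n_max), rss = rss))
}

#' Partial specific volume of a protein:RNA complex
#'
#' Mass-weighted mean of the component partial specific volumes for a
#' complex of n protein copies and one RNA:
#' \code{(n*M_P*v_P + M_R*v_R) / (n*M_P + M_R)} (mL/g), used to interpret
#' analytical-ultracentrifugation stoichiometries. n = 0 returns the RNA
#' value; large n approaches the protein value.
#'
#' @param n protein copies (>= 0)
#' @param m_protein,m_rna molecular masses (Da)
#' @param vbar_protein,vbar_rna partial specific volumes (mL/g, in (0, 1))
#' @return partial specific volume of the complex (mL/g)
#' @export
vbarComplex <- function(n, m_protein, vbar_protein, m_rna, vbar_rna) {
  if (n < 0) stop("n must be >= 0")
  if (m_protein <= 0 || m_rna <= 0) stop("masses must be positive")
  if (any(c(vbar_protein, vbar_rna) <= 0 | c(vbar_protein, vbar_rna) >= 1))
    stop("partial specific volumes must be in (0, 1)")
  (n * m_protein * vbar_protein + m_rna * vbar_rna) / (n * m_protein + m_rna)
}

#' Maximum translation rate from a luminescence trace
#'
#' The maximum translation output is the steepest rise of reporter
#' luciferase activity over time: the maximum over sliding-window ordinary
#' least-squares slopes (window of \code{window_points} consecutive
#' readings, default 5). Monotone-decreasing traces return their
#' (non-positive) maximum slope with a warning.
#'
#' @param time,luminescence trace (>= window_points readings)
#' @return maximum slope (activity per time unit)
#' @export
reporterMaxSlope <- function(time, luminescence, window_points = 5L) {
  n <- length(time)
  if (length(luminescence) != n) stop("lengths differ")
  if (n < window_points) stop("need at least ", window_points, " readings")
  slopes <- vapply(seq_len(n - window_points + 1L), function(i) {
    idx <- i:(i + window_points - 1L)
    olsFit(time[idx], luminescence[idx])$slope
  }, numeric(1))
  m <- max(slopes)
  if (m <= 0) warning("maximum slope is non-positive (decreasing trace)")
  m
}

#' Normalise reporter rates to a reference reporter
#'
#' @param rates named numeric vector of reporter rates
#' @param reference_id name of the reference reporter (maps to exactly 1)
#' @return rates relative to the reference
#' @export
normalizeToReference <- function(rates, reference_id) {
  if (!reference_id %in% names(rates)) stop("unknown reference: ", reference_id)
  if (rates[[reference_id]] == 0) stop("reference rate is zero")
  rates / rates[[reference_id]]
}

#' Apparent translation rate from a dual-luciferase time course
#'
#' Firefly activities are normalised to the Renilla co-reporter per time
#' point and the apparent translation rate k is the ordinary least-squares
#' slope of the FL/RL ratio against time.
#'
#' @param fl,rl firefly and Renilla activities per time point (rl > 0)
#' @param time hours
#' @return slope k (ratio units per hour)
#' @export
cellReporterRate <- function(fl, rl, time) {
  if (length(fl) != length(rl) || length(fl) != length(time))
    stop("fl, rl and time lengths differ")
  if (any(rl == 0)) stop("Renilla activity is zero at some time point")
  olsFit(time, fl / rl)$slope
}

#' Total cellular mRNA concentration
#'
#' Converts an mRNA copy number per cell and a cell volume to a molar
#' concentration: copies / (N_A * V), with the volume given in cubic
#' micrometres (1 um^3 = 1e-15 L). With the literature values of 300 000
#' copies and 2425 um^3 this is about 0.2 uM — well below 1 uM, and far
#' below cellular eIF4A1 (10-20 uM).
#'
#' @param copies mRNA copies per cell (default 3e5)
#' @param cell_volume_um3 cell volume in um^3 (default 2425)
#' @return molar concentration (mol/L)
#' @export
mrnaConcentration <- function(copies = 3e5, cell_volume_um3 = 2425) {
  if (copies < 0 || cell_volume_um3 <= 0) stop("invalid inputs")
  avogadro <- 6.02214076e23
  copies / (avogadro * cell_volume_um3 * 1e-15)
}
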
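#' Aggregate peptide-level TMT intensities to protein level
#'
#' Duplicate peptide sequences (same peptide, condition, time and
#' replicate) are combined per channel by median; peptide values are then
#' combined into a protein-group value by the configured operator (sum by
#' default, median available). Peptides mapping to more than one protein
#' group are excluded and counted.
#'
#' @param peptides data.frame with columns \code{protein_id},
#'   \code{peptide_seq}, \code{condition}, \code{time_h}, \code{replicate},
#'   \code{intensity_light}, \code{intensity_heavy}
#' @param operator "sum" or "median" for the peptide-to-protein step
#' @return list with \code{table} (protein-level data.frame with the same
#'   channel columns) and \code{n_excluded_peptides}
#' @export
aggregatePeptidesToProteins <- function(peptides, operator = c("sum", "median")) {
  operator <- match.arg(operator)
  need <- c("protein_id", "peptide_seq", "condition", "time_h", "replicate",
            "intensity_light", "intensity_heavy")
  miss <- setdiff(need, colnames(peptides))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  pep2prot <- unique(peptides[, c("peptide_seq", "protein_id")])
  multi <- unique(pep2prot$peptide_seq[duplicated(pep2prot$peptide_seq)])
  peptides <- peptides[!peptides$peptide_seq %in% multi, ]
  # identical peptide sequences combined by median per channel
  med <- stats::aggregate(
    cbind(intensity_light, intensity_heavy) ~
      protein_id + peptide_seq + condition + time_h + replicate,
    data = peptides, FUN = stats::median)
  op <- if (operator == "sum") sum else stats::median
  prot <- stats::aggregate(
    cbind(intensity_light, intensity_heavy) ~
      protein_id + condition + time_h + replicate,
    data = med, FUN = op)
  prot <- prot[order(prot$protein_id, prot$condition, prot$time_h,
                     prot$replicate), ]
  rownames(prot) <- NULL
  list(table = prot, n_excluded_peptides = length(multi))
}

#' Fraction of heavy-labelled protein
#'
#' F_H = I_heavy / (I_heavy + I_light), the fraction of newly synthesised
#' (heavy-labelled) protein in a pulsed-SILAC channel pair. Vectorized;
#' both intensities zero is an error.
#'
#' @param i_heavy,i_light non-negative intensities
#' @return F_H in [0, 1]
#' @export
fractionHeavy <- function(i_heavy, i_light) {
  if (any(i_heavy < 0 | i_light < 0)) stop("intensities must be >= 0")
  tot <- i_heavy + i_light
  if (any(tot == 0)) stop("heavy + light intensity is zero")
  i_heavy / tot
}

#' Fit the apparent translation rate from labelling kinetics
#'
#' Fits the linearised first-order labelling model
#' \code{ln F_H = k * t + offset} by ordinary least squares; the slope k is
#' the apparent translation rate (per hour) and its p-value comes from the
#' F-test against k = 0. Points with \code{F_H <= 0} (notably t = 0 under a
#' fresh pulse) are excluded before the log transform; replicate
#' measurements at the same time enter as separate points. At least three
#' usable points at more than one time are required, otherwise the fit is
#' flagged invalid.
#'
#' @param times hours
#' @param f_h fractions heavy, parallel to \code{times}
#' @return list with \code{k}, \code{offset}, \code{p_slope},
#'   \code{se_slope}, \code{n_points_used}, \code{valid}
#' @export
fitTurnoverRate <- function(times, f_h) {
  if (length(times) != length(f_h)) stop("times and f_h lengths differ")
  use <- !is.na(f_h) & f_h > 0 & !is.na(times)
  t_u <- times[use]; y <- log(f_h[use])
  if (length(y) < 3L || length(unique(t_u)) < 2L)
    return(list(k = NA_real_, offset = NA_real_, p_slope = NA_real_,
                se_slope = NA_real_, n_points_used = length(y), valid = FALSE))
  fit <- olsFit(t_u, y)
  list(k = fit$slope, offset = fit$intercept, p_slope = fit$p_slope,
       se_slope = fit$se_slope, n_points_used = fit$n, valid = TRUE)
}

#' Filter proteins by fit quality in both conditions
#'
#' Retains proteins whose slope F-test p-value is below \code{p_cut} in
#' BOTH conditions (default 0.1), mirroring the quality filter applied
#' before the condition comparison.
#'
#' @param fits_ctrl,fits_treat named lists of fits from [fitTurnoverRate()]
#'   (names are protein ids)
#' @param p_cut p-value cut-off (default 0.1, strict inequality)
#' @return list with \code{retained} (protein ids) and \code{counts}
#'   (input / retained / removed)
#' @export
filterByFitQuality <- function(fits_ctrl, fits_treat, p_cut = 0.1) {
  shared <- intersect(names(fits_ctrl), names(fits_treat))
  ok <- vapply(shared, function(id) {
    fc <- fits_ctrl[[id]]; ft <- fits_treat[[id]]
    isTRUE(fc$valid) && isTRUE(ft$valid) &&
      !is.na(fc$p_slope) && !is.na(ft$p_slope) &&
      fc$p_slope < p_cut && ft$p_slope < p_cut
  }, logical(1))
  list(retained = shared[ok],
       counts = c(input = length(shared), retained = sum(ok),
                  removed = sum(!ok)))
}

#' Per-protein condition comparison of translation rates
#'
#' For each retained protein computes the rate difference
#' \code{diff = k_treat - k_ctrl} and \code{log2fc = log2(k_treat/k_ctrl)}
#' (undefined unless both rates are positive), a per-protein p-value for
#' the difference, and Benjamini-Hochberg FDRs across proteins. The default
#' difference test is a z-test on the slope difference using the two fits'
#' slope standard errors; a Welch t-test on per-replicate slopes is
#' available when per-replicate slope estimates are supplied.
#'
#' @param fits_ctrl,fits_treat named lists of fits from [fitTurnoverRate()]
#' @param proteins protein ids to compare (e.g. from [filterByFitQuality()])
#' @param method "z" (slope-SE z-test, default) or "welch"
#' @param rep_slopes_ctrl,rep_slopes_treat for \code{method = "welch"}:
#'   named lists of numeric vectors of per-replicate slopes
#' @return data.frame with protein_id, k_ctrl, k_treat, diff, log2fc,
#'   p_diff, fdr
#' @export
compareConditions <- function(fits_ctrl, fits_treat, proteins = NULL,
                              method = c("z", "welch"),
                              rep_slopes_ctrl = NULL, rep_slopes_treat = NULL) {
  method <- match.arg(method)
  if (is.null(proteins))
    proteins <- intersect(names(fits_ctrl), names(fits_treat))
  if (!length(proteins)) stop("no proteins to compare")
  rows <- lapply(proteins, function(id) {
    fc <- fits_ctrl[[id]]; ft <- fits_treat[[id]]
    d <- ft$k - fc$k
    l2 <- if (!is.na(fc$k) && !is.na(ft$k) && fc$k > 0 && ft$k > 0)
      log2(ft$k / fc$k) else NA_real_
    p <- if (method == "z") {
      se <- sqrt(fc$se_slope^2 + ft$se_slope^2)
      if (is.na(se) || se == 0) { if (d == 0) 1 else 0 }
      else 2 * stats::pnorm(-abs(d) / se)
    } else {
      tTestTwoTailed(rep_slopes_ctrl[[id]], rep_slopes_treat[[id]])
    }
    data.frame(protein_id = id, k_ctrl = fc$k, k_treat = ft$k, diff = d,
               log2fc = l2, p_diff = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$p_diff)
  rownames(out) <- NULL
  out
}

#' Classify proteins as helicase-dependent or -independent
#'
#' Labels each protein by the FDR of its rate difference: dependent when
#' FDR < \code{fdr_dependent} (default 0.1), independent when
#' FDR > \code{fdr_independent} (default 0.7), otherwise unclassified.
#'
#' @param records data.frame from [compareConditions()]
#' @param fdr_dependent,fdr_independent thresholds (defaults 0.1 and 0.7)
#' @return the input with an added \code{label} column
#' @export
classifyDependence <- function(records, fdr_dependent = 0.1,
                               fdr_independent = 0.7) {
  lab <- rep("unclassified", nrow(records))
  lab[records$fdr < fdr_dependent] <- "dependent"
  lab[records$fdr > fdr_independent] <- "independent"
  records$label <- lab
  records
}
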
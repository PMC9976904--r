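#' Ordinary least-squares line fit
#'
#' Simple linear regression of y on x via [stats::lm()], returning the
#' pieces the pipeline needs: slope, intercept, residual sum of squares, the
#' slope standard error and the F-test p-value against slope = 0.
#'
#' By convention an exact fit (rss numerically zero with nonzero slope)
#' reports \code{p_slope = 0}: the F statistic diverges and platform NaNs
#' are avoided. \code{p_slope} is \code{NA} for n = 2 (no residual degrees
#' of freedom).
#'
#' @param x,y equal-length numeric vectors, \code{length >= 2}; x must not
#'   be constant
#' @return list with elements \code{slope}, \code{intercept}, \code{rss},
#'   \code{se_slope}, \code{n}, \code{p_slope}
#' @export
olsFit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("need at least 2 points")
  if (anyNA(x) || anyNA(y)) stop("NA in input")
  if (diff(range(x)) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  se <- if (n > 2L) sqrt(rss / (n - 2L) / sxx) else NA_real_
  out <- list(slope = unname(cf[2]), intercept = unname(cf[1]),
              rss = rss, se_slope = se, n = n, p_slope = NA_real_)
  if (n > 2L) out$p_slope <- fTestSlope(out)
  out
}

#' F-test of zero slope for a linear fit
#'
#' p-value of the F(1, n-2) statistic for H0: slope = 0, identical to the
#' squared-t test on the slope. An exact fit (rss = 0, slope != 0) returns
#' 0 by convention; slope exactly 0 returns 1 (F = 0).
#'
#' @param fit a fit from [olsFit()] (fields slope, se_slope, rss, n)
#' @return p-value in [0, 1]
#' @export
fTestSlope <- function(fit) {
  if (fit$n < 3L) stop("F-test needs n >= 3")
  tol <- 1e-12 * max(1, abs(fit$slope))
  if (fit$rss <= tol^2) return(if (abs(fit$slope) > tol) 0 else 1)
  f <- (fit$slope / fit$se_slope)^2
  stats::pf(f, 1, fit$n - 2L, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; the FDRs reported by the
#' pipeline use BH, the standard choice where no procedure is specified.
#' Delegates to [stats::p.adjust()]; input order is preserved.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted values (q-values), same order as input
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Wilcoxon tests
#'
#' Paired (signed-rank) or unpaired (rank-sum) two-sided Wilcoxon test.
#' Zero differences in paired mode are dropped (Wilcoxon's method); if all
#' differences are zero this is an error. The exact distribution is used up
#' to \code{exact_max} observations when there are no ties; above that (or
#' with ties) the normal approximation with continuity correction applies.
#'
#' @param x,y numeric samples; equal length required for paired mode
#' @param mode "paired" or "unpaired"
#' @param exact_max sample-size cutoff for the exact distribution
#' @return list with \code{p}, \code{statistic}, \code{n_effective}
#' @export
wilcoxonTest <- function(x, y, mode = c("paired", "unpaired"), exact_max = 25L) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (length(x) != length(y)) stop("paired mode requires equal lengths")
    d <- x - y
    d <- d[d != 0]
    if (!length(d)) stop("all differences zero")
    n <- length(d)
    wt <- suppressWarnings(stats::wilcox.test(d, exact = n <= exact_max,
                                              alternative = "two.sided"))
  } else {
    n <- min(length(x), length(y))
    wt <- suppressWarnings(stats::wilcox.test(x, y,
                                              exact = max(length(x), length(y)) <= exact_max,
                                              alternative = "two.sided"))
  }
  list(p = unname(wt$p.value), statistic = unname(wt$statistic), n_effective = n)
}

#' Two-tailed Welch t-test
#'
#' Unequal-variance (Welch) two-sample t-test; the variance assumption is a
#' package default since none is stated for the summary statistics it
#' backs.
#'
#' @param x,y numeric samples with at least 2 values each
#' @return p-value
#' @export
tTestTwoTailed <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) return(1)
  stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")$p.value
}
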
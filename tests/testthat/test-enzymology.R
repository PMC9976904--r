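test_that("progress-curve fits recover exponential unwinding kinetics", {
  t <- seq(0, 60, by = 2)
  y <- 0.8 * (1 - exp(-0.05 * t))
  fit <- fitProgressCurve(t, y)
  expect_equal(fit$amplitude, 0.8, tolerance = 1e-8)
  expect_equal(fit$k_obs, 0.05, tolerance = 1e-8)
  expect_equal(fit$initial_rate, 0.04, tolerance = 1e-7)   # A * k_obs

  flat <- fitProgressCurve(t, rep(0, length(t)))
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$initial_rate, 0)
  expect_false(flat$converged)

  lin <- fitProgressCurve(c(0, 1, 2, 3, 4, 5), c(0, 2, 4, 6, 8, 10),
                          mode = "linear_initial")
  expect_equal(lin$initial_rate, 2)

  # 2% noise: amplitude recovered within 5% (median over 100 draws)
  set.seed(6)
  err <- replicate(100, {
    yn <- y + rnorm(length(y), 0, 0.02 * 0.8)
    abs(fitProgressCurve(t, yn)$amplitude - 0.8) / 0.8
  })
  expect_lt(median(err), 0.05)
})

test_that("signal normalisation maps controls to 0 and 1", {
  expect_equal(normalizeProgressSignal(c(10, 55, 100), 10, 100), c(0, 0.5, 1))
  expect_error(normalizeProgressSignal(1, 5, 5), "equal")
})

test_that("Hill fits recover generating parameters and their defining property", {
  conc <- 2 * 10^seq(-1.5, 1.5, length.out = 8)
  resp <- 1 * conc^2 / (2^2 + conc^2)
  fit <- hillFit(conc, resp)
  expect_equal(fit$y_max, 1, tolerance = 1e-6)
  expect_equal(fit$k_half, 2, tolerance = 1e-6)
  expect_equal(fit$h, 2, tolerance = 1e-6)
  # the fitted curve passes y_max/2 at k_half by construction
  expect_equal(hillPredict(fit$k_half, fit), fit$y_max / 2, tolerance = 1e-12)

  # h fixed to 1: hyperbolic binding; compare with a double-reciprocal
  # (Lineweaver-Burk) closed-form oracle on noise-free data
  hresp <- 3 * conc / (1.5 + conc)
  hfit <- hillFit(conc, hresp, h_fixed = 1)
  inv <- oracle_ols(1 / conc, 1 / hresp)
  expect_equal(hfit$y_max, 1 / inv$intercept, tolerance = 1e-6)
  expect_equal(hfit$k_half, inv$slope / inv$intercept, tolerance = 1e-6)

  expect_error(hillFit(conc, rep(1, 8)), "all responses equal")
  expect_error(hillFit(-conc, resp), "negative")
  expect_error(hillFit(conc[1:3], resp[1:3]), "5 distinct")
})

test_that("exponential decay fits yield half-lives", {
  t <- seq(0, 40, by = 2)
  fit <- expDecayFit(t, exp(-0.1 * t))
  expect_equal(fit$rate, 0.1, tolerance = 1e-8)
  expect_equal(fit$half_life, log(2) / 0.1, tolerance = 1e-7)

  const <- expDecayFit(t, rep(2, length(t)))
  expect_equal(const$rate, 0)
  expect_false(const$converged)

  set.seed(12)
  err <- replicate(50, {
    yn <- exp(-0.1 * t) + rnorm(length(t), 0, 0.01)
    abs(expDecayFit(t, yn)$rate - 0.1) / 0.1
  })
  expect_lt(median(err), 0.05)
})

test_that("ATPase rates convert NADH absorbance slopes with epsilon", {
  t <- 0:10
  expect_equal(atpaseRate(t, 1 - 0.062 * t), 0.1, tolerance = 1e-12)
  expect_equal(atpaseRate(t, rep(0.5, 11)), 0)
  set.seed(4)
  r <- runif(1, 0.01, 0.5)
  expect_equal(atpaseRate(t, 0.9 - 0.62 * r * t), r, tolerance = 1e-12)
  expect_warning(atpaseRate(t, 0.1 + 0.01 * t), "increases")
})

test_that("relative FRET and the spectral correction behave as defined", {
  expect_equal(fretEfficiency(1, 1), 0.5)
  expect_equal(fretEfficiency(1, 0), 0)
  expect_equal(fretEfficiency(0, 1), 1)
  expect_error(fretEfficiency(0, 0), "zero")

  wl <- c(555, 565, 600, 665)
  corr <- correctFretSpectrum(wl, c(5, 11, 4, 7), c(1, 1, 1, 3))
  expect_equal(corr[2], 1)                 # normalised to the 565 nm peak
  expect_equal(corr[4], 4 / 10)
})

test_that("mixing models obey nesting and identify the subunit number", {
  expect_equal(mixingModel(0.25, "noncooperative"), 0.75)
  f <- seq(0, 1, by = 0.05)
  expect_equal(mixingModel(f, "poisoned_n", n = 1), mixingModel(f, "noncooperative"))
  # noncooperative line is the upper envelope of the poisoning family
  for (n in 2:6)
    expect_true(all(mixingModel(f[f > 0 & f < 1], "poisoned_n", n = n) <
                    mixingModel(f[f > 0 & f < 1], "noncooperative")))
  expect_error(mixingModel(0.5, "poisoned_n", n = 0), "n must be")

  fit <- fitMixing(f, (1 - f)^3)
  expect_identical(fit$n, 3L)
  expect_identical(fit$model, "poisoned_n")
  expect_identical(fitMixing(f, 1 - f)$model, "noncooperative")
  expect_equal(nrow(fit$comparison), 6L)
})

test_that("complex partial specific volumes are mass-weighted means", {
  expect_equal(vbarComplex(0, 46000, 0.73, 11000, 0.53), 0.53)
  expect_equal(vbarComplex(1, 30000, 0.73, 30000, 0.53), 0.63)
  expect_equal(vbarComplex(1e6, 46000, 0.73, 11000, 0.53), 0.73,
               tolerance = 1e-4)
  v <- vapply(0:10, vbarComplex, numeric(1), m_protein = 46000,
              vbar_protein = 0.73, m_rna = 11000, vbar_rna = 0.53)
  expect_true(all(diff(v) > 0))            # monotone toward the protein value
  expect_error(vbarComplex(1, 46000, 1.2, 11000, 0.53), "\\(0, 1\\)")
})

test_that("reporter rates use maximum sliding-window slopes and normalisation", {
  # piecewise trace: slope 1 then 5 then 0.5; steepest window slope is 5
  t <- 0:14
  y <- c(0:4, 4 + 5 * (1:5), 29 + 0.5 * (1:5))
  expect_equal(reporterMaxSlope(t, y), 5)
  expect_equal(reporterMaxSlope(0:9, 3 + 2 * (0:9)), 2)
  expect_warning(m <- reporterMaxSlope(0:9, 10 - (0:9)), "non-positive")
  expect_equal(m, -1)

  expect_equal(normalizeToReference(c(CAA = 4, AG = 8), "CAA"),
               c(CAA = 1, AG = 2))
  expect_error(normalizeToReference(c(a = 1), "b"), "unknown reference")
})

test_that("dual-luciferase rates are slopes of the FL/RL ratio", {
  expect_equal(cellReporterRate(c(2, 4, 6), c(2, 2, 2), c(1, 2, 3)), 1)
  expect_equal(cellReporterRate(c(3, 3, 3), c(1, 1, 1), c(1, 2, 3)), 0)
  expect_error(cellReporterRate(c(1, 2), c(1, 0), c(1, 2)), "zero")
  set.seed(19)
  k <- runif(1, 0.2, 3)
  tm <- 1:8
  rl <- runif(8, 1, 2)
  fl <- (5 + k * tm) * rl
  expect_equal(cellReporterRate(fl, rl, tm), k, tolerance = 1e-10)
})

test_that("cellular mRNA concentration follows copies over Avogadro times volume", {
  # hand-derived: 3e5 / (6.02214076e23 * 2425e-15 L) = 2.0543e-7 M
  expect_equal(mrnaConcentration(3e5, 2425), 2.0543e-7, tolerance = 1e-4)
  expect_equal(mrnaConcentration(0, 2425), 0)
  expect_equal(mrnaConcentration(6e5, 2425), 2 * mrnaConcentration(3e5, 2425))
})
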
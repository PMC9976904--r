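pep_row <- function(pep, prot, light, heavy, time = 2, rep = 1) {
  data.frame(protein_id = prot, peptide_seq = pep, condition = "control",
             time_h = time, replicate = rep, intensity_light = light,
             intensity_heavy = heavy)
}

test_that("peptide aggregation medians duplicates then combines per protein", {
  pep <- rbind(pep_row("AAK", "P1", 2, 2), pep_row("AAK", "P1", 4, 4),
               pep_row("CCK", "P1", 5, 5), pep_row("DDK", "P2", 7, 7),
               pep_row("EEK", "P2", 1, 1), pep_row("EEK", "P3", 1, 1))
  out <- aggregatePeptidesToProteins(pep)
  expect_equal(out$n_excluded_peptides, 1L)       # EEK maps to P2 and P3
  tab <- out$table
  expect_equal(tab$intensity_light[tab$protein_id == "P1"], 3 + 5)  # median(2,4)+5
  expect_equal(tab$intensity_light[tab$protein_id == "P2"], 7)

  med <- aggregatePeptidesToProteins(
    rbind(pep_row("A", "P1", 3, 3), pep_row("B", "P1", 5, 5),
          pep_row("C", "P1", 100, 100)), operator = "median")
  expect_equal(med$table$intensity_light, 5)
  expect_error(aggregatePeptidesToProteins(pep[, -2]), "missing column")
})

test_that("fraction heavy is the heavy share of total intensity", {
  expect_equal(fractionHeavy(3, 1), 0.75)
  expect_equal(fractionHeavy(0, 5), 0)
  expect_equal(fractionHeavy(5, 0), 1)
  expect_error(fractionHeavy(0, 0), "zero")
  set.seed(8)
  f <- fractionHeavy(runif(100), runif(100))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("turnover-rate fit recovers exact log-linear kinetics", {
  t <- c(2, 4, 8)
  fit <- fitTurnoverRate(t, exp(-2 + 0.1 * t))
  expect_equal(fit$k, 0.1, tolerance = 1e-12)
  expect_equal(fit$offset, -2, tolerance = 1e-12)
  expect_true(fit$valid)

  const <- fitTurnoverRate(c(0, 2, 4, 8), rep(0.3, 4))
  expect_equal(const$k, 0, tolerance = 1e-12)
  expect_equal(const$p_slope, 1)

  # F_H <= 0 points are dropped before the log; too few points flag the fit
  flagged <- fitTurnoverRate(c(0, 2, 4), c(0, 0.1, 0.2))
  expect_false(flagged$valid)
  expect_equal(flagged$n_points_used, 2L)
})

test_that("rate recovery on a noisy cohort has low median relative error", {
  spec <- simulationSpec(psilac = list(k_range = c(0.02, 0.2)))
  sim <- simulatePsilac(spec, seed = 101)
  d <- sim$data[sim$data$condition == "control", ]
  d$f_h <- fractionHeavy(d$intensity_heavy, d$intensity_light)
  khat <- vapply(split(d, d$protein_id),
                 function(x) fitTurnoverRate(x$time_h, x$f_h)$k, numeric(1))
  rel_err <- abs(khat[sim$truth$protein_id] - sim$truth$k_ctrl) / sim$truth$k_ctrl
  expect_lt(median(rel_err), 0.10)
})

test_that("fit-quality filter requires p < cut in both conditions", {
  mkfit <- function(p) list(k = 0.1, p_slope = p, se_slope = 0.01, valid = TRUE)
  fc <- list(a = mkfit(0.05), b = mkfit(0.05), c = mkfit(0.2))
  ft <- list(a = mkfit(0.05), b = mkfit(0.5), c = mkfit(0.05))
  out <- filterByFitQuality(fc, ft)
  expect_identical(out$retained, "a")
  expect_equal(out$counts, c(input = 3L, retained = 1L, removed = 2L))
  empty <- filterByFitQuality(list(), list())
  expect_equal(empty$counts, c(input = 0L, retained = 0L, removed = 0L))
})

test_that("condition comparison computes differences, fold changes and FDR", {
  mkfit <- function(k, se = 0.01) list(k = k, se_slope = se, p_slope = 0.01,
                                       valid = TRUE)
  fc <- list(a = mkfit(0.1), b = mkfit(0.1))
  ft <- list(a = mkfit(0.1), b = mkfit(0.05))
  rec <- compareConditions(fc, ft)
  expect_equal(rec$diff[rec$protein_id == "a"], 0)
  expect_equal(rec$log2fc[rec$protein_id == "a"], 0)
  expect_equal(rec$log2fc[rec$protein_id == "b"], -1)
  expect_equal(rec$p_diff[rec$protein_id == "a"], 1)

  # non-positive rate: log2fc undefined, difference still reported
  fneg <- list(a = mkfit(-0.02))
  rec2 <- compareConditions(list(a = mkfit(0.1)), fneg)
  expect_true(is.na(rec2$log2fc))
  expect_equal(rec2$diff, -0.12)
})

test_that("null cohorts produce almost no dependent calls", {
  spec <- simulationSpec(psilac = list(dependent_fraction = 0,
                                       n_proteins = 500L))
  sim <- simulatePsilac(spec, seed = 77)
  out <- suppressMessages(runPsilacPipeline(withr::local_tempdir(), sim$data))
  expect_lte(sum(out$dependence$label == "dependent"),
             0.01 * nrow(out$dependence))
})

test_that("dependence labels follow the FDR thresholds", {
  rec <- data.frame(protein_id = c("a", "b", "c"), fdr = c(0.05, 0.8, 0.4))
  lab <- classifyDependence(rec)$label
  expect_identical(lab, c("dependent", "independent", "unclassified"))
})

test_that("classification counts are invariant to protein input order", {
  sim <- simulatePsilac(simulationSpec(), seed = 31)
  run <- function(d) {
    out <- suppressMessages(runPsilacPipeline(withr::local_tempdir(), d))
    table(out$dependence$label)
  }
  shuffled <- sim$data[sample(nrow(sim$data)), ]
  expect_identical(run(sim$data), run(shuffled))
})

test_that("noise-free cohorts are recovered exactly", {
  spec <- simulationSpec(psilac = list(cv = 0, n_proteins = 20L))
  sim <- simulatePsilac(spec, seed = 9)
  d <- sim$data
  d$f_h <- fractionHeavy(d$intensity_heavy, d$intensity_light)
  for (cond in c("control", "treated")) {
    dd <- d[d$condition == cond, ]
    khat <- vapply(split(dd, dd$protein_id),
                   function(x) fitTurnoverRate(x$time_h, x$f_h)$k, numeric(1))
    ktrue <- if (cond == "control") sim$truth$k_ctrl else sim$truth$k_treat
    expect_equal(unname(khat[sim$truth$protein_id]), ktrue, tolerance = 1e-9)
  }
})
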
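test_that("external curves fit by OLS with a linearity flag", {
  ser <- data.frame(conc_pmol_per_ul = c(0, 1, 2), area = c(0, 200, 400))
  fit <- fit_external_curve(ser)
  expect_equal(fit$slope, 200)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$flag, "")
  # noisy series: slope recovered within 2%
  noisy <- simulate_standard_series("external", slope = 200,
                                    noise_cv = 0.01, seed = 3)
  expect_equal(fit_external_curve(noisy)$slope, 200, tolerance = 0.02)
  # degenerate inputs
  expect_error(fit_external_curve(ser[1:2, ]), "at least 3")
  flat <- data.frame(conc_pmol_per_ul = c(0, 1, 2), area = c(5, 5, 5))
  expect_error(fit_external_curve(flat), "zero slope")
})

test_that("curve inversion floors negative concentrations", {
  fit <- structure(list(slope = 200, intercept = 0), class = "curve_fit")
  expect_equal(quantify_by_curve(300, fit), 1.5)
  fit$intercept <- 100
  expect_warning(out <- quantify_by_curve(50, fit), "floored")
  expect_equal(out, 0)
  expect_equal(quantify_by_curve(100, fit), 0)
  fit$slope <- -1
  expect_error(quantify_by_curve(300, fit), "slope")
})

test_that("standard addition extrapolates the x-intercept", {
  ser <- data.frame(conc_pmol_per_ul = c(0, 0.5, 1.0, 1.5, 2.0),
                    area = c(300, 400, 500, 600, 700))
  est <- standard_addition(ser)
  expect_equal(est$endogenous, 1.5, tolerance = 1e-12)
  # no endogenous signal
  ser0 <- data.frame(conc_pmol_per_ul = c(0, 0.5, 1.0, 1.5, 2.0),
                     area = c(0, 100, 200, 300, 400))
  expect_equal(standard_addition(ser0)$endogenous, 0, tolerance = 1e-12)
  # scale invariance: multiplying all areas leaves the estimate alone
  ser2 <- ser; ser2$area <- ser$area * 7.3
  expect_equal(standard_addition(ser2)$endogenous, est$endogenous,
               tolerance = 1e-12)
  # negative intercept reported as 0 with a warning
  neg <- data.frame(conc_pmol_per_ul = c(0, 1, 2), area = c(-50, 150, 350))
  expect_warning(out <- standard_addition(neg), "negative intercept")
  expect_equal(out$endogenous, 0)
})

test_that("standard addition is nearly unbiased under 1% noise", {
  est <- vapply(1:200, function(s) {
    ser <- simulate_standard_series("addition", 1.5, 200, 0.01, seed = s)
    standard_addition(ser)$endogenous
  }, numeric(1))
  expect_equal(mean(est), 1.5, tolerance = 0.02)
})

test_that("noiseless simulate-then-quantify recovers planted amounts", {
  fit <- fit_external_curve(
    simulate_standard_series("external", slope = 350, noise_cv = 0))
  for (pmol in c(0.2, 1.1, 1.9)) {
    expect_equal(quantify_by_curve(350 * pmol, fit), pmol,
                 tolerance = 1e-9)
  }
})

test_that("conversion factors transfer standard-addition calibration", {
  expect_equal(conversion_factor(2, 3), 1.5)
  expect_error(conversion_factor(0, 3), "positive")
})

test_that("class composition normalizes to 100 mol% over absolute classes", {
  q <- data.frame(class = c("PC", "PI", "PE", "PS", "ERG", "PA", "PG", "CL"),
                  pmol = c(40, 20, 18, 16, 4, 1, 0.5, 0.5))
  comp <- class_composition(q)
  expect_equal(sum(comp$mol_percent), 100, tolerance = 1e-9)
  expect_equal(comp$mol_percent[comp$class == "PC"], 40)
  expect_equal(class_composition(data.frame(class = "PI", pmol = 3))$mol_percent,
               100)
  # relative-only species (sphingolipids) never enter the denominator
  q2 <- rbind(q, data.frame(class = "IPC", pmol = 10))
  q2$relative_only <- q2$class == "IPC"
  expect_equal(class_composition(q2)$mol_percent[
    class_composition(q2)$class == "PC"], 40)
  expect_error(class_composition(data.frame(class = "PC", pmol = 0)),
               "all-zero")
})

test_that("pooled Student's t matches the closed form and stats::t.test", {
  expect_equal(two_sample_ttest(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 4, p = 1))
  tt <- two_sample_ttest(c(1, 2, 3), c(5, 6, 7))
  expect_equal(tt$t, -4.899, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  # 2 * pt(-2 * sqrt(6), 4)
  expect_equal(tt$p, 0.0080499, tolerance = 1e-4)
  expect_error(two_sample_ttest(1, c(2, 3)), "at least 2")
  # cross-check against the reference implementation on random draws
  set.seed(42)
  for (i in 1:5) {
    a <- rnorm(4, 1); b <- rnorm(5, 2)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    mine <- two_sample_ttest(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    refw <- stats::t.test(a, b)
    minew <- two_sample_ttest(a, b, welch = TRUE)
    expect_equal(minew$df, unname(refw$parameter), tolerance = 1e-9)
    expect_equal(minew$p, refw$p.value, tolerance = 1e-12)
  }
})

test_that("sphingolipid/ergosterol report computes folds and labels", {
  mk <- function(ipc_ratios) data.frame(ipc = ipc_ratios, mipc = ipc_ratios,
                                        erg = rep(1, length(ipc_ratios)))
  rep1 <- sphingolipid_ratio_report(mk(c(0.8, 0.8, 0.8)),
                                    mk(c(0.2, 0.2, 0.2)))
  expect_equal(rep1$ipc_erg$fold_change, 4.0)
  # identical groups: fold 1, p = 1
  same <- sphingolipid_ratio_report(mk(c(0.5, 0.5, 0.5)),
                                    mk(c(0.5, 0.5, 0.5)))
  expect_equal(same$ipc_erg$fold_change, 1.0)
  expect_equal(same$ipc_erg$p, 1)
  # hand-computed pooled t: means 0.8 vs 0.2, pooled var 0.00625
  rep2 <- sphingolipid_ratio_report(mk(c(0.7, 0.8, 0.9)),
                                    mk(c(0.15, 0.2, 0.25)))
  expect_equal(rep2$ipc_erg$t, 9.29516, tolerance = 1e-5)
  expect_equal(rep2$ipc_erg$p, 0.00074531, tolerance = 1e-4)
  expect_equal(rep2$ipc_erg$label, "**")
  expect_equal(rep2$ipc_erg$sem_mcp, 0.1 / sqrt(3), tolerance = 1e-9)
  expect_error(sphingolipid_ratio_report(mk(c(0.5, 0.5))[1, , drop = FALSE],
                                         mk(c(0.2, 0.2))),
               "at least 2")
  bad <- mk(c(0.5, 0.5)); bad$erg <- c(1, 0)
  expect_error(sphingolipid_ratio_report(bad, mk(c(0.2, 0.2))),
               "ergosterol")
})

test_that("embedded domain fold changes are recovered from simulations", {
  for (fold in c(2, 8)) {
    est <- vapply(1:15, function(s) {
      g <- simulate_domain_ratios(s, fold = fold, cv = 0.10, n = 3)
      sphingolipid_ratio_report(g$mcp, g$mcc)$ipc_erg$fold_change
    }, numeric(1))
    expect_lt(abs(stats::median(est) - fold) / fold, 0.15)
  }
})

test_that("lipids per SMALP is the 1:1 molar ratio, reported integer", {
  out <- lipids_per_smalp(870, 10)
  expect_equal(out$lipids_per_smalp, 87L)
  expect_equal(lipids_per_smalp(0, 10)$lipids_per_smalp, 0L)
  expect_error(lipids_per_smalp(870, 0), "positive")
})
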
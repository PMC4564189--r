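# Gel quantitation, burst fits, hyperbolic kobs-[dNTP] fits, catalytic
# efficiencies.

test_that("gel-product quantitation with zero-point correction", {
  expect_equal(product_from_gel(1, 1, 0, 200), 100)
  expect_equal(product_from_gel(0, 1, 0, 200), 0)
  expect_equal(product_from_gel(300, 700, 0.05, 200), 50)
  expect_equal(product_from_gel(1, 99, 0.05, 200), 0)  # floored at 0
  expect_error(product_from_gel(0, 0, 0, 200), "both signals zero")
  expect_error(product_from_gel(-1, 2, 0, 200), ">= 0")
})

test_that("burst fit recovers noiseless parameters to 1e-6 relative", {
  tt <- seq(0, 20, by = 0.5)
  tc <- simulate_timecourse(A = 100, kobs = 0.5, C = 5, times = tt)
  fit <- fit_burst(tc)
  expect_false(fit$flagged)
  expect_lt(abs(fit$A - 100) / 100, 1e-6)
  expect_lt(abs(fit$kobs - 0.5) / 0.5, 1e-6)
  expect_lt(abs(fit$C - 5) / 5, 1e-6)
})

test_that("burst fit on noisy data matches a grid-search oracle", {
  tt <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 20)
  tc <- simulate_timecourse(A = 100, kobs = 0.5, C = 5, times = tt,
                            noise_sd = 2, seed = 13)
  fit <- fit_burst(tc)
  or <- oracle_burst_grid(tc$time_s, tc$product_nM,
                          A_range = c(50, 150), k_range = c(0.05, 2),
                          C_range = c(-10, 20))
  # the fit must be at least as good as the oracle optimum and agree with it
  expect_lte(fit$sse, or[["sse"]] + 1e-6)
  expect_lt(abs(fit$A - or[["A"]]) / or[["A"]], 0.02)
  expect_lt(abs(fit$kobs - or[["k"]]) / or[["k"]], 0.02)
  # and recover the generating parameters within 10%
  expect_lt(abs(fit$A - 100) / 100, 0.10)
  expect_lt(abs(fit$kobs - 0.5) / 0.5, 0.10)
})

test_that("constant time courses collapse to the kobs = 0 boundary, flagged", {
  tc <- data.frame(time_s = c(0, 1, 2, 3, 4), product_nM = rep(7, 5))
  fit <- fit_burst(tc)
  expect_true(fit$flagged)
  expect_lt(fit$kobs, 1e-6)
  expect_error(fit_burst(tc[1:3, ]), "at least 4")
})

test_that("hyperbolic fit recovers noiseless parameters and half-saturation", {
  conc <- c(1, 2, 5, 10, 25, 50, 100, 250, 500)
  kobs <- 0.58 * conc / (14.0 + conc)
  fit <- fit_mm(conc, kobs)
  expect_lt(abs(fit$kpol - 0.58) / 0.58, 1e-6)
  expect_lt(abs(fit$Kd - 14.0) / 14.0, 1e-6)
  expect_false(fit$poorly_constrained)
  # kobs at [dNTP] = Kd is kpol/2
  expect_equal(0.58 * 14 / (14 + 14), 0.58 / 2)
  expect_error(fit_mm(c(1, 1, 2), c(.1, .1, .2)), "3 distinct")
})

test_that("hyperbolic fit on noisy data near published lesion-bypass
           constants matches a 2-D grid oracle within 10%", {
  kpol_true <- 0.0060; Kd_true <- 83
  conc <- c(5, 10, 25, 50, 100, 200, 350, 500)
  kobs_clean <- kpol_true * conc / (Kd_true + conc)
  # 1.5% relative error on each rate constant: the precision of careful
  # single-turnover data, and the level at which an 8-point design
  # constrains Kd to ~5% so a 10% recovery check has power
  kobs <- .with_seed_test(17, kobs_clean * (1 + rnorm(length(conc), 0, 0.015)))
  fit <- fit_mm(conc, kobs)
  or <- oracle_mm_grid(conc, kobs, kpol_range = c(1e-4, 0.05),
                       Kd_range = c(1, 500))
  expect_lte(fit$sse, or[["sse"]] + 1e-12)
  expect_lt(abs(fit$kpol - or[["kpol"]]) / or[["kpol"]], 0.02)
  expect_lt(abs(fit$Kd - or[["Kd"]]) / or[["Kd"]], 0.02)
  expect_lt(abs(fit$kpol - kpol_true) / kpol_true, 0.10)
  expect_lt(abs(fit$Kd - Kd_true) / Kd_true, 0.10)
  expect_true(is.finite(fit$kpol_se) && is.finite(fit$Kd_se))
})

test_that("a Kd far above the sampled range is flagged poorly constrained", {
  conc <- c(10, 50, 100, 300, 500)
  kobs <- 5 * conc / (10000 + conc)  # nearly linear: Kd unidentifiable
  fit <- fit_mm(conc, kobs)
  expect_true(fit$poorly_constrained)
})

test_that("catalytic efficiencies reproduce tabulated arithmetic", {
  e1 <- efficiency(0.58, 14.0)
  expect_equal(e1$reported, 41400)
  e2 <- efficiency(0.902, 207)
  expect_equal(e2$reported, 4360)
  expect_equal(efficiency(0, 14)$value, 0)
  expect_error(efficiency(0.5, 0), "Kd")
  # ratio identity before rounding
  a <- efficiency(0.58, 14); b <- efficiency(0.902, 207)
  expect_equal(a$value / b$value, (0.58 * 207) / (0.902 * 14))
})

test_that("efficiency fold changes match the reported ~2.5 and ~0.5", {
  expect_equal(efficiency_ratio(41400, 16700, 2), 2.5)
  expect_equal(efficiency_ratio(2300, 4360, 1), 0.5)
  expect_equal(efficiency_ratio(1234, 1234), 1.0)
  expect_error(efficiency_ratio(1, 0), "denominator")
})

test_that("the bundled constants table is internally consistent except the
           one known discrepant row", {
  rep <- efficiency_report()
  checked <- rep[!is.na(rep$consistent), ]
  expect_equal(nrow(checked), 11L)
  bad <- checked[!checked$consistent, ]
  expect_equal(nrow(bad), 1L)
  expect_identical(bad$enzyme, "PolIV-T120P")
  expect_identical(bad$dntp, "dTTP")
  expect_identical(bad$lesion, "none")
  # the discrepant row recomputes to ~12,300, not the reported 2,300
  expect_equal(signif(bad$recomputed_eff, 3), 12300)
})

test_that("misincorporation screening flags efficiencies below 10% of the
           correct pair", {
  expect_true(misincorporation_flags(100, 4360))
  expect_false(misincorporation_flags(2300, 4360))
  expect_identical(misincorporation_flags(c(5, 50, 500), 600),
                   c(TRUE, TRUE, FALSE))
  # simulated competing-dNTP dataset: correct pair vs three wrong dNTPs
  correct <- efficiency(0.6, 15)$value
  wrong <- vapply(list(c(0.004, 120), c(0.01, 300), c(0.002, 80)),
                  function(p) efficiency(p[1], p[2])$value, 0)
  expect_true(all(misincorporation_flags(wrong, correct)))
})
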
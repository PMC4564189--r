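# Bead image rendering and sub-pixel 2D Gaussian localization.

make_spot_frame <- function(nx = 24, ny = 24, x0, y0, sd = 1.3,
                            photons = 1e5, background = 5, poisson = FALSE,
                            seed = 1) {
  gx <- pnorm(seq_len(nx) + 0.5, x0, sd) - pnorm(seq_len(nx) - 0.5, x0, sd)
  gy <- pnorm(seq_len(ny) + 0.5, y0, sd) - pnorm(seq_len(ny) - 0.5, y0, sd)
  lam <- photons * outer(gy, gx) + background
  if (poisson) .with_seed_test(seed, matrix(rpois(length(lam), lam), nrow = ny))
  else lam
}

test_that("a noiseless synthetic spot is localized within 1e-3 px", {
  fr <- make_spot_frame(x0 = 10.30, y0 = 7.80)
  loc <- localize_bead(fr, c(10, 8), roi_halfwidth = 6)
  expect_true(loc$ok)
  expect_lt(abs(loc$x - 10.30), 1e-3)
  expect_lt(abs(loc$y - 7.80), 1e-3)
})

test_that("a symmetric spot at the ROI center is recovered at the exact
           center, and a flat ROI errors", {
  fr <- make_spot_frame(nx = 21, ny = 21, x0 = 11, y0 = 11)
  loc <- localize_bead(fr, c(11, 11), roi_halfwidth = 7)
  expect_lt(abs(loc$x - 11), 1e-6)
  expect_lt(abs(loc$y - 11), 1e-6)
  expect_error(localize_bead(matrix(3, 30, 30), c(15, 15), 7), "no bead")
  expect_error(localize_bead(fr, c(2, 2), 7), "outside")
})

test_that("localization is unbiased over random sub-pixel placements and
           improves with photon budget", {
  set.seed(123)
  errs <- replicate(60, {
    x0 <- 12 + runif(1, -0.5, 0.5); y0 <- 12 + runif(1, -0.5, 0.5)
    fr <- make_spot_frame(x0 = x0, y0 = y0, photons = 1e6, poisson = TRUE,
                          seed = sample.int(1e6, 1))
    loc <- localize_bead(fr, c(12, 12), roi_halfwidth = 7)
    loc$x - x0
  })
  expect_lt(abs(mean(errs)), 0.01)
  rmse_at <- function(photons) {
    e <- replicate(25, {
      x0 <- 12 + runif(1, -0.5, 0.5)
      fr <- make_spot_frame(x0 = x0, y0 = 12, photons = photons,
                            poisson = TRUE, seed = sample.int(1e6, 1))
      localize_bead(fr, c(12, 12), 7)$x - x0
    })
    sqrt(mean(e^2))
  }
  r3 <- rmse_at(1e3); r4 <- rmse_at(1e4); r6 <- rmse_at(1e6)
  expect_gt(r3, r4)
  expect_gt(r4, r6)
  expect_lt(r6, 0.05)
})

test_that("bead stacks are seeded, reproducible, and store true centers", {
  cal <- calibration(0.2)
  cfg <- sim_config(noise_sd = 0, duration = 5, seed = 2,
                    pause_exit_rates = c(pol3 = Inf, pol4 = 0),
                    pol3_rate_gsd = 1, pol3_rate_median = 300,
                    pol3_term_hazard = 0)
  tr <- simulate_trajectory(cfg)
  st1 <- simulate_bead_stack(tr, cal, pixel_size_nm = 100, seed = 9)
  st2 <- simulate_bead_stack(tr, cal, pixel_size_nm = 100, seed = 9)
  expect_identical(st1$frames, st2$frames)
  expect_equal(nrow(st1$centers), length(tr$time))
  # stationary trajectory: all true centers identical
  st3 <- simulate_bead_stack(rep(0, 8), cal, seed = 3)
  expect_equal(length(unique(st3$centers$x_px)), 1L)
  expect_error(simulate_bead_stack(rep(0, 4), cal, psf_sd_px = 0.3),
               "unresolvable")
})

test_that("bead stacks round-trip through 16-bit TIFF with sidecar centers", {
  cal <- calibration(0.2)
  st <- simulate_bead_stack(c(0, 50, 100, 150), cal, photon_budget = 2000,
                            seed = 4)
  tf <- tempfile(fileext = ".tif"); cf <- tempfile(fileext = ".csv")
  write_bead_stack(st, tf, cf)
  rt <- read_bead_stack(tf, cf)
  expect_equal(rt$frames, st$frames)
  expect_equal(rt$centers$x_px, st$centers$x_px, tolerance = 1e-6)
  unlink(c(tf, cf))
})

test_that("tracking a rendered stack recovers the input trace in bp", {
  cal <- calibration(0.2)
  cfg <- sim_config(noise_sd = 0, duration = 20, seed = 5,
                    pause_exit_rates = c(pol3 = Inf, pol4 = 0),
                    pol3_rate_gsd = 1, pol3_rate_median = 100,
                    pol3_term_hazard = 0)
  tr <- simulate_trajectory(cfg)
  st <- simulate_bead_stack(tr, cal, pixel_size_nm = 100,
                            photon_budget = 2e5, seed = 6)
  out <- track_stack(st)
  expect_equal(nrow(out), length(tr$time))
  expect_true(all(out$ok))
  resid <- out$x_bp - (tr$position - tr$position[1])
  # high-SNR tracking: bp residuals far below the 70 bp thermal noise floor
  expect_lt(sqrt(mean(resid^2)), 0.2 * 70)
})

test_that("a stationary stack yields a trace SD consistent with shot-noise
           localization, and a single frame yields a single point", {
  cal <- calibration(0.2)
  st <- simulate_bead_stack(rep(0, 40), cal, photon_budget = 2e4, seed = 7)
  out <- track_stack(st)
  sd_px <- sd(out$x_px)
  # shot-noise localization precision is roughly psf_sd/sqrt(N)
  expect_lt(sd_px, 5 * 1.3 / sqrt(2e4))
  expect_gt(sd_px, 0)
  st1 <- simulate_bead_stack(0, cal, seed = 8)
  out1 <- track_stack(st1)
  expect_equal(nrow(out1), 1L)
})
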
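# Synthetic flow-stretch generator: determinism, constructed events,
# distributional ground truth, noise model, kinetic time courses.

test_that("config validation rejects invalid values", {
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(template_len = -5), "template_len")
  expect_error(sim_config(pol3_rate_median = 5, pol4_rate_median = 10),
               "fast/slow")
  expect_error(sim_config(pause_exit_rates = c(pol3 = 0, pol4 = 0)),
               "total pause exit rate")
  expect_error(sim_config(noise_sd = NaN), "finite")
})

test_that("identical seed and config give identical trajectories", {
  cfg <- sim_config(seed = 11, n_molecules = 3, duration = 60)
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  expect_identical(a, b)
  # and a different seed gives different noise
  cfg2 <- cfg; cfg2$seed <- 12L
  c2 <- simulate_trajectories(cfg2)
  expect_false(identical(a$trajectories[[1]]$position,
                         c2$trajectories[[1]]$position))
})

test_that("a noiseless forced fast-polymerase event has exactly its rate", {
  cfg <- sim_config(noise_sd = 0,
                    pol3_rate_median = 100, pol3_rate_gsd = 1,
                    pol3_term_hazard = 0,  # no intrinsic termination
                    pause_exit_rates = c(pol3 = Inf, pol4 = 0),
                    duration = 20, seed = 1)
  tr <- simulate_trajectory(cfg)
  expect_equal(nrow(tr$events), 1L)
  expect_identical(tr$events$pol_id, "POL3")
  slopes <- diff(tr$position) / diff(tr$time)
  expect_equal(slopes, rep(100, length(slopes)))
})

test_that("true event extents follow the exponential mean 1/hazard", {
  hazard <- 0.004
  cfg <- sim_config(pol3_term_hazard = hazard, displacement_hazard = 0,
                    pause_exit_rates = c(pol3 = 0.1, pol4 = 0),
                    duration = 200, template_len = 1e7,  # no template truncation
                    n_molecules = 500, noise_sd = 0, seed = 21)
  truth <- truth_events_df(simulate_trajectories(cfg))
  ext <- with(truth[truth$pol_id == "POL3" & truth$ended_by == "intrinsic", ],
              nt_end - nt_start)
  expect_gt(length(ext), 500)
  se <- sd(ext) / sqrt(length(ext))
  expect_lt(abs(mean(ext) - 1 / hazard), 3 * se)
})

test_that("pause durations follow the total exit rate", {
  cfg <- sim_config(pause_exit_rates = c(pol3 = 0.08, pol4 = 0.02),
                    duration = 400, template_len = 1e7,
                    n_molecules = 300, noise_sd = 0, seed = 22)
  sim <- simulate_trajectories(cfg)
  pauses <- unlist(lapply(sim$trajectories, function(tr) {
    ev <- tr$events
    if (nrow(ev) < 2) return(numeric(0))
    ev$t_start[-1] - ev$t_end[-nrow(ev)]  # interior pauses only
  }))
  expect_gt(length(pauses), 500)
  se <- sd(pauses) / sqrt(length(pauses))
  expect_lt(abs(mean(pauses) - 1 / 0.1), 3 * se)
  # species chosen proportional to exit rates
  truth <- truth_events_df(sim)
  frac3 <- mean(truth$pol_id == "POL3")
  expect_lt(abs(frac3 - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(truth)))
})

test_that("truth is non-decreasing and conserved within the template", {
  conds <- list(alone = sim_config(n_molecules = 10, duration = 150),
                mixed = sim_config(n_molecules = 10, duration = 150,
                                   pause_exit_rates = c(pol3 = 0.05, pol4 = 0.05)))
  sim <- simulate_experiment(conds, seed = 23)
  expect_identical(names(sim), c("alone", "mixed"))
  for (set in sim) {
    for (tr in set$trajectories) {
      expect_true(all(diff(tr$truth_position) >= -1e-9))
      expect_lte(max(tr$truth_position), tr$template_len + 1e-9)
      ev <- tr$events
      if (nrow(ev) >= 2) {
        expect_true(all(ev$t_start[-1] >= ev$t_end[-nrow(ev)] - 1e-9))
      }
      expect_true(all(ev$nt_end >= ev$nt_start))
    }
  }
  expect_error(simulate_experiment(list(a = conds[[1]], a = conds[[2]]),
                                   seed = 1),
               "unique")
})

test_that("a displacement hazard equal to the intrinsic hazard halves the
           true mean fast-polymerase extent", {
  h <- 1 / 1000
  base <- sim_config(pol3_term_hazard = h, displacement_hazard = 0,
                     pause_exit_rates = c(pol3 = 0.1, pol4 = 0),
                     duration = 150, template_len = 1e7,
                     n_molecules = 400, noise_sd = 0)
  disp <- base; disp$displacement_hazard <- h
  sim <- simulate_experiment(list(alone = base, displaced = disp), seed = 31)
  ext <- function(lab) {
    tr <- truth_events_df(sim[[lab]])
    tr <- tr[tr$ended_by %in% c("intrinsic", "displaced"), ]
    tr$nt_end - tr$nt_start
  }
  ea <- ext("alone"); ed <- ext("displaced")
  r <- mean(ed) / mean(ea)
  se_r <- r * sqrt(1 / length(ea) + 1 / length(ed))  # exponential: CV = 1
  expect_lt(abs(r - 0.5), 3 * se_r)
  # displaced endings actually occur, about half the time
  trd <- truth_events_df(sim$displaced)
  expect_gt(mean(trd$ended_by == "displaced"), 0.35)
})

test_that("measurement noise is white Gaussian with the configured SD", {
  cfg <- sim_config(noise_sd = 70, n_molecules = 2, duration = 3000,
                    pause_exit_rates = c(pol3 = 1e-9, pol4 = 0), seed = 41)
  sim <- simulate_trajectories(cfg)
  resid <- unlist(lapply(sim$trajectories,
                         function(tr) tr$position - tr$truth_position))
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) / 70 - 1), 0.05)
  expect_gt(shapiro.test(sample(resid, 3000))$p.value, 1e-4)
})

test_that("kinetic time courses follow the burst equation", {
  tc <- simulate_timecourse(A = 100, kobs = 0.5, C = 5, times = c(0, 1, 2, 5))
  expect_equal(tc$product_nM[1], 5)
  tc2 <- simulate_timecourse(A = 100, kobs = 0.5, C = 5, times = 1000)
  expect_equal(tc2$product_nM, 105, tolerance = 1e-12)
  tc3 <- simulate_timecourse(A = 100, kobs = 0.5, C = 0, times = log(2) / 0.5)
  expect_equal(tc3$product_nM, 50)
  expect_error(simulate_timecourse(100, 0.5, 0, times = c(-1, 1)), "negative")
  expect_error(simulate_timecourse(-1, 0.5, 0, times = 1), ">= 0")
  # noise is seeded and clipped at zero
  tcn <- simulate_timecourse(A = 10, kobs = 0.1, C = 0, times = 0:10,
                             noise_sd = 5, seed = 3)
  expect_identical(tcn, simulate_timecourse(A = 10, kobs = 0.1, C = 0,
                                            times = 0:10, noise_sd = 5,
                                            seed = 3))
  expect_true(all(tcn$product_nM >= 0))
})
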
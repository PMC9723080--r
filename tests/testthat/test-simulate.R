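test_that("noiseless simulation reproduces the closed-form piecewise-linear trajectory", {
  cases <- list(
    list(cfg = simulation_config(noise_sd = 0, scan_jitter_sd = 0,
                                 baseline_sd = 0),
         arm = "control", times = seq(-6, 6, 3), vols = 10:14),
    list(cfg = simulation_config(noise_sd = 0, scan_jitter_sd = 0,
                                 baseline_sd = 0),
         arm = "treated", times = seq(-6, 6, 3),
         vols = c(10, 11, 12, 12, 12)),
    list(cfg = simulation_config(noise_sd = 0, scan_jitter_sd = 0,
                                 baseline_sd = 0, scan_interval = 2,
                                 window_pre = 4, window_post = 4,
                                 baseline_mean = 8, growth_rate = 0.5,
                                 post_growth_rate_control = 0.5),
         arm = "control", times = seq(-4, 4, 2),
         vols = 8 + 0.5 * (seq(-4, 4, 2) + 4))
  )
  for (cs in cases) {
    traj <- simulate_trajectory(cs$cfg, cs$arm, seed = 11)
    expect_equal(traj$time, cs$times)
    expect_equal(traj$volume, cs$vols)
  }
})

test_that("cohort generation is deterministic, respects randomization, and subjects regenerate in isolation", {
  cfg <- simulation_config(arms = c(control = 6L, treated = 2L))
  coh1 <- simulate_cohort(cfg, seed = 5)
  coh2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(coh1$scans, coh2$scans)
  expect_equal(as.vector(table(coh1$arms)[c("control", "treated")]),
               c(6L, 2L))
  expect_equal(length(unique(coh1$scans$subject_id)), 8L)

  # subject 5 can be rebuilt alone from its substream
  alone <- simulate_trajectory(cfg, "control",
                               seed = pidtrial:::substream_seed(5, 5),
                               subject_id = "S0005")
  expect_equal(subject_trajectory(coh1, "S0005")$volume, alone$volume)

  coh3 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(coh1$scans$volume_ml, coh3$scans$volume_ml))
})

test_that("time-0 volumes have the emergent mean and dispersion", {
  cfg <- simulation_config(arms = c(control = 10000L))
  coh <- simulate_cohort(cfg, seed = 2)
  v0 <- coh$scans$volume_ml[coh$scans$time_months == 0]
  expect_length(v0, 10000L)
  expect_equal(mean(v0), 12, tolerance = 0.005)
  sd_theory <- sqrt(cfg$baseline_sd^2 + cfg$noise_sd^2)
  expect_lt(abs(sd(v0) - sd_theory) / sd_theory, 0.03)
})

test_that("survival with zero coefficients is exponential with rate h0", {
  traj <- linear_traj()
  h0 <- 0.1
  draws <- vapply(seq_len(10000L), function(i) {
    simulate_survival(traj, hazard_coefficients(h0 = h0), Inf,
                      seed = 70000 + i)$event_time
  }, numeric(1))
  expect_gt(stats::ks.test(draws, "pexp", h0)$p.value, 0.01)
  expect_equal(mean(draws), 1 / h0, tolerance = 0.03)
})

test_that("larger tumors fail earlier under a positive burden coefficient", {
  small <- linear_traj(v0 = 12)
  big <- volume_trajectory(small$time, small$volume + 2)
  cf <- hazard_coefficients(h0 = 0.05, beta2 = 0.3)
  t_small <- vapply(1:1000, function(i) {
    simulate_survival(small, cf, Inf, seed = i)$event_time
  }, numeric(1))
  t_big <- vapply(1:1000, function(i) {
    simulate_survival(big, cf, Inf, seed = 5000 + i)$event_time
  }, numeric(1))
  expect_lt(mean(t_big), mean(t_small))
  expect_lt(median(t_big), median(t_small))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(scan_interval = 0), "scan_interval")
  expect_error(simulation_config(arms = c(5, 5)), "arms")
  cfg <- simulation_config()
  expect_error(simulate_trajectory(cfg, "placebo", seed = 1), "placebo")
  expect_error(simulate_cohort(cfg), "seed")
  expect_error(
    simulate_survival(linear_traj(), hazard_coefficients(h0 = -1), 10),
    "h0"
  )
  expect_error(
    simulate_survival(volume_trajectory(c(-3, 0), c(10, 11)),
                      hazard_coefficients(h0 = 0.1), 10),
    "post-baseline"
  )
  cens <- simulate_survival(linear_traj(), hazard_coefficients(h0 = 0.1), 0)
  expect_identical(cens, list(event_time = 0, event = FALSE))
})

test_that("volumes are floored at zero and the flooring is counted", {
  cfg <- simulation_config(arms = c(control = 50L), baseline_mean = 0.2,
                           baseline_sd = 0, growth_rate = 0, noise_sd = 0.5)
  coh <- simulate_cohort(cfg, seed = 3)
  expect_true(all(coh$scans$volume_ml >= 0))
  expect_gt(coh$n_floored, 0)
})
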
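test_that("covariate process has the closed-form running integral and slope", {
  # constant 10 mL: rectangle area, zero slope
  flat <- volume_trajectory(seq(0, 12, 3), rep(10, 5))
  cp <- build_covariate_process(flat, list(event_time = 7, event = TRUE))
  expect_equal(cp$start, c(0, 3, 6))
  expect_equal(cp$stop, c(3, 6, 7))
  expect_equal(cp$integral, c(0, 30, 60))
  expect_equal(cp$slope, c(0, 0, 0))
  expect_equal(cp$event, c(FALSE, FALSE, TRUE))

  # linear 10 + t: integral at t = 6 is 10*6 + 36/2 = 78, slope 1
  lin <- volume_trajectory(seq(0, 12, 3), 10 + seq(0, 12, 3))
  cp2 <- build_covariate_process(lin, list(event_time = 8, event = FALSE))
  expect_equal(cp2$integral[cp2$start == 6], 78)
  expect_equal(cp2$slope, rep(1, 3))
  expect_false(any(cp2$event))

  # intervals are contiguous and non-overlapping
  expect_equal(cp2$start[-1L], cp2$stop[-length(cp2$stop)])
})

test_that("boundary processes: single post-baseline scan and early events", {
  # one post-baseline scan but pre-treatment history: two-point slope
  one_post <- volume_trajectory(c(-3, 0), c(11, 12))
  cp <- build_covariate_process(one_post, list(event_time = 5, event = TRUE))
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$slope, 1 / 3)
  # no usable history at all -> degenerate
  expect_error(
    build_covariate_process(volume_trajectory(0, 12),
                            list(event_time = 5, event = TRUE)),
    "fewer than 2 scans"
  )
  # event at/before the first scan -> degenerate at-risk process
  expect_error(
    build_covariate_process(one_post, list(event_time = 0, event = TRUE)),
    "degenerate"
  )
})

test_that("partial likelihood matches the closed form at zero and brute force elsewhere", {
  toy <- toy_cox_records()
  # at beta = 0 each event contributes -log(risk-set size): sizes 3 and 2
  expect_equal(partial_log_likelihood(toy, c(0, 0, 0)),
               -(log(3) + log(2)))
  set.seed(31)
  for (rep in 1:8) {
    b <- stats::rnorm(3, sd = 0.5)
    expect_equal(partial_log_likelihood(toy, b),
                 toy_cox_loglik_bruteforce(toy, b), tolerance = 1e-12)
  }
})

test_that("likelihood is invariant to covariate location shifts and record order", {
  toy <- toy_cox_records()
  b <- c(0.2, -0.1, 0.4)
  shifted <- toy
  shifted$volume <- shifted$volume + 100
  expect_equal(partial_log_likelihood(toy, b),
               partial_log_likelihood(shifted, b), tolerance = 1e-12)
  shuffled <- toy[c(3, 1, 2), ]
  expect_equal(partial_log_likelihood(toy, b),
               partial_log_likelihood(shuffled, b), tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  cfg <- simulation_config(arms = c(control = 30L), baseline_sd = 2)
  coh <- simulate_cohort(cfg, seed = 21)
  coh <- simulate_cohort_survival(coh, hazard_coefficients(h0 = 0.05), 24)
  rec <- cohort_covariate_process(coh)
  set.seed(77)
  for (rep in 1:3) {
    b <- stats::rnorm(3, sd = 0.02)
    g <- partial_log_likelihood_gradient(rec, b)
    g_fd <- vapply(1:3, function(i) {
      h <- rep(0, 3)
      h[i] <- 1e-5
      (partial_log_likelihood(rec, b + h) -
         partial_log_likelihood(rec, b - h)) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(g - g_fd) / pmax(abs(g_fd), 1)), 1e-6)
  }
})

test_that("fit agrees with the survival package on a single active covariate", {
  skip_if_not_installed("survival")
  cfg <- simulation_config(arms = c(control = 120L), baseline_sd = 2)
  coh <- simulate_cohort(cfg, seed = 33)
  coh <- simulate_cohort_survival(
    coh, hazard_coefficients(h0 = 0.04, beta2 = 0.1), 24
  )
  rec <- cohort_covariate_process(coh)
  rec$integral <- 0 # constant columns are dropped from the fit
  rec$slope <- 0
  fit <- fit_cox_pid(rec)
  ref <- survival::coxph(
    survival::Surv(start, stop, event) ~ volume,
    data = rec, ties = "breslow"
  )
  expect_equal(unname(fit$beta["beta2"]), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$standard_errors[2L],
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$beta[c("beta1", "beta3")],
               c(beta1 = 0, beta3 = 0))
})

test_that("fitting recovers generating coefficients with honest uncertainty", {
  cfg <- simulation_config(arms = c(control = 200L), baseline_sd = 3,
                           noise_sd = 1.5, window_post = 24)
  truth <- hazard_coefficients(h0 = 0.04, beta2 = 0.05)
  fits <- lapply(1:5, function(s) {
    coh <- simulate_cohort(cfg, seed = 100 + s)
    coh <- simulate_cohort_survival(coh, truth, 24)
    fit_cox_pid(coh)
  })
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  z2 <- vapply(fits, function(f) {
    (f$beta[["beta2"]] - 0.05) / f$standard_errors[2L]
  }, numeric(1))
  expect_lt(abs(mean(z2)), 3 / sqrt(5))
  null_cover <- vapply(fits, function(f) {
    all(abs(f$beta[c("beta1", "beta3")]) <
          3 * f$standard_errors[c(1L, 3L)])
  }, logical(1))
  expect_gte(sum(null_cover), 4L)
  # subject relabeling does not move the estimate
  coh <- simulate_cohort(cfg, seed = 101)
  coh <- simulate_cohort_survival(coh, truth, 24)
  rec <- cohort_covariate_process(coh)
  ord <- order(rev(seq_len(nrow(rec))))
  expect_equal(fit_cox_pid(rec)$beta, fit_cox_pid(rec[ord, ])$beta,
               tolerance = 1e-8)
})

test_that("sparse-event data warns but still yields a finite likelihood", {
  cfg <- simulation_config(arms = c(control = 12L))
  coh <- simulate_cohort(cfg, seed = 8)
  surv <- data.frame(
    subject_id = cohort_subjects(coh),
    event_time_months = seq(2, 13, length.out = 12),
    event = c(1L, rep(0L, 11))
  )
  rec <- cohort_covariate_process(coh, surv)
  expect_true(is.finite(partial_log_likelihood(rec, c(0, 0, 0))))
  # the fit warns up front; with one event the MLE itself may not exist
  expect_warning(try(fit_cox_pid(rec), silent = TRUE), "unstable")
})
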
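test_that("score levels map to the response categories", {
  expect_equal(score_to_category(c(-3, -2, -1, 0, 1, 2, 3)),
               c("PD", "PD", "SD", "SD", "SD", "PR", "CR"))
  expect_error(score_to_category(4), "invalid")
  expect_error(levin_series(c(0, 4), enhancing = c(0, 5)), "invalid")
})

test_that("compartments combine with any-PD / all-respond logic", {
  cases <- list(
    list(e = -2, ne = 0, out = "PD"),   # either compartment progressing
    list(e = 2, ne = 1, out = "SD"),    # response needs both definite
    list(e = 0, ne = 0, out = "SD"),
    list(e = 2, ne = 2, out = "PR"),
    list(e = 3, ne = 2, out = "PR"),    # CR needs both complete
    list(e = 3, ne = 3, out = "CR"),
    list(e = 3, ne = NA, out = "CR"),   # sole compartment defers
    list(e = NA, ne = -3, out = "PD"),
    list(e = 1, ne = -1, out = "SD")
  )
  for (cs in cases) {
    expect_equal(combine_compartments(cs$e, cs$ne), cs$out)
  }
  expect_error(combine_compartments(NA, NA), "at least one")
})

test_that("series assessment applies confirmation and dates PFS at onset", {
  pd <- assess_series(levin_series(c(0, 8, 16), enhancing = c(0, -2, -2)))
  expect_equal(pd$category, "PD")
  expect_true(pd$confirmed && pd$pfs_event)
  expect_equal(pd$pfs_time, 8)

  cr <- assess_series(levin_series(c(8, 12), enhancing = c(3, 3)))
  expect_equal(cr$category, "CR")
  expect_true(cr$confirmed)
  expect_equal(cr$onset_time, 8)
  expect_false(cr$pfs_event)

  none <- assess_series(levin_series(c(0, 4, 8, 12),
                                     enhancing = c(0, -1, 1, 0)))
  expect_equal(none$category, "SD")
  expect_false(none$pfs_event)
  expect_equal(none$pfs_time, 12)

  # a PD that recovers before confirmation never becomes an event
  recov <- assess_series(levin_series(c(0, 8, 16), enhancing = c(0, -2, 0)))
  expect_false(recov$pfs_event)
  # a confirming scan must be at least the window later
  tooearly <- assess_series(levin_series(c(0, 8, 10),
                                         enhancing = c(0, -2, -2)),
                            confirmation_window = 4)
  expect_false(tooearly$pfs_event)
  # new lesion can bypass confirmation when configured
  nl <- assess_series(levin_series(c(0, 8), enhancing = c(0, -3)),
                      confirm_new_lesion = FALSE)
  expect_true(nl$pfs_event)
  expect_equal(nl$pfs_time, 8)
  expect_equal(assess_series(NULL)$category, "not-evaluable")
})

test_that("stable scans inserted before the event do not change the call", {
  base <- levin_series(c(0, 8, 16), enhancing = c(0, -2, -2))
  padded <- levin_series(c(-8, -4, 0, 8, 16),
                         enhancing = c(0, 0, 0, -2, -2))
  a <- assess_series(base)
  b <- assess_series(padded)
  expect_equal(b$category, a$category)
  expect_equal(b$pfs_time, a$pfs_time)
  expect_equal(b$pfs_event, a$pfs_event)
})

test_that("pseudo-volume accumulates negated scores and is antisymmetric", {
  s <- levin_series(c(4, 8, 12), enhancing = c(-1, -1, -2))
  expect_equal(levin_pseudovolume(s)$volume, c(1, 2, 4))
  expect_equal(
    levin_pseudovolume(levin_series(c(4, 8), enhancing = c(1, 1)))$volume,
    c(-1, -2)
  )
  expect_equal(
    levin_pseudovolume(levin_series(c(2, 4), enhancing = c(0, 0)))$volume,
    c(0, 0)
  )
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    sc <- sample(-2:2, n, replace = TRUE)
    plus <- levin_pseudovolume(levin_series(seq_len(n) * 4, enhancing = sc))
    minus <- levin_pseudovolume(levin_series(seq_len(n) * 4,
                                             enhancing = -sc))
    expect_equal(plus$volume, -minus$volume)
  }
  # the pseudo-volume feeds the PID estimators directly
  grown <- levin_pseudovolume(
    levin_series(c(4, 8, 12, 16), enhancing = c(-1, -1, -1, -1))
  )
  expect_equal(growth_rate(grown, eval_window(4, 16)), 0.25)
})

test_that("the synthetic rater applies the threshold table and flags", {
  expect_equal(simulate_rater(c(80, 50, 20, 0, -30, -45), rater_model()),
               c(-2L, -2L, -1L, 0L, 1L, 2L))
  expect_equal(simulate_rater(0, rater_model(), new_lesion = TRUE), -3L)
  expect_equal(simulate_rater(0, rater_model(), disappearance = TRUE), 3L)
  expect_error(rater_model(pd = 10, worse = 15), "decreasing")
  # noisy rater stays on the scale and is reproducible under a seed
  noisy <- rater_model(rater_noise_sd = 1)
  s1 <- simulate_rater(rep(0, 500), noisy, seed = 4)
  s2 <- simulate_rater(rep(0, 500), noisy, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% -2:2))
  expect_true(any(s1 != 0))
})

test_that("zero-noise rater PFS equals the volume-threshold PFS subject by subject", {
  # fast-growing treated arm so both progressions and responses occur
  cfg <- simulation_config(arms = c(treated = 30L),
                           post_growth_rate_treated = 2, noise_sd = 0.8)
  coh <- simulate_cohort(cfg, seed = 3)
  model <- rater_model()
  for (id in cohort_subjects(coh)) {
    tr <- subject_trajectory(coh, id)
    levin <- assess_series(rate_trajectory(tr, model))
    # independent route: threshold the percent changes directly
    v <- tr$volume
    tw <- tr$time[-1L] * 13 / 3
    pct <- 100 * diff(v) / v[-length(v)]
    pd <- pct >= 50
    not_improved <- pct >= 15
    pfs <- tw[length(tw)]
    ev <- FALSE
    for (i in seq_along(pd)) {
      if (pd[i] &&
          any(tw >= tw[i] + 4 & seq_along(tw) > i & not_improved)) {
        pfs <- tw[i]
        ev <- TRUE
        break
      }
    }
    expect_equal(levin$pfs_time, pfs)
    expect_equal(levin$pfs_event, ev)
  }
})
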
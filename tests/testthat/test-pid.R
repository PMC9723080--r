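test_that("quadrature rules are exact on their polynomial classes", {
  # linear volume, reference at 0: area of the triangle = 6
  traj <- volume_trajectory(c(0, 3, 6), c(12, 13, 14))
  w <- eval_window(0, 6, reference_time = 0)
  expect_equal(integrate_volume_curve(traj, w, "trapezoid"), 6.0)
  expect_equal(integrate_volume_curve(traj, w, "midpoint"), 6.0)
  expect_equal(integrate_volume_curve(traj, w, "simpson"), 6.0)

  # V(t) = t^2 sampled at 0,3,6 with reference volume 0: Simpson is exact
  sq <- volume_trajectory(c(0, 3, 6), c(0, 9, 36))
  expect_equal(integrate_volume_curve(sq, w, "simpson"), 72.0)

  # all three agree to machine precision on linear data over uneven nodes
  set.seed(42)
  for (rep in 1:20) {
    t <- sort(stats::runif(2 + sample(1:6, 1), 0, 6))
    t <- c(0, t[t > 0.1], 6)
    v <- 5 + 0.7 * t
    tr <- volume_trajectory(t, v)
    exact <- 0.7 * 6^2 / 2 # integral of (v - v(0))
    for (m in c("trapezoid", "midpoint", "simpson")) {
      expect_equal(integrate_volume_curve(tr, w, m), exact,
                   tolerance = 1e-12)
    }
  }
})

test_that("quadrature error shrinks at the theoretical order", {
  area_err <- function(n, method, f, exact) {
    t <- seq(0, 6, length.out = n)
    tr <- volume_trajectory(t, f(t), require_nonnegative = FALSE)
    w <- eval_window(0, 6, reference_time = 0)
    abs(integrate_volume_curve(tr, w, method) - exact)
  }
  cubic <- function(t) t^3
  # trapezoid ~ h^2 on t^3
  e_t <- vapply(c(5, 9, 17, 33), area_err, numeric(1), "trapezoid",
                cubic, 6^4 / 4)
  order_t <- log2(e_t[-length(e_t)] / e_t[-1L])
  expect_true(all(abs(order_t - 2) < 0.2))
  # Simpson integrates cubics exactly
  e_s3 <- vapply(c(5, 9), area_err, numeric(1), "simpson", cubic, 6^4 / 4)
  expect_true(all(e_s3 < 1e-9))
  # ... so its finite order is measured on t^4: ~ h^4
  quart <- function(t) t^4
  e_s <- vapply(c(5, 9, 17, 33), area_err, numeric(1), "simpson",
                quart, 6^5 / 5)
  order_s <- log2(e_s[-length(e_s)] / e_s[-1L])
  expect_true(all(abs(order_s - 4) < 0.3))
})

test_that("integration preconditions are enforced", {
  w <- eval_window(0, 6, reference_time = 0)
  expect_error(
    integrate_volume_curve(volume_trajectory(0, 10), w),
    ">= 2 scans"
  )
  far <- volume_trajectory(c(0, 20, 26), c(10, 11, 12))
  expect_error(
    integrate_volume_curve(far, eval_window(19, 26, reference_time = 21.8,
                                            tolerance = 0.5)),
    "no scan within"
  )
})

test_that("tumor burden uses the nearest scan with an earlier tie-break", {
  traj <- volume_trajectory(c(0, 3.1, 6.1), c(12, 13.5, 14.02))
  expect_equal(tumor_burden(traj, 6, tolerance = 1), 14.02)
  expect_equal(tumor_burden(traj, 0), 12)
  # two scans equidistant from the target: the earlier wins
  tie <- volume_trajectory(c(0, 5, 7), c(12, 13, 15))
  expect_equal(tumor_burden(tie, 6, tolerance = 1.5), 13)
  expect_error(tumor_burden(traj, 12, tolerance = 1), "no scan within")
})

test_that("growth rate is the OLS slope over in-window scans", {
  expect_equal(growth_rate(volume_trajectory(c(0, 3, 6), c(10, 11, 12)),
                           eval_window(0, 6)), 1 / 3)
  expect_equal(growth_rate(volume_trajectory(c(0, 3, 6), c(10, 10, 10)),
                           eval_window(0, 6)), 0)
  expect_error(growth_rate(volume_trajectory(0, 10), eval_window(0, 6)),
               ">= 2 scans")
})

test_that("delta identities hold and noiseless subjects give the closed-form deltas", {
  control <- linear_traj()
  d <- compute_delta_pid(control)
  expect_equal(c(d$delta_lambda1, d$delta_lambda2, d$delta_lambda3),
               c(0, 2, 0))
  treated <- linear_traj(slope_post = 0)
  d2 <- compute_delta_pid(treated)
  expect_equal(c(d2$delta_lambda1, d2$delta_lambda2, d2$delta_lambda3),
               c(-6, 0, -1 / 3))

  # deltas always equal post minus pre, recomputed subject by subject
  coh <- simulate_cohort(simulation_config(arms = c(control = 10L,
                                                    treated = 10L)),
                         seed = 9)
  deltas <- cohort_delta_pid(coh)
  expect_equal(deltas$delta_lambda1,
               deltas$lambda1_post - deltas$lambda1_pre)
  expect_equal(deltas$delta_lambda2,
               deltas$lambda2_post - deltas$lambda2_pre)
  expect_equal(deltas$delta_lambda3,
               deltas$lambda3_post - deltas$lambda3_pre)
})

test_that("slope-difference variance reflects the shared-anchor covariance", {
  # Pre and post windows share the unjittered anchor scan, whose noise
  # enters the two slopes with opposite signs: Var(post - pre) is 3x a
  # single window's variance, not 2x. With windows that share no scan the
  # classic doubling reappears.
  coh <- simulate_cohort(simulation_config(arms = c(control = 4000L)),
                         seed = 13)
  deltas <- cohort_delta_pid(coh)
  shared <- var(deltas$delta_lambda3) /
    mean(c(var(deltas$lambda3_pre), var(deltas$lambda3_post)))
  expect_gt(shared, 2.6)
  expect_lt(shared, 3.4)

  ids <- cohort_subjects(coh)
  pre_w <- eval_window(-6, -2)
  post_w <- eval_window(2, 6)
  slopes <- vapply(ids, function(id) {
    tr <- subject_trajectory(coh, id)
    c(growth_rate(tr, pre_w), growth_rate(tr, post_w))
  }, numeric(2))
  disjoint <- var(slopes[2, ] - slopes[1, ]) /
    mean(c(var(slopes[1, ]), var(slopes[2, ])))
  expect_gt(disjoint, 1.8)
  expect_lt(disjoint, 2.2)
})
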
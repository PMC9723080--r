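# PID treatment-effect parameters: lambda1 (tumor control, integral of the
# volume-time curve relative to a reference scan), lambda2 (tumor burden),
# lambda3 (linear growth rate), and their pre-vs-post treatment differences.

#' Evaluation window for PID parameters
#'
#' A closed time window `[start, end]` over which a PID parameter is
#' computed, plus the reference time whose scan anchors the tumor-control
#' integrand. Scan matching at window boundaries and at the reference time
#' uses `tolerance` months (default 1.5, half the nominal quarterly scan
#' interval): a scan belongs to the window when its time lies in
#' `[start - tolerance, end + tolerance]`, which keeps nominal boundary
#' scans whose jittered dates fall just outside the window.
#'
#' @param start,end Window bounds in months, `start < end`.
#' @param reference_time Time whose (nearest) scan provides the reference
#'   volume for the integral; must lie in `[start, end]`. `NULL` means "the
#'   earliest in-window scan" (the historic reference used for
#'   pre-treatment windows).
#' @param tolerance Scan-matching tolerance in months.
#' @return An object of class `eval_window`.
#' @examples
#' eval_window(-6, 0)            # pre-treatment, historic reference
#' eval_window(0, 6, reference_time = 0)  # post-treatment
#' @export
eval_window <- function(start, end, reference_time = NULL, tolerance = 1.5) {
  if (!is.numeric(start) || !is.numeric(end) || start >= end) {
    stop("eval_window needs numeric start < end", call. = FALSE)
  }
  if (!is.null(reference_time) &&
      (reference_time < start || reference_time > end)) {
    stop("reference_time must lie within [start, end]", call. = FALSE)
  }
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  structure(list(start = start, end = end, reference_time = reference_time,
                 tolerance = tolerance),
            class = "eval_window")
}

#' @export
print.eval_window <- function(x, ...) {
  ref <- if (is.null(x$reference_time)) "earliest in-window scan" else
    sprintf("t = %g", x$reference_time)
  cat(sprintf("Evaluation window [%g, %g] months (reference: %s, tolerance %g)\n",
              x$start, x$end, ref, x$tolerance))
  invisible(x)
}

# Scans belonging to a window (tolerance-extended membership).
window_scans <- function(trajectory, window) {
  trajectory <- as_trajectory(trajectory, require_anchor = FALSE)
  keep <- trajectory$time >= window$start - window$tolerance &
    trajectory$time <= window$end + window$tolerance
  trajectory[keep, , drop = FALSE]
}

# Nearest scan to a target time within tolerance; earlier scan wins ties.
nearest_scan <- function(trajectory, at_time, tolerance) {
  d <- abs(trajectory$time - at_time)
  i <- which.min(d) # which.min returns the first (earliest) minimum
  if (!length(i) || d[i] > tolerance) {
    stop(sprintf("no scan within %g months of t = %g (subject %s)",
                 tolerance, at_time, subject_id_of(trajectory)),
         call. = FALSE)
  }
  trajectory[i, , drop = FALSE]
}

# Quadrature of samples (t, f) over [t_1, t_n]; t strictly increasing.
quadrature <- function(t, f, method) {
  n <- length(t)
  trap <- function(i, j) (t[j] - t[i]) * (f[i] + f[j]) / 2
  if (method == "trapezoid") {
    return(sum(diff(t) * (f[-1L] + f[-n]) / 2))
  }
  # pairwise panels [t_i, t_{i+2}]; trailing lone interval -> trapezoid
  total <- 0
  i <- 1L
  while (i + 2L <= n) {
    h0 <- t[i + 1L] - t[i]
    h1 <- t[i + 2L] - t[i + 1L]
    if (method == "simpson") {
      # three-point Newton-Cotes weights for arbitrary nodes
      w <- (h0 + h1) / 6 * c(2 - h1 / h0,
                             (h0 + h1)^2 / (h0 * h1),
                             2 - h0 / h1)
      total <- total + sum(w * f[i:(i + 2L)])
    } else { # midpoint: linear interpolant at the panel's time midpoint
      tm <- (t[i] + t[i + 2L]) / 2
      fm <- stats::approx(t[i:(i + 2L)], f[i:(i + 2L)], xout = tm)$y
      total <- total + fm * (t[i + 2L] - t[i])
    }
    i <- i + 2L
  }
  if (i + 1L <= n) total <- total + trap(i, i + 1L)
  total
}

#' Tumor-control parameter: integral of the volume-time curve
#'
#' Computes `lambda1`, the quadrature approximation of
#' `integral of (V(t') - V(reference)) dt'` over an evaluation window, from
#' the observed (possibly unevenly spaced) scans. The reference volume is
#' the observed volume of the scan nearest `reference_time` (the earliest
#' in-window scan when the window's reference is the historic default).
#' Integration runs over exactly `[start, end]` -- so pre- and
#' post-treatment windows always cover equal durations -- by clipping or
#' linearly extending the sampled polyline at the window bounds; an
#' extension uses the window's OLS slope and can never exceed the
#' scan-matching tolerance.
#'
#' `trapezoid` joins consecutive samples linearly; `midpoint` evaluates the
#' linear interpolant at the time midpoint of each consecutive pair of
#' intervals (equal to the trapezoid on linear data, distinct otherwise);
#' `simpson` fits a quadratic through each consecutive sample triplet with
#' uneven-spacing weights. Midpoint and Simpson fall back to a trapezoid
#' panel for a trailing lone interval.
#'
#' @param trajectory A [volume_trajectory()] (or data frame with `time`,
#'   `volume`).
#' @param window An [eval_window()].
#' @param method `"trapezoid"` (default), `"midpoint"`, or `"simpson"`.
#' @return `lambda1` in mL·months.
#' @examples
#' traj <- volume_trajectory(c(0, 3, 6), c(12, 13, 14))
#' integrate_volume_curve(traj, eval_window(0, 6, reference_time = 0)) # 6
#' @export
integrate_volume_curve <- function(trajectory, window,
                                   method = c("trapezoid", "midpoint",
                                              "simpson")) {
  method <- match.arg(method)
  stopifnot(inherits(window, "eval_window"))
  scans <- window_scans(trajectory, window)
  if (nrow(scans) < 2L) {
    stop(sprintf("need >= 2 scans in window [%g, %g] (found %d, subject %s)",
                 window$start, window$end, nrow(scans),
                 subject_id_of(trajectory)),
         call. = FALSE)
  }
  v_ref <- if (is.null(window$reference_time)) {
    scans$volume[1L]
  } else {
    nearest_scan(scans, window$reference_time, window$tolerance)$volume
  }
  t <- scans$time
  f <- scans$volume - v_ref
  n <- length(t)
  # integrate over exactly [start, end] so pre and post windows always
  # cover equal durations: clip or linearly extend the sampled polyline at
  # the window bounds. Extensions (never longer than the matching
  # tolerance) use the window's OLS slope, which is exact on linear data
  # and, unlike the boundary segment's slope, does not blow up when two
  # jittered scan dates nearly coincide.
  ols <- ols_slope(t, f)
  value_at <- function(x) {
    if (x <= t[1L]) {
      f[1L] + ols * (x - t[1L])
    } else if (x >= t[n]) {
      f[n] + ols * (x - t[n])
    } else {
      stats::approx(t, f, xout = x)$y
    }
  }
  inside <- t > window$start & t < window$end
  quadrature(c(window$start, t[inside], window$end),
             c(value_at(window$start), f[inside], value_at(window$end)),
             method)
}

#' Tumor burden at a time point
#'
#' `lambda2`: the observed volume of the scan nearest `at_time` within
#' `tolerance` months. When two scans are equidistant the earlier one is
#' used (documented tie-break).
#'
#' @param trajectory A [volume_trajectory()].
#' @param at_time Target time in months.
#' @param tolerance Matching tolerance in months.
#' @return Volume in mL.
#' @export
tumor_burden <- function(trajectory, at_time, tolerance = 1.5) {
  trajectory <- as_trajectory(trajectory, require_anchor = FALSE)
  nearest_scan(trajectory, at_time, tolerance)$volume
}

#' Linear growth rate over a window
#'
#' `lambda3`: the ordinary-least-squares slope of volume on time over the
#' scans in the window.
#'
#' @param trajectory A [volume_trajectory()].
#' @param window An [eval_window()].
#' @return Slope in mL/month.
#' @examples
#' traj <- volume_trajectory(c(0, 3, 6), c(10, 11, 12))
#' growth_rate(traj, eval_window(0, 6)) # 1/3
#' @export
growth_rate <- function(trajectory, window) {
  stopifnot(inherits(window, "eval_window"))
  scans <- window_scans(trajectory, window)
  ols_slope(scans$time, scans$volume, subject_id_of(trajectory))
}

ols_slope <- function(t, v, sid = "?") {
  if (length(t) < 2L || max(t) - min(t) <= 0) {
    stop("growth rate needs >= 2 scans with distinct times (subject ",
         sid, ")", call. = FALSE)
  }
  tc <- t - mean(t)
  sum(tc * (v - mean(v))) / sum(tc^2)
}

#' Pre-vs-post treatment change in the PID parameters
#'
#' Computes the per-subject treatment-effect triple: `delta_lambda1 =
#' lambda1(post) - lambda1(pre)` (change in tumor control),
#' `delta_lambda2 = V(post end) - V(0)` (change in burden), and
#' `delta_lambda3 = lambda3(post) - lambda3(pre)` (change in growth rate).
#' By convention the pre-window integral is referenced to the earliest
#' in-window ("historic") scan and the post-window integral to the
#' treatment-start anchor at time 0.
#'
#' @param trajectory A [volume_trajectory()].
#' @param pre,post [eval_window()]s; defaults are `[-6, 0]` with historic
#'   reference and `[0, 6]` referenced at 0.
#' @param method Quadrature method, see [integrate_volume_curve()].
#' @return An object of class `delta_pid`: list with `subject_id`,
#'   per-window `lambda1`, `lambda2`, `lambda3`, and the three deltas.
#' @examples
#' traj <- volume_trajectory(c(-6, -3, 0, 3, 6), c(10, 11, 12, 12, 12))
#' compute_delta_pid(traj) # treated-like subject: dl1 = -6, dl3 = -1/3
#' @export
compute_delta_pid <- function(trajectory,
                              pre = eval_window(-6, 0),
                              post = eval_window(0, 6, reference_time = 0),
                              method = "trapezoid") {
  trajectory <- as_trajectory(trajectory, require_anchor = FALSE)
  tag <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(what, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  l1_pre <- tag("pre-window tumor control", {
    integrate_volume_curve(trajectory, pre, method)
  })
  l1_post <- tag("post-window tumor control", {
    integrate_volume_curve(trajectory, post, method)
  })
  l2_pre <- tag("baseline tumor burden", {
    tumor_burden(trajectory, if (is.null(post$reference_time)) 0 else
      post$reference_time, post$tolerance)
  })
  l2_post <- tag("post-window tumor burden", {
    tumor_burden(trajectory, post$end, post$tolerance)
  })
  l3_pre <- tag("pre-window growth rate", growth_rate(trajectory, pre))
  l3_post <- tag("post-window growth rate", growth_rate(trajectory, post))
  structure(list(
    subject_id = subject_id_of(trajectory),
    lambda1_pre = l1_pre, lambda1_post = l1_post,
    lambda2_pre = l2_pre, lambda2_post = l2_post,
    lambda3_pre = l3_pre, lambda3_post = l3_post,
    delta_lambda1 = l1_post - l1_pre,
    delta_lambda2 = l2_post - l2_pre,
    delta_lambda3 = l3_post - l3_pre
  ), class = "delta_pid")
}

#' @export
print.delta_pid <- function(x, ...) {
  cat("PID treatment-effect parameters, subject", x$subject_id, "\n")
  cat(sprintf("  tumor control  lambda1: pre %8.3f  post %8.3f  delta %8.3f mL.months\n",
              x$lambda1_pre, x$lambda1_post, x$delta_lambda1))
  cat(sprintf("  tumor burden   lambda2: pre %8.3f  post %8.3f  delta %8.3f mL\n",
              x$lambda2_pre, x$lambda2_post, x$delta_lambda2))
  cat(sprintf("  growth rate    lambda3: pre %8.4f  post %8.4f  delta %8.4f mL/month\n",
              x$lambda3_pre, x$lambda3_post, x$delta_lambda3))
  invisible(x)
}

#' Per-subject PID estimates for a whole cohort
#'
#' Applies [compute_delta_pid()] to every subject and returns one row per
#' subject (the CSV schema written by the `estimate` CLI command).
#'
#' @inheritParams compute_delta_pid
#' @param cohort A `pid_cohort` or cohort scan data frame.
#' @return Data frame with columns `subject_id`, `arm` (when known), the six
#'   per-window lambdas and the three deltas.
#' @export
cohort_delta_pid <- function(cohort,
                             pre = eval_window(-6, 0),
                             post = eval_window(0, 6, reference_time = 0),
                             method = "trapezoid") {
  ids <- cohort_subjects(cohort)
  scans <- if (inherits(cohort, "pid_cohort")) cohort$scans else cohort
  rows <- lapply(ids, function(id) {
    traj <- subject_trajectory(cohort, id)
    d <- compute_delta_pid(traj, pre, post, method)
    data.frame(
      subject_id = id,
      arm = if ("arm" %in% names(scans)) {
        scans$arm[scans$subject_id == id][1L]
      } else NA_character_,
      lambda1_pre = d$lambda1_pre, lambda1_post = d$lambda1_post,
      delta_lambda1 = d$delta_lambda1,
      lambda2_pre = d$lambda2_pre, lambda2_post = d$lambda2_post,
      delta_lambda2 = d$delta_lambda2,
      lambda3_pre = d$lambda3_pre, lambda3_post = d$lambda3_post,
      delta_lambda3 = d$delta_lambda3
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
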
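# Cohort simulator: piecewise-linear tumor growth, jittered scan dates,
# additive volumetric noise, and survival draws from the PID hazard.

# Derive a 31-bit substream seed from (seed, index) so any subject is
# reproducible in isolation. The derivation must avalanche: R's
# Mersenne-Twister seeding leaves measurable correlation (~0.04) between
# the first outputs of streams whose seeds differ by an affine relation,
# which is enough to bias a 400-subject simulation when trajectory and
# outcome streams sit at a constant offset. Murmur3-style 32-bit finalizer
# mixing, exact in doubles (all intermediates < 2^53).

u32 <- function(x) x %% 4294967296

# 32-bit modular multiply via 16-bit limbs
mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  u32(((hi * b) %% 65536) * 65536 + lo * b)
}

# bitwise xor of 32-bit values held in doubles
xor32 <- function(a, b) {
  al <- a %% 65536
  bl <- b %% 65536
  bitwXor((a - al) / 65536, (b - bl) / 65536) * 65536 + bitwXor(al, bl)
}

fmix32 <- function(h) {
  h <- xor32(h, floor(h / 65536))
  h <- mul32(h, 2246822507)
  h <- xor32(h, floor(h / 8192))
  h <- mul32(h, 3266489909)
  xor32(h, floor(h / 65536))
}

substream_seed <- function(seed, index) {
  h <- fmix32(u32(as.numeric(seed)))
  h <- fmix32(u32(h + mul32(u32(as.numeric(index)), 2654435769)))
  as.integer(h %% 2147483646) + 1L
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one subject's volume trajectory
#'
#' Draws a single trajectory under the generative model: the true volume is
#' piecewise linear, anchored at `baseline_mean` (SD `baseline_sd`) at the
#' earliest nominal scan time, growing at `growth_rate` before treatment
#' start (time 0) and at the arm-specific post-treatment rate afterwards,
#' continuous at 0. Every nominal scan time except the time-0 anchor is
#' perturbed by Normal(0, `scan_jitter_sd`) truncated at just under half
#' the scan interval (3 SD at the defaults), so a scan never leaves its
#' scheduling slot; the true volume is evaluated at the perturbed
#' acquisition time and the perturbed time is recorded.
#' Observed volume adds Normal(0, `noise_sd`) measurement noise and is
#' floored at 0 mL (the number of floored scans is recorded in the
#' `n_floored` attribute).
#'
#' @param config A [simulation_config()].
#' @param arm Arm label; must be one of `names(config$arms)` (or at least
#'   have a post-treatment growth rate configured).
#' @param seed Integer seed for this subject's random stream.
#' @param subject_id Identifier stored on the trajectory.
#' @return A [volume_trajectory()].
#' @examples
#' cfg <- simulation_config(noise_sd = 0, scan_jitter_sd = 0, baseline_sd = 0)
#' simulate_trajectory(cfg, "control", seed = 1) # exactly 10,11,12,13,14
#' @export
simulate_trajectory <- function(config, arm, seed, subject_id = "S1") {
  config <- validate_simulation_config(config)
  if (!arm %in% names(config$post_growth_rates)) {
    stop("unknown arm '", arm, "': no post-treatment growth rate configured",
         call. = FALSE)
  }
  nominal <- nominal_scan_times(config)
  g_post <- config$post_growth_rates[[arm]]
  with_rng_seed(seed, {
    baseline <- stats::rnorm(1, config$baseline_mean, config$baseline_sd)
    jitter <- stats::rnorm(length(nominal), 0, config$scan_jitter_sd)
    # truncate at just under half the scan interval (3 SD at the defaults):
    # a scan stays attributable to its scheduling slot, scan order is
    # preserved, and every scan remains within matching tolerance
    lim <- 0.999 * config$scan_interval / 2
    jitter <- pmax(pmin(jitter, lim), -lim)
    jitter[nominal == 0] <- 0
    t_obs <- nominal + jitter
    v0 <- baseline + config$growth_rate * (0 - nominal[1L])
    v_true <- ifelse(
      t_obs <= 0,
      baseline + config$growth_rate * (t_obs - nominal[1L]),
      v0 + g_post * t_obs
    )
    v_obs <- v_true + stats::rnorm(length(t_obs), 0, config$noise_sd)
    n_floored <- sum(v_obs < 0)
    v_obs <- pmax(v_obs, 0)
    ord <- order(t_obs)
    traj <- volume_trajectory(t_obs[ord], v_obs[ord], subject_id = subject_id)
    attr(traj, "arm") <- arm
    attr(traj, "n_floored") <- n_floored
    traj
  })
}

#' Simulate a randomized trial cohort
#'
#' Generates one trajectory per subject with [simulate_trajectory()], using
#' per-subject random substreams derived deterministically from
#' `(seed, subject index)`, so the cohort is bitwise reproducible and any
#' single subject can be regenerated in isolation. Subjects are assigned to
#' arms in configuration order (`arms = c(control = 40, treated = 40)` gives
#' subjects 1-40 control, 41-80 treated); arm labels, not subject order,
#' carry the randomization.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed; defaults to `config$seed`.
#' @return An object of class `pid_cohort`: a list with `scans` (data frame
#'   `subject_id`, `arm`, `time_months`, `volume_ml`), `arms`, `config`,
#'   `seed`, and `n_floored` (count of volume observations floored at 0).
#' @examples
#' coh <- simulate_cohort(simulation_config(), seed = 1)
#' coh
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  config <- validate_simulation_config(config)
  if (is.null(seed)) {
    stop("simulate_cohort needs a seed (argument or config$seed)",
         call. = FALSE)
  }
  arm_labels <- rep(names(config$arms), times = config$arms)
  n <- length(arm_labels)
  ids <- sprintf("S%04d", seq_len(n))
  scans <- vector("list", n)
  n_floored <- 0L
  for (i in seq_len(n)) {
    traj <- simulate_trajectory(
      config, arm_labels[i],
      seed = substream_seed(seed, i),
      subject_id = ids[i]
    )
    n_floored <- n_floored + attr(traj, "n_floored")
    scans[[i]] <- data.frame(
      subject_id = ids[i],
      arm = arm_labels[i],
      time_months = traj$time,
      volume_ml = traj$volume
    )
  }
  out <- list(
    scans = do.call(rbind, scans),
    arms = arm_labels,
    config = config,
    seed = seed,
    n_floored = n_floored
  )
  rownames(out$scans) <- NULL
  class(out) <- "pid_cohort"
  out
}

#' @export
print.pid_cohort <- function(x, ...) {
  tab <- table(x$arms)
  cat("Simulated trial cohort: ", length(x$arms), " subjects (",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "), ", nrow(x$scans), " scans\n", sep = "")
  if (x$n_floored > 0) {
    cat("  note:", x$n_floored, "volume observation(s) floored at 0 mL\n")
  }
  invisible(x)
}

#' Subject identifiers of a cohort
#' @param cohort A `pid_cohort` (or cohort scan data frame).
#' @return Character vector of subject ids in cohort order.
#' @export
cohort_subjects <- function(cohort) {
  scans <- if (inherits(cohort, "pid_cohort")) cohort$scans else cohort
  unique(scans$subject_id)
}

#' Extract one subject's trajectory from a cohort
#'
#' @param cohort A `pid_cohort` or a cohort scan data frame with columns
#'   `subject_id`, `time_months`, `volume_ml`.
#' @param subject_id Which subject.
#' @return A [volume_trajectory()] with an `arm` attribute when available.
#' @export
subject_trajectory <- function(cohort, subject_id) {
  scans <- if (inherits(cohort, "pid_cohort")) cohort$scans else cohort
  rows <- scans[scans$subject_id == subject_id, , drop = FALSE]
  if (!nrow(rows)) {
    stop("no scans for subject '", subject_id, "'", call. = FALSE)
  }
  traj <- volume_trajectory(rows$time_months, rows$volume_ml,
                            subject_id = subject_id)
  if ("arm" %in% names(rows)) attr(traj, "arm") <- rows$arm[1L]
  traj
}

#' Coefficients of the PID hazard model
#'
#' The hazard is `h(t) = h0 * exp(beta1 * I(t) + beta2 * V(t) + beta3 *
#' dV/dt)` where `I(t)` is the running integral of volume from treatment
#' start, `V(t)` the current volume and `dV/dt` the current growth rate:
#' the integral ("tumor control"), proportional ("tumor burden") and
#' derivative ("growth rate") components of the trajectory.
#'
#' @param h0 Baseline hazard rate per month (used only for simulation);
#'   must be `> 0` when simulating.
#' @param beta1 Coefficient per mL·month (integral component).
#' @param beta2 Coefficient per mL (proportional component).
#' @param beta3 Coefficient per mL/month (derivative component).
#' @param standard_errors Optional numeric triple of SEs.
#' @return An object of class `hazard_coefficients`.
#' @export
hazard_coefficients <- function(h0 = NA_real_, beta1 = 0, beta2 = 0,
                                beta3 = 0, standard_errors = NULL) {
  for (nm in c("beta1", "beta2", "beta3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("hazard coefficient '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  structure(
    list(h0 = h0, beta = c(beta1 = beta1, beta2 = beta2, beta3 = beta3),
         standard_errors = standard_errors),
    class = "hazard_coefficients"
  )
}

#' @export
print.hazard_coefficients <- function(x, ...) {
  cat("PID hazard coefficients\n")
  cat(sprintf("  h0:    %.4g per month\n", x$h0))
  lab <- c("beta1 (integral, per mL.month)",
           "beta2 (burden,   per mL)      ",
           "beta3 (slope,    per mL/month)")
  for (i in 1:3) {
    se <- if (!is.null(x$standard_errors)) {
      sprintf("  (SE %.4g)", x$standard_errors[i])
    } else ""
    cat(sprintf("  %s: % .5g%s\n", lab[i], x$beta[i], se))
  }
  invisible(x)
}

#' Draw a survival time from the PID hazard
#'
#' Inverse-transform sampling of the cumulative hazard implied by
#' [hazard_coefficients()] with the three covariates held piecewise constant
#' between post-baseline scan times (step functions, last value carried to
#' `max_followup`). The event indicator is `FALSE` (administrative
#' censoring) when the drawn time exceeds `max_followup`.
#'
#' @param trajectory A [volume_trajectory()] with at least 2 observations at
#'   `time >= 0`.
#' @param coefficients A [hazard_coefficients()] with `h0 > 0`.
#' @param max_followup Censoring horizon in months (may be `Inf`).
#' @param seed Integer seed for the draw; when `NULL` the current RNG
#'   stream is used.
#' @param slope_window `"expanding"` (OLS over all scans up to each interval
#'   start) or `"last2"` (two most recent scans); see
#'   [build_covariate_process()].
#' @return List with `event_time` (months) and `event` (logical).
#' @examples
#' traj <- volume_trajectory(c(-3, 0, 3, 6), c(11, 12, 13, 14))
#' simulate_survival(traj, hazard_coefficients(h0 = 0.1), 24, seed = 1)
#' @export
simulate_survival <- function(trajectory, coefficients, max_followup,
                              seed = NULL, slope_window = "expanding") {
  trajectory <- as_trajectory(trajectory)
  if (!inherits(coefficients, "hazard_coefficients")) {
    stop("coefficients must be a hazard_coefficients object", call. = FALSE)
  }
  if (!is.finite(coefficients$h0) || coefficients$h0 <= 0) {
    stop("h0 must be > 0 to simulate survival", call. = FALSE)
  }
  if (sum(trajectory$time >= 0) < 2L) {
    stop("trajectory needs at least 2 post-baseline observations",
         call. = FALSE)
  }
  if (max_followup < 0) stop("max_followup must be >= 0", call. = FALSE)
  if (max_followup == 0) {
    return(list(event_time = 0, event = FALSE))
  }
  steps <- covariate_steps(trajectory, slope_window = slope_window)
  # piecewise-constant hazard levels on [t_k, t_{k+1}), last carried forward
  lp <- as.matrix(steps[, c("integral", "volume", "slope")]) %*%
    coefficients$beta
  rate <- coefficients$h0 * exp(drop(lp))
  knots <- steps$time
  draw <- function() {
    e <- stats::rexp(1)
    h_acc <- 0
    for (k in seq_along(knots)) {
      width <- if (k < length(knots)) knots[k + 1L] - knots[k] else Inf
      seg <- rate[k] * width
      if (h_acc + seg >= e) {
        t_ev <- knots[k] + (e - h_acc) / rate[k]
        if (t_ev > max_followup) {
          return(list(event_time = max_followup, event = FALSE))
        }
        return(list(event_time = t_ev, event = TRUE))
      }
      h_acc <- h_acc + seg
    }
    list(event_time = max_followup, event = FALSE) # all rates ~0
  }
  if (is.null(seed)) draw() else with_rng_seed(seed, draw())
}

#' Attach simulated survival outcomes to a cohort
#'
#' Draws one survival outcome per subject from the PID hazard, with
#' per-subject substreams derived from `(seed, subject index)` offset so
#' they do not reuse the trajectory streams.
#'
#' @param cohort A `pid_cohort`.
#' @param coefficients A [hazard_coefficients()] with `h0 > 0`.
#' @param max_followup Censoring horizon in months.
#' @param seed Integer seed; defaults to the cohort's simulation seed.
#' @return The cohort with a `survival` data frame added
#'   (`subject_id`, `event_time_months`, `event`).
#' @export
simulate_cohort_survival <- function(cohort, coefficients, max_followup,
                                     seed = cohort$seed) {
  stopifnot(inherits(cohort, "pid_cohort"))
  ids <- cohort_subjects(cohort)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    traj <- subject_trajectory(cohort, ids[i])
    s <- simulate_survival(traj, coefficients, max_followup,
                           seed = substream_seed(seed + 500009, i))
    out[[i]] <- data.frame(subject_id = ids[i],
                           event_time_months = s$event_time,
                           event = as.integer(s$event))
  }
  cohort$survival <- do.call(rbind, out)
  rownames(cohort$survival) <- NULL
  cohort
}
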
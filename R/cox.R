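# Cox proportional-hazards model with the three PID terms as time-varying
# covariates, in counting-process form. The covariates are step functions
# updated at scan times (left-continuous): on [t_k, t_{k+1}) a subject
# carries the running trapezoid integral of volume from treatment start to
# t_k, the volume observed at t_k, and the growth-rate estimate from scans
# up to t_k.

# Covariate step values at each post-baseline scan time.
covariate_steps <- function(trajectory, slope_window = c("expanding",
                                                         "last2")) {
  slope_window <- match.arg(slope_window)
  trajectory <- as_trajectory(trajectory, require_anchor = FALSE)
  post <- trajectory[trajectory$time >= 0, , drop = FALSE]
  if (nrow(post) < 1L) {
    stop("trajectory has no post-baseline (time >= 0) scans", call. = FALSE)
  }
  t <- post$time
  v <- post$volume
  integral <- c(0, cumsum(diff(t) * (v[-1L] + v[-length(v)]) / 2))
  slope <- vapply(seq_along(t), function(k) {
    upto <- trajectory[trajectory$time <= t[k], , drop = FALSE]
    if (slope_window == "last2" && nrow(upto) > 2L) {
      upto <- upto[(nrow(upto) - 1L):nrow(upto), , drop = FALSE]
    }
    if (nrow(upto) < 2L) return(NA_real_)
    ols_slope(upto$time, upto$volume, subject_id_of(trajectory))
  }, numeric(1))
  # a lone leading scan with no history: carry the first defined slope back
  if (anyNA(slope)) {
    first_ok <- which(!is.na(slope))[1L]
    if (is.na(first_ok)) {
      stop("cannot form a growth-rate covariate: fewer than 2 scans",
           call. = FALSE)
    }
    slope[seq_len(first_ok - 1L)] <- slope[first_ok]
  }
  data.frame(time = t, integral = integral, volume = v, slope = slope)
}

#' Counting-process records for one subject
#'
#' Discretizes a subject's trajectory and survival outcome into one record
#' per inter-scan interval up to the event or censoring time. Each record
#' carries the interval `[start, stop)`, the running trapezoid integral of
#' volume from treatment start to the interval start, the most recent
#' observed volume, and the growth-rate estimate from observations up to the
#' interval start (OLS over all history by default, the two most recent
#' scans with `slope_window = "last2"`). Covariates are carried forward past
#' the last scan. The final record is flagged when the event occurred.
#'
#' @param trajectory A [volume_trajectory()].
#' @param survival List or row with `event_time` (months, `> 0`) and `event`
#'   (logical or 0/1).
#' @param slope_window `"expanding"` or `"last2"`.
#' @return Data frame of class `counting_process`: `subject_id`, `start`,
#'   `stop`, `integral`, `volume`, `slope`, `event`.
#' @examples
#' traj <- volume_trajectory(c(0, 3, 6), c(10, 10, 10))
#' build_covariate_process(traj, list(event_time = 7, event = TRUE))
#' @export
build_covariate_process <- function(trajectory, survival,
                                    slope_window = "expanding") {
  trajectory <- as_trajectory(trajectory, require_anchor = FALSE)
  event_time <- survival$event_time
  event <- as.logical(survival$event)
  steps <- covariate_steps(trajectory, slope_window = slope_window)
  if (event_time <= steps$time[1L]) {
    stop("degenerate at-risk process: event/censoring at or before the ",
         "first post-baseline scan (subject ", subject_id_of(trajectory),
         ")", call. = FALSE)
  }
  starts <- steps$time[steps$time < event_time]
  k <- length(starts)
  stops <- c(starts[-1L], event_time)
  out <- data.frame(
    subject_id = subject_id_of(trajectory),
    start = starts,
    stop = stops,
    integral = steps$integral[seq_len(k)],
    volume = steps$volume[seq_len(k)],
    slope = steps$slope[seq_len(k)],
    event = c(rep(FALSE, k - 1L), isTRUE(event))
  )
  class(out) <- c("counting_process", "data.frame")
  out
}

#' Counting-process records for a cohort
#'
#' @param cohort A `pid_cohort` with a `survival` component (see
#'   [simulate_cohort_survival()]), or a cohort scan data frame plus an
#'   explicit `survival` data frame (`subject_id`, `event_time_months`,
#'   `event`).
#' @param survival Optional survival data frame overriding
#'   `cohort$survival`.
#' @param slope_window Passed to [build_covariate_process()].
#' @return A `counting_process` data frame stacking all subjects.
#' @export
cohort_covariate_process <- function(cohort, survival = NULL,
                                     slope_window = "expanding") {
  if (is.null(survival) && inherits(cohort, "pid_cohort")) {
    survival <- cohort$survival
  }
  if (is.null(survival)) {
    stop("no survival outcomes supplied", call. = FALSE)
  }
  ids <- cohort_subjects(cohort)
  rows <- lapply(ids, function(id) {
    s <- survival[survival$subject_id == id, , drop = FALSE]
    if (!nrow(s)) stop("no survival record for subject ", id, call. = FALSE)
    build_covariate_process(
      subject_trajectory(cohort, id),
      list(event_time = s$event_time_months[1L], event = s$event[1L]),
      slope_window = slope_window
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("counting_process", "data.frame")
  out
}

cox_design <- function(records) {
  if (!all(c("start", "stop", "integral", "volume", "slope", "event") %in%
           names(records))) {
    stop("records must have columns start, stop, integral, volume, slope, ",
         "event", call. = FALSE)
  }
  x <- as.matrix(records[, c("integral", "volume", "slope")])
  if (any(!is.finite(x))) stop("non-finite covariates", call. = FALSE)
  ev <- which(as.logical(records$event))
  if (!length(ev)) stop("no events in the data", call. = FALSE)
  list(x = x, start = records$start, stop = records$stop, ev = ev,
       ev_time = records$stop[ev])
}

# risk-set membership matrix: rows = events, cols = records
cox_risk_sets <- function(d) {
  outer(d$ev_time, d$start, ">") & outer(d$ev_time, d$stop, "<=")
}

#' Cox partial log-likelihood of the PID hazard
#'
#' Evaluates the counting-process partial log-likelihood at a coefficient
#' triple. A subject contributes to the risk set of an event time while any
#' of its intervals covers it (interval `start < t <= stop`), with that
#' interval's covariates; tied event times are handled with the Breslow
#' approximation.
#'
#' @param records A `counting_process` data frame (all subjects stacked),
#'   see [build_covariate_process()].
#' @param betas Numeric triple `(beta1, beta2, beta3)` for the integral,
#'   volume and slope covariates.
#' @return The partial log-likelihood (scalar).
#' @export
partial_log_likelihood <- function(records, betas) {
  stopifnot(length(betas) == 3L)
  d <- cox_design(records)
  lp <- drop(d$x %*% betas)
  risk <- cox_risk_sets(d)
  if (any(rowSums(risk) == 0L)) {
    stop("empty risk set at an event time", call. = FALSE)
  }
  elp <- exp(lp)
  sum(lp[d$ev]) - sum(log(risk %*% elp))
}

#' Gradient of the Cox partial log-likelihood
#'
#' Analytic score vector of [partial_log_likelihood()] with respect to the
#' three coefficients.
#'
#' @inheritParams partial_log_likelihood
#' @return Numeric triple.
#' @export
partial_log_likelihood_gradient <- function(records, betas) {
  d <- cox_design(records)
  cox_ll_parts(d, betas)$grad
}

# log-likelihood, gradient and Hessian in one pass
cox_ll_parts <- function(d, betas) {
  lp <- drop(d$x %*% betas)
  elp <- exp(lp)
  risk <- cox_risk_sets(d)
  denom <- drop(risk %*% elp)
  if (any(denom <= 0) || any(rowSums(risk) == 0L)) {
    stop("empty risk set at an event time", call. = FALSE)
  }
  w <- risk * rep(elp, each = nrow(risk)) / denom # event x record weights
  xbar <- w %*% d$x                               # weighted covariate means
  ll <- sum(lp[d$ev]) - sum(log(denom))
  grad <- colSums(d$x[d$ev, , drop = FALSE]) - colSums(xbar)
  w_total <- colSums(w) # per-record weight summed over event times
  hess <- -(crossprod(d$x * sqrt(w_total)) - crossprod(xbar))
  list(ll = ll, grad = grad, hess = hess)
}

#' Fit the PID Cox model
#'
#' Maximizes the counting-process partial log-likelihood by Newton-Raphson
#' with step halving, on internally standardized covariates (z-scores over
#' records) for conditioning; coefficients and standard errors are reported
#' back on natural units. Covariates with (near-)zero variance are fixed at
#' coefficient 0 and excluded from the optimization. Convergence requires
#' gradient norm below `tol` (standardized scale) within `max_iter`
#' iterations.
#'
#' @param cohort A `pid_cohort` with survival, a `counting_process` data
#'   frame, or a cohort plus `survival` data frame (see
#'   [cohort_covariate_process()]).
#' @param survival Optional survival data frame when `cohort` is not a
#'   `counting_process`.
#' @param slope_window Passed to [build_covariate_process()].
#' @param tol Gradient-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return A `pid_cox_fit`: [hazard_coefficients()] plus `loglik`,
#'   `loglik_null`, `iterations`, `n_events`, `n_records`, `gradient_norm`,
#'   `vcov` (natural units), `converged`.
#' @export
fit_cox_pid <- function(cohort, survival = NULL, slope_window = "expanding",
                        tol = 1e-8, max_iter = 100L) {
  records <- if (inherits(cohort, "counting_process")) cohort else
    cohort_covariate_process(cohort, survival, slope_window = slope_window)
  d <- cox_design(records)
  n_events <- length(d$ev)
  if (n_events < 10L) {
    warning("only ", n_events,
            " event(s); PID coefficient estimates will be unstable",
            call. = FALSE)
  }
  ctr <- colMeans(d$x)
  scl <- apply(d$x, 2, stats::sd)
  active <- which(scl > 1e-12)
  if (!length(active)) stop("all covariates are constant", call. = FALSE)
  dz <- d
  dz$x <- sweep(sweep(d$x, 2, ctr), 2, pmax(scl, 1e-12), "/")
  dz$x[, setdiff(1:3, active)] <- 0

  beta <- rep(0, 3)
  parts <- cox_ll_parts(dz, beta)
  iter <- 0L
  repeat {
    gnorm <- sqrt(sum(parts$grad[active]^2))
    if (gnorm < tol || iter >= max_iter) break
    iter <- iter + 1L
    h <- parts$hess[active, active, drop = FALSE]
    step <- rep(0, 3)
    step[active] <- tryCatch(solve(-h, parts$grad[active]),
                             error = function(e) {
                               stop("singular information matrix during ",
                                    "Newton iteration", call. = FALSE)
                             })
    new_beta <- beta + step
    new_parts <- cox_ll_parts(dz, new_beta)
    halvings <- 0L
    while (!is.finite(new_parts$ll) || new_parts$ll < parts$ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      new_beta <- beta + (new_beta - beta) / 2
      new_parts <- cox_ll_parts(dz, new_beta)
    }
    beta <- new_beta
    parts <- new_parts
    if (any(abs(beta[active]) > 50)) {
      stop("monotone likelihood: coefficients diverging (complete ",
           "separation?)", call. = FALSE)
    }
  }
  converged <- sqrt(sum(parts$grad[active]^2)) < tol
  if (!converged) {
    stop(sprintf(paste0("Cox fit did not converge in %d iterations ",
                        "(|gradient| = %.3g; last standardized beta: %s)"),
                 max_iter, sqrt(sum(parts$grad[active]^2)),
                 paste(signif(beta, 4), collapse = ", ")),
         call. = FALSE)
  }
  vcov_z <- matrix(NA_real_, 3, 3)
  vcov_z[active, active] <- solve(-parts$hess[active, active, drop = FALSE])
  scale_mat <- tcrossprod(1 / pmax(scl, 1e-12))
  vcov_nat <- vcov_z * scale_mat
  beta_nat <- unname(beta / pmax(scl, 1e-12))
  beta_nat[setdiff(1:3, active)] <- 0
  se_nat <- unname(sqrt(diag(vcov_nat)))
  out <- hazard_coefficients(
    h0 = NA_real_,
    beta1 = beta_nat[1L], beta2 = beta_nat[2L], beta3 = beta_nat[3L],
    standard_errors = se_nat
  )
  out$loglik <- parts$ll
  out$loglik_null <- partial_log_likelihood(records, c(0, 0, 0))
  out$iterations <- iter
  out$n_events <- n_events
  out$n_records <- nrow(records)
  out$gradient_norm <- sqrt(sum(parts$grad[active]^2))
  out$vcov <- vcov_nat
  out$converged <- converged
  class(out) <- c("pid_cox_fit", class(out))
  out
}

#' @export
print.pid_cox_fit <- function(x, ...) {
  cat("Cox PID hazard fit (counting process, Breslow ties)\n")
  cat(sprintf("  records: %d, events: %d, Newton iterations: %d\n",
              x$n_records, x$n_events, x$iterations))
  cat(sprintf("  partial log-likelihood: %.4f (null %.4f)\n",
              x$loglik, x$loglik_null))
  lab <- c("beta1 integral per mL.month ",
           "beta2 burden   per mL       ",
           "beta3 slope    per mL/month ")
  for (i in 1:3) {
    z <- x$beta[i] / x$standard_errors[i]
    cat(sprintf("  %s % .5g  (SE %.4g, z = %.2f)\n",
                lab[i], x$beta[i], x$standard_errors[i], z))
  }
  invisible(x)
}
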
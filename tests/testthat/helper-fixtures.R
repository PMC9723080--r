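# Shared fixtures: small deterministic trajectories and a 3-subject toy
# counting-process dataset (fixed covariates, one interval per subject).

linear_traj <- function(times = seq(-6, 6, 3), slope_pre = 1 / 3,
                        slope_post = 1 / 3, v0 = 12, subject_id = "S1") {
  v <- ifelse(times <= 0, v0 + slope_pre * times, v0 + slope_post * times)
  volume_trajectory(times, v, subject_id = subject_id)
}

toy_cox_records <- function() {
  out <- rbind(
    data.frame(subject_id = "a", start = 0, stop = 1,
               integral = 1.0, volume = 5, slope = 0.10, event = TRUE),
    data.frame(subject_id = "b", start = 0, stop = 2,
               integral = 2.5, volume = 6, slope = -0.20, event = TRUE),
    data.frame(subject_id = "c", start = 0, stop = 3,
               integral = 3.0, volume = 7, slope = 0.30, event = FALSE)
  )
  class(out) <- c("counting_process", "data.frame")
  out
}

# Independent oracle: direct enumeration of the Cox partial-likelihood
# product for single-interval-per-subject records, written with plain
# loops over hand-readable risk sets.
toy_cox_loglik_bruteforce <- function(records, betas) {
  eta <- betas[1] * records$integral + betas[2] * records$volume +
    betas[3] * records$slope
  ll <- 0
  for (i in which(records$event)) {
    at_risk <- records$stop >= records$stop[i]
    ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
  }
  ll
}
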
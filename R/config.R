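#' Generative parameters for a simulated tumor-volume trial
#'
#' Bundles the parameters of the trajectory simulator: a slow-growing glioma
#' cohort observed for a fixed pre-treatment window and a post-treatment
#' window, scanned on a nominal quarterly grid with normally distributed
#' scan-date jitter, with normally distributed volumetric measurement noise.
#' Defaults describe a cohort of 10 mL tumors (SD 0.5 mL) six months before
#' treatment, growing 1 mL every 3 months, measured with 0.25 mL noise
#' (roughly 250 voxels), scanned every 3 months with 2-week-SD date jitter,
#' randomized 1:1 (40 per arm) between an ineffective therapy (growth
#' unchanged) and a cytostatic therapy (growth stabilized at 0).
#'
#' @param arms Named integer vector of subjects per arm. Arm names must be
#'   a subset of `c("control", "treated")` or supply matching
#'   `post_growth_rates`.
#' @param baseline_mean,baseline_sd Mean and SD (mL) of the true tumor volume
#'   at the earliest nominal scan time (`-window_pre` months).
#' @param growth_rate True pre-treatment growth rate, mL/month. The default
#'   is exactly 1/3 (1 mL every 3 months).
#' @param post_growth_rate_control,post_growth_rate_treated Post-treatment
#'   growth rates (mL/month) for the two default arms.
#' @param noise_sd SD of volumetric measurement noise, mL.
#' @param scan_interval Nominal months between scans.
#' @param scan_jitter_sd SD of scan-date jitter, months (default 0.5, i.e.
#'   about 2 weeks). The treatment-start anchor scan at time 0 is never
#'   jittered.
#' @param window_pre,window_post Length in months of the pre- and
#'   post-treatment observation windows.
#' @param seed Optional default seed used by [simulate_cohort()] when no
#'   seed is passed explicitly.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_trajectory()]
#' @examples
#' cfg <- simulation_config()
#' cfg
#' @export
simulation_config <- function(arms = c(control = 40L, treated = 40L),
                              baseline_mean = 10,
                              baseline_sd = 0.5,
                              growth_rate = 1 / 3,
                              post_growth_rate_control = 1 / 3,
                              post_growth_rate_treated = 0,
                              noise_sd = 0.25,
                              scan_interval = 3,
                              scan_jitter_sd = 0.5,
                              window_pre = 6,
                              window_post = 6,
                              seed = NULL) {
  cfg <- list(
    arms = arms,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    growth_rate = growth_rate,
    post_growth_rates = c(
      control = post_growth_rate_control,
      treated = post_growth_rate_treated
    ),
    noise_sd = noise_sd,
    scan_interval = scan_interval,
    scan_jitter_sd = scan_jitter_sd,
    window_pre = window_pre,
    window_post = window_post,
    seed = seed
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid simulation config: field '", field, "' ", why, call. = FALSE)
  }
  scalar_num <- function(field, x) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      bad(field, "must be a single finite number")
    }
  }
  if (is.null(names(cfg$arms)) || any(!nzchar(names(cfg$arms)))) {
    bad("arms", "must be a named vector of per-arm subject counts")
  }
  if (any(cfg$arms < 0) || any(cfg$arms != round(cfg$arms))) {
    bad("arms", "counts must be non-negative integers")
  }
  if (sum(cfg$arms) < 1) bad("arms", "must contain at least one subject")
  for (f in c("baseline_mean", "baseline_sd", "growth_rate", "noise_sd",
              "scan_interval", "scan_jitter_sd", "window_pre", "window_post")) {
    scalar_num(f, cfg[[f]])
  }
  for (f in c("baseline_sd", "noise_sd", "scan_jitter_sd")) {
    if (cfg[[f]] < 0) bad(f, "must be >= 0 (a standard deviation)")
  }
  if (cfg$scan_interval <= 0) bad("scan_interval", "must be > 0")
  if (cfg$window_pre < 0 || cfg$window_post < 0) {
    bad("window_pre/window_post", "must be >= 0")
  }
  missing_rates <- setdiff(names(cfg$arms), names(cfg$post_growth_rates))
  if (length(missing_rates)) {
    bad("arms", paste0(
      "has arm(s) without a post-treatment growth rate: ",
      paste(missing_rates, collapse = ", ")
    ))
  }
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
      bad("seed", "must be a single integer or NULL")
    }
  }
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Tumor-volume trial simulation config\n")
  cat("  arms:              ",
      paste(sprintf("%s=%d", names(x$arms), x$arms), collapse = ", "), "\n")
  cat(sprintf("  baseline:           %.3g mL (SD %.3g) at t = -%g months\n",
              x$baseline_mean, x$baseline_sd, x$window_pre))
  cat(sprintf("  growth rate:        %.4g mL/month pre-treatment\n",
              x$growth_rate))
  cat("  post-tx rates:     ",
      paste(sprintf("%s=%.4g", names(x$post_growth_rates),
                    x$post_growth_rates), collapse = ", "), "mL/month\n")
  cat(sprintf("  measurement noise:  %.3g mL;  scan every %g mo (jitter SD %g mo)\n",
              x$noise_sd, x$scan_interval, x$scan_jitter_sd))
  cat(sprintf("  windows:            %g mo pre, %g mo post\n",
              x$window_pre, x$window_post))
  invisible(x)
}

#' Nominal scan grid of a simulation config
#'
#' The nominal (unjittered) scan times implied by the windows and scan
#' interval, always including the treatment-start anchor at time 0.
#'
#' @param config A [simulation_config()].
#' @return Numeric vector of nominal scan times in months, increasing.
#' @export
nominal_scan_times <- function(config) {
  pre <- rev(seq(0, config$window_pre, by = config$scan_interval))
  post <- seq(0, config$window_post, by = config$scan_interval)
  sort(unique(c(-pre, post)))
}
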
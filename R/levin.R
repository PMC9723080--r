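# Modified Levin scoring engine: 7-level qualitative change scores per scan
# pair (-3 new lesion / emerging enhancement .. +3 complete disappearance),
# compartment combination for mixed enhancing/non-enhancing tumors, 4-week
# confirmation logic, PFS derivation, digitization of scores into a
# pseudo-volume signal, and a threshold-based synthetic rater.

levin_levels <- -3:3

check_levin_score <- function(score, allow_na = TRUE) {
  ok <- (allow_na & is.na(score)) | score %in% levin_levels
  if (!all(ok)) {
    stop("invalid modified Levin score(s): ",
         paste(unique(score[!ok]), collapse = ", "),
         " (must be integers in -3..+3)", call. = FALSE)
  }
  invisible(score)
}

#' Ordered modified-Levin score series for one subject
#'
#' @param time_weeks Strictly increasing assessment times, weeks from
#'   treatment start.
#' @param enhancing,nonenhancing Integer scores in `-3..+3` (NA = compartment
#'   not assessed); at least one compartment must be scored at every entry.
#'   Supplying only `enhancing` describes a single-compartment tumor.
#' @param subject_id Identifier.
#' @return Data frame of class `levin_series`.
#' @examples
#' levin_series(c(0, 8, 16), enhancing = c(0, -2, -2))
#' @export
levin_series <- function(time_weeks, enhancing = NULL, nonenhancing = NULL,
                         subject_id = "S1") {
  n <- length(time_weeks)
  if (n < 1L) stop("empty score series", call. = FALSE)
  if (is.unsorted(time_weeks, strictly = TRUE)) {
    stop("assessment times must be strictly increasing (subject ",
         subject_id, ")", call. = FALSE)
  }
  if (is.null(enhancing)) enhancing <- rep(NA_integer_, n)
  if (is.null(nonenhancing)) nonenhancing <- rep(NA_integer_, n)
  if (length(enhancing) != n || length(nonenhancing) != n) {
    stop("score vectors must match the number of assessment times",
         call. = FALSE)
  }
  check_levin_score(enhancing)
  check_levin_score(nonenhancing)
  if (any(is.na(enhancing) & is.na(nonenhancing))) {
    stop("every entry needs at least one scored compartment (subject ",
         subject_id, ")", call. = FALSE)
  }
  out <- data.frame(time_weeks = as.numeric(time_weeks),
                    enhancing = as.integer(enhancing),
                    nonenhancing = as.integer(nonenhancing))
  attr(out, "subject_id") <- subject_id
  class(out) <- c("levin_series", "data.frame")
  out
}

#' Response category of a single modified Levin score
#'
#' `0` and `+/-1` (possibly better/worse) map to stable disease; `-2`
#' (definitely worse) and `-3` (new lesion or emerging enhancement) to
#' progressive disease; `+2` (definitely better) to partial response; `+3`
#' (complete disappearance) to complete response.
#'
#' @param score Integer score(s) in `-3..+3`.
#' @return Character vector in `c("CR", "PR", "SD", "PD")`.
#' @export
score_to_category <- function(score) {
  check_levin_score(score, allow_na = FALSE)
  ifelse(score <= -2, "PD",
         ifelse(score == 3, "CR",
                ifelse(score == 2, "PR", "SD")))
}

#' Combine enhancing and non-enhancing compartment scores
#'
#' Progression is declared when *either* assessed compartment definitely
#' progressed (score `<= -2`); response requires a definite response from
#' *every* assessed compartment (`>= +2` for PR, `>= +3` for CR); anything
#' else is stable disease. A missing compartment defers to the present one.
#'
#' @param enhancing,nonenhancing Scores in `-3..+3`, possibly NA (not both).
#' @return Category in `c("CR", "PR", "SD", "PD")` (vectorized).
#' @examples
#' combine_compartments(-2, 0)  # "PD"
#' combine_compartments(2, 1)   # "SD": both must respond definitely
#' @export
combine_compartments <- function(enhancing = NA, nonenhancing = NA) {
  n <- max(length(enhancing), length(nonenhancing))
  enhancing <- rep_len(enhancing, n)
  nonenhancing <- rep_len(nonenhancing, n)
  check_levin_score(enhancing)
  check_levin_score(nonenhancing)
  if (any(is.na(enhancing) & is.na(nonenhancing))) {
    stop("at least one compartment score must be present", call. = FALSE)
  }
  # the minimum over assessed compartments drives both rules: PD if any
  # compartment <= -2, PR/CR only if all compartments reach the level
  worst <- pmin(enhancing, nonenhancing, na.rm = TRUE)
  ifelse(worst <= -2, "PD",
         ifelse(worst >= 3, "CR",
                ifelse(worst >= 2, "PR", "SD")))
}

#' Response assessment and PFS from a score series
#'
#' Walks the assessments chronologically, combining compartments at each
#' entry. A PD-level assessment is confirmed by any later assessment at
#' least `confirmation_window` weeks after it whose worst compartment score
#' is still `<= -1` (not improved above the progression-leaning range); a
#' PR (CR) is confirmed by a later PR-or-better (CR) assessment at least 4
#' weeks after onset. Progression-free survival is dated at the first
#' assessment of the confirmed progression pair; subjects with no confirmed
#' progression are censored at their last assessment.
#'
#' @param series A [levin_series()].
#' @param confirmation_window Weeks required between a PD call and its
#'   confirming scan (default 4; responses always use 4 weeks).
#' @param confirm_new_lesion Should a score of `-3` (new lesion) also
#'   require confirmation? Default `TRUE`, by symmetry with `-2`.
#' @return An object of class `response_assessment`: `category` (first
#'   confirmed event, else `"SD"`, else `"not-evaluable"`), `onset_time`,
#'   `confirmed`, `pfs_time` (weeks), `pfs_event` (logical).
#' @examples
#' s <- levin_series(c(0, 8, 16), enhancing = c(0, -2, -2))
#' assess_series(s) # confirmed PD, PFS 8 weeks
#' @export
assess_series <- function(series, confirmation_window = 4,
                          confirm_new_lesion = TRUE) {
  if (is.null(series) || !nrow(series)) {
    return(structure(list(category = "not-evaluable", onset_time = NA_real_,
                          confirmed = FALSE, pfs_time = NA_real_,
                          pfs_event = FALSE),
                     class = "response_assessment"))
  }
  stopifnot(inherits(series, "levin_series"))
  t <- series$time_weeks
  cat_i <- combine_compartments(series$enhancing, series$nonenhancing)
  worst <- pmin(series$enhancing, series$nonenhancing, na.rm = TRUE)
  n <- length(t)

  pd_confirmed <- function(i) {
    if (!confirm_new_lesion && !is.na(worst[i]) && worst[i] <= -3) {
      return(TRUE)
    }
    later <- which(t >= t[i] + confirmation_window)
    later <- later[later > i]
    any(worst[later] <= -1)
  }
  resp_confirmed <- function(i, need) {
    later <- which(t >= t[i] + 4)
    later <- later[later > i]
    any(cat_i[later] %in% need)
  }

  first_event <- NULL
  for (i in seq_len(n)) {
    ok <- switch(cat_i[i],
                 PD = pd_confirmed(i),
                 PR = resp_confirmed(i, c("PR", "CR")),
                 CR = resp_confirmed(i, "CR"),
                 FALSE)
    if (ok) {
      first_event <- list(category = cat_i[i], onset = t[i])
      break
    }
  }
  pd_idx <- which(cat_i == "PD")
  pd_idx <- pd_idx[vapply(pd_idx, pd_confirmed, logical(1))]
  if (length(pd_idx)) {
    pfs_time <- t[pd_idx[1L]]
    pfs_event <- TRUE
  } else {
    pfs_time <- t[n]
    pfs_event <- FALSE
  }
  structure(list(
    category = if (is.null(first_event)) "SD" else first_event$category,
    onset_time = if (is.null(first_event)) NA_real_ else first_event$onset,
    confirmed = !is.null(first_event),
    pfs_time = pfs_time,
    pfs_event = pfs_event
  ), class = "response_assessment")
}

#' @export
print.response_assessment <- function(x, ...) {
  cat("Response assessment:", x$category)
  if (x$confirmed) cat(sprintf(" (confirmed, onset week %g)", x$onset_time))
  cat("\n")
  cat(sprintf("  PFS: %g weeks (%s)\n", x$pfs_time,
              if (x$pfs_event) "progression" else "censored"))
  invisible(x)
}

#' Digitize a score series into a pseudo-volume signal
#'
#' Accumulates scores into a tumor-behavior estimate usable by the PID
#' estimators when volumes are not measurable: each assessment decrements
#' the running signal by its total score, so worsening (negative scores)
#' increases the pseudo-volume. With scores `s_1..s_k`,
#' `V~(t_1) = -s_1` and `V~(t_k) = V~(t_{k-1}) - s_k`. When both
#' compartments are scored their scores are summed.
#'
#' @param series A [levin_series()].
#' @return Data frame with columns `time` (weeks) and `volume`
#'   (score-units), suitable for [growth_rate()] and
#'   [integrate_volume_curve()].
#' @examples
#' s <- levin_series(c(4, 8, 12), enhancing = c(-1, -1, -2))
#' levin_pseudovolume(s)$volume # 1 2 4
#' @export
levin_pseudovolume <- function(series) {
  stopifnot(inherits(series, "levin_series"))
  total <- rowSums(cbind(series$enhancing, series$nonenhancing),
                   na.rm = TRUE)
  data.frame(time = series$time_weeks, volume = cumsum(-total))
}

#' Synthetic rater model
#'
#' Maps percent volume change between sequential scans to a modified Levin
#' score by threshold lookup, optionally with discrete rater noise. Default
#' cutpoints: change `>= pd` percent scores -2, `>= worse` scores -1,
#' `> stable` scores 0, `> better` scores +1, else +2. The defaults blend
#' the ROC-derived cutoffs for progression (+15%) and response (-20%) with
#' the observed score medians (+72% for -2, -41% for +1) from retrospective
#' reader data. Scores of -3/+3 are assigned only via explicit
#' new-lesion/disappearance flags, never by threshold.
#'
#' @param pd,worse,stable,better Percent-change cutpoints, strictly
#'   decreasing.
#' @param rater_noise_sd Score-units SD of the rater's discrete noise: the
#'   assigned score is perturbed by +/-1 with total probability
#'   `rater_noise_sd^2` (the variance of a unit perturbation), clipped to
#'   `[-2, +2]`.
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(pd = 50, worse = 15, stable = -20, better = -40,
                        rater_noise_sd = 0) {
  cuts <- c(pd = pd, worse = worse, stable = stable, better = better)
  if (any(diff(cuts) >= 0)) {
    stop("rater cutpoints must be strictly decreasing: pd > worse > ",
         "stable > better", call. = FALSE)
  }
  if (rater_noise_sd < 0 || rater_noise_sd > 1) {
    stop("rater_noise_sd must be in [0, 1] (score units)", call. = FALSE)
  }
  structure(list(cuts = cuts, rater_noise_sd = rater_noise_sd),
            class = "rater_model")
}

#' Simulate a qualitative rater
#'
#' @param percent_change Percent volume change(s) between sequential scans
#'   (e.g. `+50` for a 50% increase).
#' @param model A [rater_model()].
#' @param seed Optional seed for the rater-noise draws.
#' @param new_lesion,disappearance Logical flag(s): force scores of -3
#'   (new lesion / emerging enhancement) or +3 (complete disappearance).
#' @return Integer score(s) in `-3..+3`.
#' @examples
#' simulate_rater(c(80, 0, -45), rater_model()) # -2 0 2
#' @export
simulate_rater <- function(percent_change, model = rater_model(),
                           seed = NULL, new_lesion = FALSE,
                           disappearance = FALSE) {
  stopifnot(inherits(model, "rater_model"))
  n <- length(percent_change)
  new_lesion <- rep_len(new_lesion, n)
  disappearance <- rep_len(disappearance, n)
  cuts <- model$cuts
  score <- ifelse(percent_change >= cuts["pd"], -2L,
                  ifelse(percent_change >= cuts["worse"], -1L,
                         ifelse(percent_change > cuts["stable"], 0L,
                                ifelse(percent_change > cuts["better"],
                                       1L, 2L))))
  p_flip <- min(1, model$rater_noise_sd^2)
  if (p_flip > 0) {
    flip <- function() {
      u <- stats::runif(n)
      delta <- ifelse(u < p_flip / 2, -1L, ifelse(u < p_flip, 1L, 0L))
      pmax(pmin(score + delta, 2L), -2L)
    }
    score <- if (is.null(seed)) flip() else with_rng_seed(seed, flip())
  }
  score[new_lesion] <- -3L
  score[disappearance] <- 3L
  as.integer(score)
}

#' Rate a volume trajectory with the synthetic rater
#'
#' Converts a measured trajectory into a modified-Levin score series by
#' scoring the percent volume change between each pair of sequential scans
#' (single compartment). Times are converted from months to weeks with
#' 1 month = 13/3 weeks.
#'
#' @param trajectory A [volume_trajectory()].
#' @param model A [rater_model()].
#' @param seed Optional seed for rater noise.
#' @param weeks_per_month Time conversion factor.
#' @return A [levin_series()] with one entry per scan after the first.
#' @export
rate_trajectory <- function(trajectory, model = rater_model(), seed = NULL,
                            weeks_per_month = 13 / 3) {
  trajectory <- as_trajectory(trajectory, require_anchor = FALSE)
  if (nrow(trajectory) < 2L) {
    stop("need at least 2 scans to rate sequential change", call. = FALSE)
  }
  v <- trajectory$volume
  pct <- 100 * diff(v) / ifelse(v[-length(v)] > 0, v[-length(v)], NA_real_)
  if (anyNA(pct)) {
    stop("cannot compute percent change from a zero-volume scan",
         call. = FALSE)
  }
  levin_series(
    time_weeks = trajectory$time[-1L] * weeks_per_month,
    enhancing = simulate_rater(pct, model, seed = seed),
    subject_id = subject_id_of(trajectory)
  )
}
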
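#' Longitudinal volume trajectory for one subject
#'
#' A `volume_trajectory` is a data frame with columns `time` (months relative
#' to treatment start) and `volume` (mL), strictly increasing in time, with a
#' `subject_id` attribute. By convention a trajectory carries exactly one
#' anchor observation at time 0 (the treatment-start scan); set
#' `require_anchor = FALSE` for derived signals (e.g. score pseudo-volumes)
#' that have no anchor.
#'
#' @param time Numeric vector of observation times (months).
#' @param volume Numeric vector of volumes (mL), same length, all `>= 0`
#'   unless `require_nonnegative = FALSE`.
#' @param subject_id Opaque subject identifier.
#' @param require_anchor Require exactly one observation at time 0.
#' @param require_nonnegative Require all volumes `>= 0`.
#' @return A data frame of class `volume_trajectory`.
#' @examples
#' volume_trajectory(c(-6, -3, 0, 3, 6), c(10, 11, 12, 13, 14))
#' @export
volume_trajectory <- function(time, volume, subject_id = "S1",
                              require_anchor = TRUE,
                              require_nonnegative = TRUE) {
  if (length(time) != length(volume)) {
    stop("time and volume must have the same length", call. = FALSE)
  }
  if (length(time) < 1L) {
    stop("a trajectory needs at least one observation", call. = FALSE)
  }
  if (anyNA(time) || anyNA(volume)) {
    stop("trajectory times and volumes must not contain NA", call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("trajectory times must be strictly increasing (subject ",
         subject_id, ")", call. = FALSE)
  }
  if (require_nonnegative && any(volume < 0)) {
    stop("volumes must be non-negative (subject ", subject_id, ")",
         call. = FALSE)
  }
  if (require_anchor && sum(time == 0) != 1L) {
    stop("trajectory must contain exactly one anchor observation at time 0 ",
         "(subject ", subject_id, ")", call. = FALSE)
  }
  out <- data.frame(time = as.numeric(time), volume = as.numeric(volume))
  attr(out, "subject_id") <- subject_id
  class(out) <- c("volume_trajectory", "data.frame")
  out
}

#' Coerce a (time, volume) data frame to a volume_trajectory
#'
#' @param x A `volume_trajectory`, or any data frame with `time` and
#'   `volume` columns.
#' @param ... Passed to [volume_trajectory()].
#' @return A `volume_trajectory`.
#' @export
as_trajectory <- function(x, ...) {
  if (inherits(x, "volume_trajectory")) return(x)
  if (!is.data.frame(x) || !all(c("time", "volume") %in% names(x))) {
    stop("cannot coerce to volume_trajectory: need columns 'time', 'volume'",
         call. = FALSE)
  }
  sid <- attr(x, "subject_id")
  volume_trajectory(x$time, x$volume,
                    subject_id = if (is.null(sid)) "S1" else sid, ...)
}

#' @export
print.volume_trajectory <- function(x, ...) {
  cat("Volume trajectory for subject ", attr(x, "subject_id"),
      " (", nrow(x), " scans)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

subject_id_of <- function(trajectory) {
  sid <- attr(trajectory, "subject_id")
  if (is.null(sid)) "?" else sid
}
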
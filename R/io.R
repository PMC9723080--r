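# CSV/YAML/JSON plumbing. Numeric CSV columns are written with %.17g so a
# write/read round trip reproduces doubles bit-for-bit and rewriting is
# byte-identical.

fmt_num <- function(x) {
  out <- vapply(x, function(v) formatC(v, format = "g", digits = 17),
                character(1))
  sub("^\\s+", "", out)
}

write_precise_csv <- function(df, path, numeric_cols) {
  out <- df
  for (nm in numeric_cols) out[[nm]] <- fmt_num(df[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read / write a cohort scan table
#'
#' The cohort CSV has one row per scan with columns `subject_id`, `arm`,
#' `time_months`, `volume_ml`. Times must be strictly increasing within
#' subject. Volumes survive a write/read round trip at full double
#' precision.
#'
#' @param path CSV path.
#' @return `read_cohort`: a `pid_cohort` (without config/seed);
#'   `write_cohort`: the path, invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("subject_id", "arm", "time_months", "volume_ml"),
                  path)
  for (id in unique(df$subject_id)) {
    t <- df$time_months[df$subject_id == id]
    if (is.unsorted(t, strictly = TRUE)) {
      stop("scan times not strictly increasing for subject '", id,
           "' in '", path, "'", call. = FALSE)
    }
  }
  out <- list(
    scans = df[, c("subject_id", "arm", "time_months", "volume_ml")],
    arms = df$arm[!duplicated(df$subject_id)],
    config = NULL,
    seed = NULL,
    n_floored = NA_integer_
  )
  class(out) <- "pid_cohort"
  out
}

#' @rdname read_cohort
#' @param cohort A `pid_cohort` or cohort scan data frame.
#' @export
write_cohort <- function(cohort, path) {
  scans <- if (inherits(cohort, "pid_cohort")) cohort$scans else cohort
  require_columns(scans, c("subject_id", "arm", "time_months", "volume_ml"),
                  "<cohort>")
  write_precise_csv(scans[, c("subject_id", "arm", "time_months",
                              "volume_ml")],
                    path, c("time_months", "volume_ml"))
}

#' Read / write survival outcomes
#'
#' Columns: `subject_id`, `event_time_months`, `event` (0/1).
#' @param path CSV path.
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("subject_id", "event_time_months", "event"), path)
  df
}

#' @rdname read_survival
#' @param survival Survival data frame.
#' @export
write_survival <- function(survival, path) {
  require_columns(survival, c("subject_id", "event_time_months", "event"),
                  "<survival>")
  write_precise_csv(survival, path, "event_time_months")
}

#' Read / write modified-Levin score tables
#'
#' Columns: `subject_id`, `time_weeks`, `enhancing_score`,
#' `nonenhancing_score` (empty = not assessed), plus optional
#' `new_lesion_flag` and `disappearance_flag`.
#'
#' @param path CSV path.
#' @return `read_levin_scores`: a named list of [levin_series()].
#' @export
read_levin_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("subject_id", "time_weeks"), path)
  if (!any(c("enhancing_score", "nonenhancing_score") %in% names(df))) {
    stop("file '", path, "' needs an enhancing_score and/or ",
         "nonenhancing_score column", call. = FALSE)
  }
  ids <- unique(df$subject_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$subject_id == id, , drop = FALSE]
    levin_series(
      rows$time_weeks,
      enhancing = if ("enhancing_score" %in% names(rows))
        rows$enhancing_score else NULL,
      nonenhancing = if ("nonenhancing_score" %in% names(rows))
        rows$nonenhancing_score else NULL,
      subject_id = id
    )
  })
  names(out) <- ids
  out
}

#' @rdname read_levin_scores
#' @param series_list Named list of [levin_series()].
#' @export
write_levin_scores <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(subject_id = attr(s, "subject_id"),
               time_weeks = s$time_weeks,
               enhancing_score = s$enhancing,
               nonenhancing_score = s$nonenhancing)
  }))
  write_precise_csv(rows, path, "time_weeks")
}

#' Read a simulation config from YAML
#'
#' The YAML mirrors the [simulation_config()] arguments; `arms` is a
#' mapping of arm name to subject count.
#'
#' @param path YAML path.
#' @return A `simulation_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$arms)) {
    args$arms <- stats::setNames(as.integer(unlist(y$arms)), names(y$arms))
  }
  for (nm in c("baseline_mean", "baseline_sd", "growth_rate",
               "post_growth_rate_control", "post_growth_rate_treated",
               "noise_sd", "scan_interval", "scan_jitter_sd",
               "window_pre", "window_post", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(simulation_config, args)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version, per-stage
#' output paths and wall-clock timestamps of a pipeline run as JSON. Every
#' listed output must exist on disk.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run.
#' @param config Optional `simulation_config`.
#' @param outputs Named character vector/list of stage output paths.
#' @param started POSIXct start time (finish time is taken at call time).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = NULL, outputs = list(),
                               started = Sys.time()) {
  outputs <- as.list(outputs)
  missing <- !vapply(outputs, file.exists, logical(1))
  if (any(missing)) {
    stop("manifest lists missing output file(s): ",
         paste(unlist(outputs[missing]), collapse = ", "), call. = FALSE)
  }
  manifest <- list(
    package = "pidtrial",
    version = as.character(utils::packageVersion("pidtrial")),
    seed = seed,
    config = if (!is.null(config)) unclass(config) else NULL,
    outputs = outputs,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
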
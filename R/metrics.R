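#' Within-mini-block position profile of windowed connectivity
#'
#' Averages the windowed partial correlation at each within-block volume
#' position, separately per condition, across all mini-blocks (and runs, if
#' the stream spans several). Each volume is attributed to the condition of
#' its own mini-block even though its window may straddle the preceding
#' block. Alongside the mean, the number of windows with a negative partial
#' correlation at each position is counted (the frequency-of-negative-fc
#' secondary measure).
#'
#' @param stream An `fc_stream` from [stream_fc()], or several runs'
#'   streams row-bound together.
#' @return A tibble with columns `condition` (`"fcnf"` / `"nonf"`),
#'   `position`, `mean_fc` (NA when no defined value contributes),
#'   `n_negative` and `n_contributing`.
#' @export
position_profile <- function(stream) {
  stopifnot(all(c("condition", "block_pos", "r_p") %in% names(stream)))
  stream |>
    dplyr::filter(.data$condition %in% c("fcnf", "nonf")) |>
    dplyr::group_by(condition = .data$condition, position = .data$block_pos) |>
    dplyr::summarise(
      mean_fc = if (any(!is.na(.data$r_p))) mean(.data$r_p, na.rm = TRUE)
                else NA_real_,
      n_negative = sum(.data$r_p < 0, na.rm = TRUE),
      n_contributing = sum(!is.na(.data$r_p)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition, .data$position)
}

#' Initial functional connectivity
#'
#' The average windowed partial correlation over the first two post-fixation
#' mini-blocks of the first run, irrespective of their conditions (condition
#' order is counterbalanced, so this always mixes one fc-NF and one no-NF
#' block). Only defined window values contribute; if one of the two blocks
#' is entirely undefined a warning is raised and the mean is taken over the
#' remaining defined values.
#'
#' @param stream The first run's `fc_stream`.
#' @return Mean partial correlation (scalar).
#' @export
initial_fc <- function(stream) {
  stopifnot(all(c("condition", "block", "r_p") %in% names(stream)))
  blocks <- unique(stream$block[stream$condition != "fixation"])
  if (length(blocks) < 2) {
    stop("fewer than two post-fixation mini-blocks", call. = FALSE)
  }
  first_two <- sort(blocks)[1:2]
  sub <- stream[stream$block %in% first_two, ]
  per_block_defined <- tapply(!is.na(sub$r_p), sub$block, any)
  if (!all(per_block_defined)) {
    warning("a mini-block contributes no defined fc value to initial fc",
            call. = FALSE)
  }
  vals <- sub$r_p[!is.na(sub$r_p)]
  if (length(vals) == 0) stop("no defined fc values in the first two mini-blocks",
                              call. = FALSE)
  mean(vals)
}

#' Practice-related change in connectivity across runs
#'
#' The ordinary least-squares slope of per-run total fc on the run index
#' (1..n_runs), where total fc is the mean of all defined windowed partial
#' correlations of the run. A negative slope is change in the desired
#' direction (connectivity drifting more negative with practice); positive
#' slopes are returned signed.
#'
#' @param run_streams A list of per-run `fc_stream`s, or one tibble with a
#'   `run` column.
#' @param scope Which windows enter the per-run mean: `"all"` volumes of
#'   both mini-block conditions (default), or one condition only.
#' @return Least-squares slope (fc change per run).
#' @export
practice_slope <- function(run_streams, scope = c("all", "fcnf_only",
                                                  "nonf_only")) {
  scope <- match.arg(scope)
  streams <- as_run_list(run_streams)
  if (length(streams) < 2) stop("practice slope needs at least two runs",
                                call. = FALSE)
  run_means <- vapply(streams, function(s) {
    keep <- switch(scope,
      all = s$condition %in% c("fcnf", "nonf"),
      fcnf_only = s$condition == "fcnf",
      nonf_only = s$condition == "nonf"
    )
    mean(s$r_p[keep], na.rm = TRUE)
  }, numeric(1))
  run_idx <- seq_along(run_means)
  unname(coef(lm(run_means ~ run_idx))[2])
}

#' The fc-NF-effect: no-NF minus fc-NF connectivity
#'
#' Difference between the mean windowed partial correlation over all no-NF
#' volumes and over all fc-NF volumes, pooled across runs. Positive values
#' mean connectivity was more negative during feedback than during the
#' frozen display (the desired direction).
#'
#' @param run_streams A list of per-run `fc_stream`s, or one tibble (a `run`
#'   column is not required for pooling).
#' @return Mean no-NF r_p minus mean fc-NF r_p.
#' @export
fcnf_effect <- function(run_streams) {
  pooled <- if (is.data.frame(run_streams)) run_streams
            else dplyr::bind_rows(run_streams)
  vals_nonf <- pooled$r_p[pooled$condition == "nonf" & !is.na(pooled$r_p)]
  vals_fcnf <- pooled$r_p[pooled$condition == "fcnf" & !is.na(pooled$r_p)]
  if (length(vals_nonf) == 0 || length(vals_fcnf) == 0) {
    stop("a condition has no defined fc values", call. = FALSE)
  }
  mean(vals_nonf) - mean(vals_fcnf)
}

as_run_list <- function(run_streams) {
  if (is.data.frame(run_streams)) {
    if (!"run" %in% names(run_streams)) {
      stop("a single tibble of several runs needs a run column", call. = FALSE)
    }
    split(run_streams, run_streams$run)
  } else {
    run_streams
  }
}

#' Subject-level summary of one subject's neurofeedback session
#'
#' Convenience wrapper computing every subject-level measure from the
#' per-run fc streams: [initial_fc()] (first run), [practice_slope()],
#' [fcnf_effect()] and the pooled [position_profile()].
#'
#' @inheritParams practice_slope
#' @return A list of class `subject_metrics` with elements `initial_fc`,
#'   `practice_slope`, `fcnf_effect` and `profile`.
#' @export
subject_metrics <- function(run_streams, scope = "all") {
  streams <- as_run_list(run_streams)
  pooled <- dplyr::bind_rows(streams)
  out <- list(
    initial_fc = initial_fc(streams[[1]]),
    practice_slope = if (length(streams) >= 2) {
      practice_slope(streams, scope = scope)
    } else NA_real_,
    fcnf_effect = fcnf_effect(pooled),
    profile = position_profile(pooled)
  )
  class(out) <- "subject_metrics"
  out
}

#' @export
print.subject_metrics <- function(x, ...) {
  cat(sprintf(
    "subject metrics: initial fc %.3f, practice slope %.4f/run, fc-NF-effect %.4f\n",
    x$initial_fc, x$practice_slope, x$fcnf_effect
  ))
  invisible(x)
}

#' Subject metrics for a whole cohort
#'
#' Runs the fc engine over every subject and run of a tidy cohort
#' time-series table and reduces each subject to the subject-level measures.
#'
#' @param timeseries Tidy table (`subject`, `run`, `volume`, `condition`,
#'   `pfc`, `amy`, `cst`), e.g. from [simulate_cohort()].
#' @param schedules Named list of the schedule variants (`"fcnf"` /
#'   `"nonf"`-starting); each subject is matched to the variant whose labels
#'   agree with their recorded conditions. A single `run_schedule` is
#'   accepted when the whole cohort shares one schedule.
#' @param config A [feedback_config()].
#' @param method Streaming method passed to [stream_fc()].
#' @param scope Passed to [practice_slope()].
#' @return A list with `metrics` (tibble: `subject`, `initial_fc`,
#'   `practice_slope`, `fcnf_effect`), `profiles` (long tibble: `subject`,
#'   `condition`, `position`, `mean_fc`, `n_negative`, `n_contributing`) and
#'   `streams` (tibble of all per-volume streams keyed by subject and run).
#' @export
cohort_metrics <- function(timeseries, schedules, config,
                           method = "rolling", scope = "all") {
  if (inherits(schedules, "run_schedule")) schedules <- list(schedules)
  subjects <- sort(unique(timeseries$subject))
  per_subject <- lapply(subjects, function(s) {
    sub <- timeseries[timeseries$subject == s, ]
    runs <- sort(unique(sub$run))
    first_run <- sub[sub$run == runs[1], ]
    sched <- match_schedule(first_run$condition, schedules)
    streams <- lapply(runs, function(r) {
      st <- stream_fc(sub[sub$run == r, ], sched, config, method = method)
      st$subject <- s
      st$run <- r
      st
    })
    sm <- subject_metrics(streams, scope = scope)
    list(
      row = tibble::tibble(subject = s, initial_fc = sm$initial_fc,
                           practice_slope = sm$practice_slope,
                           fcnf_effect = sm$fcnf_effect),
      profile = dplyr::mutate(sm$profile, subject = s, .before = 1),
      stream = dplyr::bind_rows(streams)
    )
  })
  list(
    metrics = dplyr::bind_rows(lapply(per_subject, `[[`, "row")),
    profiles = dplyr::bind_rows(lapply(per_subject, `[[`, "profile")),
    streams = dplyr::bind_rows(lapply(per_subject, `[[`, "stream"))
  )
}

match_schedule <- function(conditions, schedules) {
  for (sched in schedules) {
    if (nrow(sched) == length(conditions) &&
        all(sched$condition == conditions)) {
      return(sched)
    }
  }
  stop("no schedule variant matches the recorded conditions", call. = FALSE)
}

#' Write / read subject metrics and profile tables
#'
#' Metrics: one row per subject (`subject`, `initial_fc`, `practice_slope`,
#' `fcnf_effect`). Profiles: long format (`subject`, `condition`,
#' `position`, `mean_fc`, `n_negative`, `n_contributing`).
#'
#' @param metrics,profiles Tibbles as produced by [cohort_metrics()].
#' @param path File path.
#' @export
write_metrics_tsv <- function(metrics, path) {
  readr::write_tsv(metrics, path)
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @export
read_metrics_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_integer(), .default = readr::col_double()
  ))
}

#' @rdname write_metrics_tsv
#' @export
write_profiles_tsv <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @export
read_profiles_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    condition = readr::col_character(),
    subject = readr::col_integer(), position = readr::col_integer(),
    n_negative = readr::col_integer(), n_contributing = readr::col_integer(),
    .default = readr::col_double()
  ))
}
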
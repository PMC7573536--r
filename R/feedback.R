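#' Thermometer feedback configuration
#'
#' Parameters of the ten-segment thermometer display. The lower bound of the
#' displayed correlation range is always 0; the upper bound defines the
#' implementation: -1 for the negative implementation (reinforces negative
#' connectivity over the full range), -0.3 for the weighted negative
#' implementation (same direction, finer resolution: one segment = 0.03
#' correlation units instead of 0.1), and +1 for the positive implementation.
#' During no-NF mini-blocks the display is frozen at the sixth segment.
#'
#' @param implementation One of `"negative"`, `"weighted_negative"`,
#'   `"positive"`; sets the default `upper_bound`.
#' @param upper_bound Correlation value mapped to the full thermometer.
#'   Defaults to -1 / -0.3 / +1 by implementation; must be nonzero.
#' @param n_segments Number of thermometer segments (10).
#' @param frozen_segment Segment shown throughout no-NF mini-blocks (6).
#' @param window_length Moving correlation window length in volumes (20).
#' @return A list of class `feedback_config`.
#' @examples
#' cfg <- feedback_config("weighted_negative")
#' segment_width(cfg)  # 0.03
#' @export
feedback_config <- function(implementation = c("negative", "weighted_negative",
                                               "positive"),
                            upper_bound = NULL, n_segments = 10L,
                            frozen_segment = 6L, window_length = 20L) {
  implementation <- match.arg(implementation)
  if (is.null(upper_bound)) {
    upper_bound <- switch(implementation,
      negative = -1, weighted_negative = -0.3, positive = 1
    )
  }
  stopifnot(is.numeric(upper_bound), length(upper_bound) == 1)
  if (upper_bound == 0) stop("upper_bound must be nonzero", call. = FALSE)
  stopifnot(n_segments >= 1, frozen_segment >= 1,
            frozen_segment <= n_segments, window_length >= 3)
  cfg <- list(
    implementation = implementation,
    lower_bound = 0,
    upper_bound = upper_bound,
    n_segments = as.integer(n_segments),
    frozen_segment = as.integer(frozen_segment),
    window_length = as.integer(window_length)
  )
  class(cfg) <- "feedback_config"
  cfg
}

#' @export
print.feedback_config <- function(x, ...) {
  cat(sprintf(
    "feedback config: %s (bounds [%g, %g], %d segments of %.3g, frozen %d/%d, L = %d)\n",
    x$implementation, x$lower_bound, x$upper_bound, x$n_segments,
    segment_width(x), x$frozen_segment, x$n_segments, x$window_length
  ))
  invisible(x)
}

#' Correlation width of one thermometer segment
#'
#' The change in partial correlation corresponding to a one-segment change of
#' the display: |upper - lower| / n_segments, i.e. 0.1, 0.03 and 0.1 for the
#' negative, weighted negative and positive implementations.
#'
#' @param config A [feedback_config()].
#' @return Segment width in correlation units.
#' @export
segment_width <- function(config) {
  stopifnot(inherits(config, "feedback_config"))
  abs(config$upper_bound - config$lower_bound) / config$n_segments
}

#' Map a partial correlation to a thermometer segment
#'
#' Linear quantization of the correlation between the configured bounds:
#' `clamp(floor(n_segments * (r - lower) / (upper - lower)), 0, n_segments)`.
#' The mapping is a monotone step function toward the upper bound; values
#' outside the range clamp, and the upper bound itself fills the thermometer.
#'
#' @param r_p Partial correlation value(s); `NA` passes through.
#' @param config A [feedback_config()].
#' @return Integer segment count(s) in `0:n_segments`.
#' @examples
#' fc_to_thermometer(-0.15, feedback_config("weighted_negative"))  # 5
#' fc_to_thermometer(-0.2, feedback_config("positive"))            # 0
#' @export
fc_to_thermometer <- function(r_p, config) {
  stopifnot(inherits(config, "feedback_config"))
  frac <- (r_p - config$lower_bound) / (config$upper_bound - config$lower_bound)
  seg <- floor(config$n_segments * frac)
  seg <- pmax(0, pmin(config$n_segments, seg))
  as.integer(seg)
}

#' Segment shown on screen for a given condition
#'
#' During fc-NF mini-blocks the thermometer reflects the current windowed
#' partial correlation via [fc_to_thermometer()]; during no-NF mini-blocks it
#' is frozen at `frozen_segment`; during fixation nothing is displayed
#' (`NA`). An undefined correlation (degenerate or unfilled window) during
#' fc-NF falls back to the frozen segment so that the display always renders.
#'
#' @param condition Condition label(s): `"fixation"`, `"fcnf"` or `"nonf"`.
#' @param r_p Partial correlation value(s), possibly `NA`.
#' @param config A [feedback_config()].
#' @return Integer segment count(s), `NA` during fixation.
#' @export
displayed_segment <- function(condition, r_p, config) {
  stopifnot(inherits(config, "feedback_config"))
  if (!all(condition %in% .conditions)) {
    stop("unknown condition label", call. = FALSE)
  }
  n <- max(length(condition), length(r_p))
  condition <- rep_len(condition, n)
  r_p <- rep_len(r_p, n)
  out <- rep(NA_integer_, n)
  out[condition == "nonf"] <- config$frozen_segment
  is_fc <- condition == "fcnf"
  seg <- fc_to_thermometer(r_p[is_fc], config)
  seg[is.na(seg)] <- config$frozen_segment
  out[is_fc] <- seg
  out
}
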
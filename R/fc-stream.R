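#' Partial correlation between two signals controlling for a third
#'
#' The windowed connectivity measure: the correlation between prefrontal and
#' amygdala activity after removing the linear contribution of the control
#' (corticospinal tract) signal from both. Computed in closed form,
#' `(r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) * (1 - r_yc^2))`, which equals
#' the correlation of the least-squares residuals of `x` and `y` on `c`.
#'
#' @param x,y Signal vectors (e.g. PFC and amygdala BOLD).
#' @param c Control signal vector partialled out of both.
#' @return Partial correlation in `[-1, 1]`.
#' @examples
#' partial_correlation(c(1, 2, 3, 4, 6), c(1, 2, 3, 4, 6), c(1, 1, 2, 2, 3))
#' @export
partial_correlation <- function(x, y, c) {
  n <- length(x)
  if (length(y) != n || length(c) != n) {
    stop("x, y and c must have equal length", call. = FALSE)
  }
  if (n < 3) stop("window too short", call. = FALSE)
  if (anyNA(x) || anyNA(y) || anyNA(c) ||
      !all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(c))) {
    stop("non-finite values in window", call. = FALSE)
  }
  r <- partial_correlation_closed(x, y, c)
  if (is.na(r)) stop("degenerate window", call. = FALSE)
  r
}

# Closed form on one window; returns NA on zero variance or collinearity
# with the control instead of erroring (the streaming path needs to flag
# degenerate windows without aborting the run).
partial_correlation_closed <- function(x, y, c) {
  sx <- sd(x); sy <- sd(y); sc <- sd(c)
  if (sx == 0 || sy == 0 || sc == 0) return(NA_real_)
  rxy <- cor(x, y); rxc <- cor(x, c); ryc <- cor(y, c)
  denom <- (1 - rxc^2) * (1 - ryc^2)
  if (denom <= .Machine$double.eps) return(NA_real_)
  r <- (rxy - rxc * ryc) / sqrt(denom)
  max(-1, min(1, r))
}

#' Moving-window partial-correlation stream
#'
#' The online engine: for every volume `t >= L` compute the partial
#' correlation between PFC and amygdala, controlling for the CST signal, over
#' the window of the `L` most recent volumes (current volume included), and
#' map it to the displayed thermometer segment given the schedule condition
#' at `t`. Volumes whose window is not yet filled, or whose window is
#' degenerate (zero variance or perfect collinearity with the control),
#' carry `NA`.
#'
#' @param samples A data frame with one row per schedule volume and numeric
#'   columns `pfc`, `amy`, `cst`.
#' @param schedule The [build_run_schedule()] the samples were acquired
#'   under; must have the same number of volumes.
#' @param config A [feedback_config()]; supplies the window length and the
#'   thermometer mapping.
#' @param method `"window"` recomputes every window from scratch (reference
#'   path); `"rolling"` uses running sums (identical to `1e-10`, used for
#'   large simulations).
#' @return An `fc_stream` tibble with one row per volume: `volume`,
#'   `condition`, `block`, `block_pos`, `r_p`, window composition counts
#'   `n_fcnf`, `n_nonf`, `n_fixation`, and `displayed` (thermometer segment,
#'   `NA` during fixation).
#' @export
stream_fc <- function(samples, schedule, config,
                      method = c("window", "rolling")) {
  method <- match.arg(method)
  validate_run_schedule(schedule)
  stopifnot(inherits(config, "feedback_config"))
  need <- c("pfc", "amy", "cst")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns pfc, amy, cst", call. = FALSE)
  }
  n <- nrow(schedule)
  if (nrow(samples) != n) {
    stop("samples and schedule lengths differ", call. = FALSE)
  }
  L <- config$window_length
  if (n < L) stop("run shorter than the correlation window", call. = FALSE)

  x <- as.numeric(samples$pfc)
  y <- as.numeric(samples$amy)
  z <- as.numeric(samples$cst)
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("non-finite ROI samples", call. = FALSE)
  }

  r_p <- rep(NA_real_, n)
  if (method == "window") {
    for (t in L:n) {
      idx <- (t - L + 1):t
      r_p[t] <- partial_correlation_closed(x[idx], y[idx], z[idx])
    }
  } else {
    r_p[L:n] <- rolling_partial(x, y, z, L)
  }

  comp <- window_composition_all(schedule, L)
  counts <- matrix(NA_integer_, nrow = n, ncol = 3)
  counts[L:n, ] <- cbind(comp$n_fcnf, comp$n_nonf, comp$n_fixation)

  out <- tibble::tibble(
    volume = schedule$volume,
    condition = schedule$condition,
    block = schedule$block,
    block_pos = schedule$block_pos,
    r_p = r_p,
    n_fcnf = counts[, 1],
    n_nonf = counts[, 2],
    n_fixation = counts[, 3],
    displayed = displayed_segment(schedule$condition, r_p, config)
  )
  class(out) <- c("fc_stream", class(out))
  out
}

# Windowed partial correlations for all windows via running sums.
# Means are removed per window before forming cross-products to keep the
# rolling arithmetic well conditioned for offset-heavy BOLD signals.
rolling_partial <- function(x, y, z, L) {
  n <- length(x)
  # global centering leaves every windowed correlation unchanged but keeps
  # the cumulative sums small for offset-heavy signals
  x <- x - mean(x); y <- y - mean(y); z <- z - mean(z)
  wsum <- function(v) {
    cs <- c(0, cumsum(v))
    cs[(L + 1):(n + 1)] - cs[1:(n - L + 1)]
  }
  mx <- wsum(x) / L; my <- wsum(y) / L; mz <- wsum(z) / L
  sxx <- wsum(x * x) / L - mx^2
  syy <- wsum(y * y) / L - my^2
  szz <- wsum(z * z) / L - mz^2
  sxy <- wsum(x * y) / L - mx * my
  sxz <- wsum(x * z) / L - mx * mz
  syz <- wsum(y * z) / L - my * mz

  tol <- .Machine$double.eps * 100
  ok <- sxx > tol & syy > tol & szz > tol
  rxy <- rxz <- ryz <- rep(NA_real_, length(mx))
  rxy[ok] <- sxy[ok] / sqrt(sxx[ok] * syy[ok])
  rxz[ok] <- sxz[ok] / sqrt(sxx[ok] * szz[ok])
  ryz[ok] <- syz[ok] / sqrt(syy[ok] * szz[ok])
  denom <- (1 - rxz^2) * (1 - ryz^2)
  out <- ifelse(ok & denom > .Machine$double.eps,
                (rxy - rxz * ryz) / sqrt(denom), NA_real_)
  pmax(-1, pmin(1, out))
}

#' Write / read an fc stream as a tab-separated table
#'
#' @param stream An `fc_stream` tibble from [stream_fc()] (extra key columns
#'   such as `subject` and `run` are preserved).
#' @param path File path.
#' @return `write_fc_stream_tsv()` returns `path` invisibly;
#'   `read_fc_stream_tsv()` returns the tibble.
#' @export
write_fc_stream_tsv <- function(stream, path) {
  readr::write_tsv(stream, path)
  invisible(path)
}

#' @rdname write_fc_stream_tsv
#' @export
read_fc_stream_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    condition = readr::col_character(),
    .default = readr::col_double()
  ))
  for (col in intersect(c("volume", "block", "block_pos", "n_fcnf", "n_nonf",
                          "n_fixation", "displayed", "subject", "run"),
                        names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  class(out) <- c("fc_stream", class(out))
  out
}
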
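#' Group-level position profile with window counts
#'
#' Averages per-subject position profiles into a group profile, weighting
#' subjects equally (the average of subject means, not of pooled volumes),
#' and attaches the number of fc-NF volumes contained in the moving window
#' at each position. The count at a position is the window composition of
#' the canonical schedule averaged over that condition's mini-blocks (the
#' blocks of a steady-state run all share one composition; the first block
#' after fixation differs, which the average reflects).
#'
#' @param profiles Long per-subject profile table from [cohort_metrics()].
#' @param schedule The design's `run_schedule` (either start variant; the
#'   per-position counts are averaged over blocks, so the variants agree).
#' @param L Window length in volumes.
#' @return A tibble of profile points: `condition`, `position`, `mean_fc`,
#'   `n_negative` (group-average count) and `n_fcnf_in_window`.
#' @export
group_profile <- function(profiles, schedule, L = 20L) {
  grp <- profiles |>
    dplyr::group_by(condition = .data$condition, position = .data$position) |>
    dplyr::summarise(
      mean_fc = mean(.data$mean_fc, na.rm = TRUE),
      n_negative = mean(.data$n_negative),
      .groups = "drop"
    )
  counts <- window_composition_all(schedule, L) |>
    dplyr::left_join(
      tibble::tibble(volume = schedule$volume,
                     condition = schedule$condition,
                     position = schedule$block_pos),
      by = "volume"
    ) |>
    dplyr::filter(.data$condition %in% c("fcnf", "nonf")) |>
    dplyr::group_by(condition = .data$condition, position = .data$position) |>
    dplyr::summarise(n_fcnf_in_window = mean(.data$n_fcnf), .groups = "drop")
  dplyr::left_join(grp, counts, by = c("condition", "position")) |>
    dplyr::arrange(.data$condition, .data$position)
}

#' Correlate the group profile with the window's fc-NF volume count
#'
#' The primary group-level measure of feedback effectiveness: the Pearson
#' correlation, over all profile points of both conditions, between the
#' group-average fc (or the frequency of negative partial correlations) at
#' each position and the number of fc-NF volumes inside the moving window at
#' that position. In the standard design this uses N = 40 points (20 per
#' condition). An effective negative-reinforcement implementation yields a
#' negative correlation for mean fc and a positive one for the negative-fc
#' frequency.
#'
#' @param points Profile points from [group_profile()].
#' @param outcome `"mean_fc"` or `"n_negative"`.
#' @return A list with `r`, `n`, `p` (two-tailed) and `zero_variance`
#'   (`TRUE` with `r = NA` when either variable is constant).
#' @export
profile_vs_count <- function(points, outcome = c("mean_fc", "n_negative")) {
  outcome <- match.arg(outcome)
  y <- points[[outcome]]
  x <- points$n_fcnf_in_window
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 profile points", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, n = length(x), p = NA_real_,
                zero_variance = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value,
       zero_variance = FALSE)
}

#' Compare two independent Pearson correlations via Fisher's z
#'
#' Both coefficients are Fisher r-to-z transformed (`atanh`); their
#' difference divided by `sqrt(1/(n1-3) + 1/(n2-3))` is referred to the
#' standard normal (two-tailed). A Student-t approximation (df =
#' n1 + n2 - 6) is available as a variant; the two agree closely at the
#' sample sizes in play.
#'
#' @param r1,r2 Correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @param variant `"z"` (default) or `"t"`.
#' @return A list with `statistic`, `p` (two-tailed) and `variant`.
#' @examples
#' fisher_compare(-0.72, 40, 0.37, 40)$p  # far below 0.001
#' @export
fisher_compare <- function(r1, n1, r2, n2, variant = c("z", "t")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("transform undefined for |r| = 1", call. = FALSE)
  }
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  stat <- (atanh(r1) - atanh(r2)) / se
  p <- if (variant == "z") {
    2 * pnorm(-abs(stat))
  } else {
    2 * pt(-abs(stat), df = n1 + n2 - 6)
  }
  list(statistic = stat, p = p, variant = variant)
}

#' Multivariate outliers by bootstrapping the Mahalanobis distance
#'
#' For each of `B` bootstrap resamples (with replacement) of the bivariate
#' point cloud, the mean vector and covariance matrix are estimated and
#' every original point's squared Mahalanobis distance to them computed; a
#' point is flagged when its distance averaged over resamples exceeds the
#' threshold. The default threshold is the 0.975 quantile of chi-square with
#' 2 degrees of freedom (about 7.378). Resamples with a singular covariance
#' are redrawn.
#'
#' @param x,y Paired observations (no missing values).
#' @param B Number of bootstrap resamples (>= 100).
#' @param threshold Squared-distance cutoff.
#' @param seed Integer seed; flagging is deterministic given the seed.
#' @return A list with `flagged` (logical vector), `distance` (per-point
#'   bootstrap-averaged squared distance), `threshold` and `B`.
#' @export
mahalanobis_bootstrap_outliers <- function(x, y, B = 1000L,
                                           threshold = qchisq(0.975, df = 2),
                                           seed = 1L) {
  stopifnot(length(x) == length(y), B >= 100)
  n <- length(x)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  pts <- cbind(x, y)
  S_full <- stats::cov(pts)
  if (det(S_full) <= .Machine$double.eps) {
    stop("singular covariance", call. = FALSE)
  }
  dist_sum <- numeric(n)
  withr::with_seed(as.integer(seed), {
    b <- 0L
    while (b < B) {
      idx <- sample.int(n, n, replace = TRUE)
      S <- stats::cov(pts[idx, , drop = FALSE])
      if (!is.finite(det(S)) || det(S) <= .Machine$double.eps) next
      mu <- colMeans(pts[idx, , drop = FALSE])
      dist_sum <- dist_sum + mahalanobis(pts, mu, S)
      b <- b + 1L
    }
  })
  dist_mean <- dist_sum / B
  list(flagged = dist_mean > threshold, distance = dist_mean,
       threshold = threshold, B = as.integer(B))
}

#' Pearson correlation between two subject-level measures
#'
#' Two-tailed Pearson correlation over complete pairs (pairwise deletion of
#' missing entries). Optionally, multivariate outliers are flagged with
#' [mahalanobis_bootstrap_outliers()] and the correlation recomputed on the
#' retained pairs; both the raw and the cleaned coefficients are reported.
#'
#' @param x,y Per-subject values (missing entries allowed).
#' @param remove_outliers Flag and remove multivariate outliers.
#' @param B,threshold,seed Passed to [mahalanobis_bootstrap_outliers()].
#' @return A list of class `correlation_result`: `r`, `n`, `p`, and when
#'   outlier removal was requested `outliers` (indices into the complete
#'   pairs, in the original vectors' indexing), `r_after_removal`,
#'   `p_after_removal`, `n_after_removal`.
#' @export
correlate_measures <- function(x, y, remove_outliers = FALSE, B = 1000L,
                               threshold = qchisq(0.975, df = 2), seed = 1L) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  if (sum(keep) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  xs <- x[keep]; ys <- y[keep]
  ct <- cor.test(xs, ys, method = "pearson", alternative = "two.sided")
  out <- list(r = unname(ct$estimate), n = length(xs), p = ct$p.value)
  if (remove_outliers) {
    fl <- mahalanobis_bootstrap_outliers(xs, ys, B = B,
                                         threshold = threshold, seed = seed)
    out$outliers <- which(keep)[fl$flagged]
    retained <- !fl$flagged
    if (sum(retained) < 3) stop("fewer than 3 pairs after outlier removal",
                                call. = FALSE)
    ct2 <- cor.test(xs[retained], ys[retained], method = "pearson",
                    alternative = "two.sided")
    out$r_after_removal <- unname(ct2$estimate)
    out$p_after_removal <- ct2$p.value
    out$n_after_removal <- sum(retained)
  }
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, p = %.4g\n", x$n - 2, x$r, x$p))
  if (!is.null(x$r_after_removal)) {
    cat(sprintf("after removing %d outlier(s): r(%d) = %.3f, p = %.4g\n",
                length(x$outliers), x$n_after_removal - 2,
                x$r_after_removal, x$p_after_removal))
  }
  invisible(x)
}

#' Paired and one-sample t-tests
#'
#' Thin wrappers over [stats::t.test()] with complete-case handling and the
#' two-tailed convention used throughout: `paired_t()` tests the session
#' change `post - pre`; `one_sample_t()` tests a mean against `mu0` (e.g.
#' the practice slopes of a cohort against zero).
#'
#' @param pre,post Paired measurements.
#' @param values Sample for the one-sample test.
#' @param mu0 Null mean.
#' @return A list with `t`, `df`, `p` and `mean` (mean difference, or sample
#'   mean).
#' @export
paired_t <- function(pre, post) {
  keep <- complete.cases(pre, post)
  d <- post[keep] - pre[keep]
  if (length(d) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (sd(d) == 0) stop("zero variance of differences", call. = FALSE)
  tt <- t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(d))
}

#' @rdname paired_t
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (sd(values) == 0) stop("zero variance", call. = FALSE)
  tt <- t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(values))
}
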
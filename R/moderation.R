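#' Three-way moderation model with mean centering
#'
#' Ordinary least squares of an outcome on a focal predictor X, two
#' moderators W and Z, and all their two- and three-way products, after mean
#' centering X, W and Z (products are formed from the centered main effects
#' and not re-centered — the standard moderation convention). The model is
#'
#' `y = i_Y + b1*x + b2*w + b3*xw + b4*z + b5*xz + b6*wz + b7*xwz + e`
#'
#' with coefficient standard errors from the OLS covariance, two-tailed p
#' from t with n - 8 residual degrees of freedom, and 95% t-based confidence
#' intervals. In the neurofeedback application X is state anxiety (STAI-S),
#' W is PFC GABA, Z is ACC GABA and Y is the fc-NF-effect.
#'
#' @param x,w,z,y Numeric vectors; rows with any missing value are dropped
#'   (complete-case).
#' @return A list of class `moderation_fit`: `coefficients` (tibble with
#'   `term` = i_Y, b1..b7, `role` = Constant/X/W/XW/Z/XZ/WZ/XWZ, `coeff`,
#'   `se`, `t`, `p`, `llci`, `ulci`), `f` (overall F), `df1`, `df2`, `p`,
#'   `r_squared`, `n`, `vcov` (coefficient covariance), `w_sd`, `z_sd`
#'   (sample SDs of the centered moderators, used by [simple_slopes()]).
#' @examples
#' set.seed(1)
#' x <- rnorm(19); w <- rnorm(19); z <- rnorm(19)
#' y <- -0.3 * x + rnorm(19, sd = 0.5)
#' fit <- fit_model3(x, w, z, y)
#' fit$df1; fit$df2  # 7 and 11
#' @export
fit_model3 <- function(x, w, z, y) {
  keep <- complete.cases(x, w, z, y)
  x <- x[keep]; w <- w[keep]; z <- z[keep]; y <- y[keep]
  n <- length(y)
  if (n <= 8) stop("no residual df: need n > 8 complete cases", call. = FALSE)
  if (n < 10) stop("need at least 10 complete cases", call. = FALSE)

  xc <- x - mean(x); wc <- w - mean(w); zc <- z - mean(z)
  d <- data.frame(y = y, x = xc, w = wc, xw = xc * wc, z = zc,
                  xz = xc * zc, wz = wc * zc, xwz = xc * wc * zc)
  fit <- lm(y ~ x + w + xw + z + xz + wz + xwz, data = d)
  if (fit$rank < 8) stop("rank-deficient design", call. = FALSE)

  sm <- summary(fit)
  ct <- sm$coefficients
  ci <- confint(fit, level = 0.95)
  terms <- c("i_Y", paste0("b", 1:7))
  roles <- c("Constant", "X", "W", "XW", "Z", "XZ", "WZ", "XWZ")
  coefs <- tibble::tibble(
    term = terms, role = roles,
    coeff = unname(ct[, 1]), se = unname(ct[, 2]),
    t = unname(ct[, 3]), p = unname(ct[, 4]),
    llci = unname(ci[, 1]), ulci = unname(ci[, 2])
  )
  fstat <- sm$fstatistic
  out <- list(
    coefficients = coefs,
    f = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    r_squared = sm$r.squared,
    n = n,
    vcov = vcov(fit),
    w_sd = sd(wc), z_sd = sd(zc)
  )
  out$p <- unname(out$p)
  class(out) <- "moderation_fit"
  out
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("moderation model 3: F(%d, %d) = %.3f, p = %.4g, R^2 = %.3f, n = %d\n",
              x$df1, x$df2, x$f, x$p, x$r_squared, x$n))
  tab <- as.data.frame(x$coefficients)
  tab[, c("coeff", "se", "t", "llci", "ulci")] <-
    round(tab[, c("coeff", "se", "t", "llci", "ulci")], 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Simple slopes of the focal predictor at fixed moderator levels
#'
#' Evaluates the conditional effect of X on Y,
#' `b1 + b3*w + b5*z + b7*w*z`, at the nine combinations of the centered
#' moderator levels -1 SD, 0, +1 SD, with the standard error of each slope
#' from the linear-combination variance of the coefficient covariance and t
#' tests on the fit's residual degrees of freedom. At (0, 0) the slope and
#' its standard error equal those of b1 exactly.
#'
#' @param fit A [fit_model3()] result.
#' @param w_sd,z_sd Moderator spreads defining the +/-1 SD levels; default
#'   to the sample SDs stored in the fit.
#' @return A tibble with `w_level`, `z_level` (labels `-1 SD`, `0`,
#'   `+1 SD`), `w`, `z` (centered values), `slope`, `se`, `t`, `p`, `llci`,
#'   `ulci`.
#' @export
simple_slopes <- function(fit, w_sd = NULL, z_sd = NULL) {
  stopifnot(inherits(fit, "moderation_fit"))
  if (is.null(w_sd)) w_sd <- fit$w_sd
  if (is.null(z_sd)) z_sd <- fit$z_sd
  levels_w <- c(-w_sd, 0, w_sd)
  levels_z <- c(-z_sd, 0, z_sd)
  labels <- c("-1 SD", "0", "+1 SD")
  b <- setNames(fit$coefficients$coeff, fit$coefficients$term)
  V <- fit$vcov
  idx <- c("x", "xw", "xz", "xwz")  # lm terms carrying the X effect
  grid <- expand.grid(wi = 1:3, zi = 1:3)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    w <- levels_w[grid$wi[k]]; z <- levels_z[grid$zi[k]]
    cvec <- c(1, w, z, w * z)
    slope <- b["b1"] + b["b3"] * w + b["b5"] * z + b["b7"] * w * z
    se <- sqrt(drop(t(cvec) %*% V[idx, idx] %*% cvec))
    tt <- slope / se
    crit <- qt(0.975, df = fit$df2)
    tibble::tibble(
      w_level = labels[grid$wi[k]], z_level = labels[grid$zi[k]],
      w = w, z = z, slope = unname(slope), se = se, t = unname(tt),
      p = 2 * pt(-abs(unname(tt)), df = fit$df2),
      llci = unname(slope) - crit * se, ulci = unname(slope) + crit * se
    )
  })
  dplyr::bind_rows(rows)
}

#' Specificity check: refit the moderation with alternative moderator pairs
#'
#' Refits [fit_model3()] with each candidate (W, Z) column pair (e.g.
#' glutamate instead of GABA, or mixed neurotransmitter sets) and reports
#' each model's overall F test, to check whether the moderation is specific
#' to the original moderators.
#'
#' @param data Data frame holding all columns.
#' @param x_col,y_col Focal predictor and outcome column names.
#' @param wz_pairs List of `c(w, z)` column-name pairs.
#' @return A tibble with `w`, `z`, `f`, `df1`, `df2`, `p`, `r_squared`.
#' @export
moderation_specificity <- function(data, x_col, y_col, wz_pairs) {
  rows <- lapply(wz_pairs, function(pr) {
    fit <- fit_model3(data[[x_col]], data[[pr[1]]], data[[pr[2]]],
                      data[[y_col]])
    tibble::tibble(w = pr[1], z = pr[2], f = fit$f, df1 = fit$df1,
                   df2 = fit$df2, p = fit$p, r_squared = fit$r_squared)
  })
  dplyr::bind_rows(rows)
}
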
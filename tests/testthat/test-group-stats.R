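test_that("profile-vs-count correlation matches the textbook formula", {
  pts <- tibble::tibble(
    condition = "fcnf", position = 1:6,
    mean_fc = c(0.30, 0.18, 0.21, 0.05, -0.02, -0.11),
    n_negative = c(1, 2, 2, 4, 5, 6),
    n_fcnf_in_window = c(1, 4, 8, 12, 16, 20)
  )
  res <- profile_vs_count(pts, "mean_fc")
  x <- pts$n_fcnf_in_window; y <- pts$mean_fc
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$n, 6)
  t_hand <- r_hand * sqrt(4) / sqrt(1 - r_hand^2)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-10)

  flat <- pts
  flat$mean_fc <- 0.2
  res_flat <- profile_vs_count(flat, "mean_fc")
  expect_true(res_flat$zero_variance)
  expect_true(is.na(res_flat$r))
})

test_that("group profile weights subjects equally and carries window counts", {
  sched <- exp12_schedule("fcnf")
  profs <- dplyr::bind_rows(
    tibble::tibble(subject = 1, condition = "fcnf", position = 1:20,
                   mean_fc = 0.2, n_negative = 2L, n_contributing = 7L),
    tibble::tibble(subject = 2, condition = "fcnf", position = 1:20,
                   mean_fc = -0.4, n_negative = 6L, n_contributing = 7L),
    tibble::tibble(subject = 1, condition = "nonf", position = 1:20,
                   mean_fc = 0.1, n_negative = 1L, n_contributing = 7L),
    tibble::tibble(subject = 2, condition = "nonf", position = 1:20,
                   mean_fc = 0.3, n_negative = 3L, n_contributing = 7L)
  )
  gp <- group_profile(profs, sched, 20)
  expect_equal(nrow(gp), 40)
  expect_equal(gp$mean_fc[gp$condition == "fcnf"], rep(-0.1, 20))
  expect_equal(gp$n_negative[gp$condition == "nonf"], rep(2, 20))
  # in the fc-NF-starting schedule every no-NF block follows an fc-NF block,
  # so the count is k at fc-NF position k and 20 - k at no-NF position k
  expect_equal(gp$n_fcnf_in_window[gp$condition == "fcnf"], 1:20)
  expect_equal(gp$n_fcnf_in_window[gp$condition == "nonf"], 20 - 1:20)
  # in the no-NF-starting variant the first no-NF block follows fixation
  gp2 <- group_profile(profs, flip_start_condition(sched), 20)
  expect_equal(gp2$n_fcnf_in_window[gp2$condition == "nonf"],
               (20 - 1:20) * 6 / 7)
})

test_that("Fisher z comparison matches the closed form and is antisymmetric", {
  res <- fisher_compare(0.5, 103, 0.3, 103)
  stat_hand <- (atanh(0.5) - atanh(0.3)) / sqrt(1 / 100 + 1 / 100)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(stat_hand)), tolerance = 1e-12)

  same <- fisher_compare(0.4, 40, 0.4, 50)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # the comparison that separates the weighted-negative implementation
  expect_lt(fisher_compare(-0.72, 40, 0.37, 40)$p, 0.001)

  a <- fisher_compare(0.6, 30, -0.2, 45)
  b <- fisher_compare(-0.2, 45, 0.6, 30)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p, b$p)

  tv <- fisher_compare(0.5, 40, 0.3, 40, variant = "t")
  expect_equal(tv$statistic, fisher_compare(0.5, 40, 0.3, 40)$statistic)
  expect_gt(tv$p, fisher_compare(0.5, 40, 0.3, 40)$p)

  expect_error(fisher_compare(1, 40, 0.3, 40), "transform undefined")
})

test_that("a gross outlier is flagged and nothing else", {
  set.seed(6)
  x <- rnorm(30, sd = 0.5); y <- 0.4 * x + rnorm(30, sd = 0.5)
  x <- c(x, 10); y <- c(y, -10)
  fl <- mahalanobis_bootstrap_outliers(x, y, B = 200, seed = 3)
  expect_true(fl$flagged[31])
  expect_equal(sum(fl$flagged), 1)
  # deterministic given the seed
  fl2 <- mahalanobis_bootstrap_outliers(x, y, B = 200, seed = 3)
  expect_identical(fl$distance, fl2$distance)
  expect_error(mahalanobis_bootstrap_outliers(rep(1, 10), rep(2, 10)),
               "singular covariance")
})

test_that("outlier flagging is invariant to affine transforms of the cloud", {
  set.seed(12)
  x <- rnorm(40); y <- rnorm(40)
  x[40] <- 6; y[40] <- -5
  base <- mahalanobis_bootstrap_outliers(x, y, B = 300, seed = 9)
  trans <- mahalanobis_bootstrap_outliers(3 * x - 7, -0.5 * y + 2,
                                          B = 300, seed = 9)
  expect_identical(base$flagged, trans$flagged)
  expect_equal(base$distance, trans$distance, tolerance = 1e-8)
})

test_that("correlate_measures handles exact fits, missingness and outliers", {
  x <- 1:10
  res <- correlate_measures(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-10)

  # pairwise deletion
  xm <- c(1, 2, NA, 4, 5, 6, 7, NA)
  ym <- c(2.1, 3.9, 5, 8.3, 9.8, 12.1, 14.2, 1)
  res2 <- correlate_measures(xm, ym)
  expect_equal(res2$n, 6)
  keep <- complete.cases(xm, ym)
  expect_equal(res2$r, cor(xm[keep], ym[keep]))

  # zero flagged points: cleaned result equals the plain result
  set.seed(8)
  xa <- rnorm(25); ya <- 0.5 * xa + rnorm(25)
  res3 <- correlate_measures(xa, ya, remove_outliers = TRUE, B = 200,
                             seed = 2)
  if (length(res3$outliers) == 0) {
    expect_equal(res3$r_after_removal, res3$r)
    expect_equal(res3$p_after_removal, res3$p)
  } else {
    expect_lte(length(res3$outliers), 2)
  }
  expect_error(correlate_measures(c(1, NA, 3), c(NA, 2, 4)), "3 complete")
})

test_that("null p-values of the measure correlation are uniform", {
  set.seed(123)
  n_rep <- 1000
  pvals <- vapply(seq_len(n_rep), function(i) {
    correlate_measures(rnorm(20), rnorm(20))$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("t-test wrappers match closed forms", {
  pre <- c(4, 5, 6); post <- pre + c(1, 2, 3)
  res <- paired_t(pre, post)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$mean, 2)

  same <- paired_t(c(1, 2, 3, 4), c(1, 2, 3, 4) + c(0.1, -0.1, 0.1, -0.1))
  expect_equal(same$p, 1)  # mean difference zero

  os <- one_sample_t(c(-1, 0, 1), 0)
  expect_equal(os$t, 0)
  expect_equal(os$p, 1)
  expect_error(paired_t(c(1, 2), c(2, 3)), "zero variance")
  expect_error(one_sample_t(rep(3, 5), 0), "zero variance")
})
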
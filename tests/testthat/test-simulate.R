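test_that("generation is bit-identical for equal seeds and differs across seeds", {
  sched <- exp12_schedule("fcnf")
  a <- simulate_subject_timeseries(subject_params(seed = 11), sched, 2)
  b <- simulate_subject_timeseries(subject_params(seed = 11), sched, 2)
  c0 <- simulate_subject_timeseries(subject_params(seed = 12), sched, 2)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$pfc, c0$pfc)))
  expect_lt(abs(cor(a$pfc, c0$pfc)), 0.1)

  co <- cohort_params(n_subjects = 3, seed = 21)
  s1 <- simulate_cohort(co, sched, 1)
  s2 <- simulate_cohort(co, sched, 1)
  expect_identical(s1$timeseries, s2$timeseries)
  expect_identical(s1$covariates, s2$covariates)
})

test_that("windowed partial correlation recovers the generating coupling", {
  # long stationary series, no feedback response, no confound, no smoothing
  sched <- schedule_from_labels(rep("nonf", 10000))
  p <- subject_params(rho_base = -0.3, delta_response = 0, run_drift = 0,
                      gamma = 0, ar_coef = 0, seed = 100)
  ts <- simulate_subject_timeseries(p, sched, 1)
  st <- stream_fc(ts, sched, weighted_cfg(), method = "rolling")
  vals <- st$r_p[!is.na(st$r_p)]
  # overlapping windows: effective sample size ~ n / L for the SE of the mean
  se <- sd(vals) / sqrt(length(vals) / 20)
  expect_lt(abs(mean(vals) - (-0.3)), 3 * se + 0.01)
  # empirical innovation correlation converges to rho
  expect_lt(abs(cor(ts$pfc, ts$amy) - (-0.3)), 0.03)
})

test_that("null configuration shows no fc-NF/no-NF difference", {
  sched <- exp12_schedule("fcnf")
  p <- subject_params(delta_response = 0, gamma = 0, seed = 55)
  ts <- simulate_subject_timeseries(p, sched, 4)
  streams <- lapply(1:4, function(r) {
    stream_fc(ts[ts$run == r, ], sched, weighted_cfg(), method = "rolling")
  })
  eff <- fcnf_effect(streams)
  pooled <- dplyr::bind_rows(streams)
  se <- sd(pooled$r_p, na.rm = TRUE) /
    sqrt(sum(!is.na(pooled$r_p)) / 20)
  expect_lt(abs(eff), 3 * se)
})

test_that("the shared nuisance inflates raw correlation but not the partial", {
  sched <- schedule_from_labels(rep("nonf", 6000))
  p <- subject_params(rho_base = 0, delta_response = 0, gamma = 1,
                      ar_coef = 0, seed = 77)
  ts <- simulate_subject_timeseries(p, sched, 1)
  expect_gt(cor(ts$pfc, ts$amy), 0.3)  # materially positive
  st <- stream_fc(ts, sched, weighted_cfg(), method = "rolling")
  vals <- st$r_p[!is.na(st$r_p)]
  se <- sd(vals) / sqrt(length(vals) / 20)
  expect_lt(abs(mean(vals)), 3 * se + 0.01)

  # paired simulation: same seed with and without the confound gives the
  # same expected partial correlation
  p0 <- subject_params(rho_base = 0, delta_response = 0, gamma = 0,
                       ar_coef = 0, seed = 77)
  ts0 <- simulate_subject_timeseries(p0, sched, 1)
  st0 <- stream_fc(ts0, sched, weighted_cfg(), method = "rolling")
  m0 <- mean(st0$r_p, na.rm = TRUE)
  expect_lt(abs(mean(vals) - m0), 3 * se)
})

test_that("an implied coupling outside (-1, 1) errors", {
  sched <- exp12_schedule("fcnf")
  p <- subject_params(rho_base = 0.8, delta_response = 0.3, seed = 1)
  expect_error(simulate_subject_timeseries(p, sched, 1), "invalid coupling")
  expect_error(subject_params(rho_base = 1.2), "abs")
})

test_that("cohort covariates carry the configured links", {
  sched <- exp12_schedule("fcnf")
  co <- cohort_params(n_subjects = 400, seed = 31)
  sim <- simulate_cohort(co, sched, 1)
  cov <- sim$covariates
  lat <- sim$latents
  # positive trait-anxiety link and negative thought-control link to the
  # baseline coupling, on the latent scale
  expect_gt(cor(cov$stai_t, lat$rho_base), 0.5)
  expect_lt(cor(cov$tcaq_pre, lat$rho_base), -0.5)
  # state anxiety attenuates the (negative) feedback response
  expect_gt(cor(cov$stai_s, lat$delta_response), 0.5)
  # start conditions counterbalanced
  expect_equal(sum(lat$start_condition == "fcnf"), 200)

  # null links: no spurious covariate-latent correlations
  co0 <- cohort_params(n_subjects = 400, seed = 32, b_stait_rho = 0,
                       b_tcaq_rho = 0, b_stais_delta = 0, b_drift_tcaq = 0)
  sim0 <- simulate_cohort(co0, sched, 1)
  null_bound <- qnorm(0.975) / sqrt(400)  # 95% null bound for r at this n
  expect_lt(abs(cor(sim0$covariates$stai_t, sim0$latents$rho_base)),
            3 * null_bound)
  expect_lt(abs(cor(sim0$covariates$stai_s, sim0$latents$delta_response)),
            3 * null_bound)
})

test_that("trait-anxiety link is recovered from measured initial fc", {
  sched <- exp12_schedule("fcnf")
  co <- cohort_params(n_subjects = 200, seed = 61)
  sim <- simulate_cohort(co, sched, 1)
  cm <- cohort_metrics(sim$timeseries, sim$schedules, weighted_cfg())
  joined <- dplyr::left_join(cm$metrics, sim$covariates, by = "subject")
  res <- correlate_measures(joined$initial_fc, joined$stai_t)
  expect_gt(res$r, 0)
  expect_lt(res$p, 0.05)
})

test_that("GABA moderation of the anxiety link is recovered at scale", {
  sched <- exp12_schedule("fcnf")
  co <- cohort_params(n_subjects = 500, seed = 71, b_xwz_delta = 0.04)
  sim <- simulate_cohort(co, sched, 1)
  cov <- sim$covariates
  # the latent feedback response carries the generating three-way structure;
  # sign flips because the fc-NF-effect is the negative of the response
  fit <- fit_model3(cov$stai_s, cov$gaba_pfc, cov$gaba_acc,
                    -sim$latents$delta_response)
  b7 <- fit$coefficients[fit$coefficients$term == "b7", ]
  generating <- -0.04 / (co$stai_s_sd * co$gaba_pfc_sd * co$gaba_acc_sd)
  expect_lt(b7$p, 0.05)
  expect_gt(generating, b7$llci)
  expect_lt(generating, b7$ulci)
})
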
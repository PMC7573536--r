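test_that("position profile averages hand-computed block values", {
  sched <- schedule_from_labels(rep(c("fcnf", "nonf", "fcnf", "nonf"),
                                    each = 3))
  r_p <- c(0.2, -0.4, 0.1, NA, NA, NA, 0.0, -0.2, 0.3, NA, NA, NA)
  st <- manual_stream(sched, r_p)
  prof <- position_profile(st)
  fc <- prof[prof$condition == "fcnf", ]
  expect_equal(fc$mean_fc, c(0.1, -0.3, 0.2))
  expect_equal(fc$n_negative, c(0L, 2L, 0L))
  expect_equal(fc$n_contributing, c(2L, 2L, 2L))
  nn <- prof[prof$condition == "nonf", ]
  expect_true(all(is.na(nn$mean_fc)))
  expect_equal(nn$n_contributing, rep(0L, 3))
})

test_that("a single mini-block profile is the block's values verbatim", {
  sched <- schedule_from_labels(rep(c("fixation", "fcnf"), c(2, 4)))
  vals <- c(NA, NA, 0.3, -0.1, 0.25, -0.6)
  prof <- position_profile(manual_stream(sched, vals))
  expect_equal(prof$mean_fc, vals[3:6])
  expect_equal(prof$n_negative, c(0L, 1L, 0L, 1L))
})

test_that("profile lengths follow the design", {
  sched12 <- exp12_schedule("fcnf")
  ts <- simulate_subject_timeseries(subject_params(seed = 2), sched12, 1)
  st <- stream_fc(ts, sched12, weighted_cfg(), method = "rolling")
  prof <- position_profile(st)
  expect_equal(sum(prof$condition == "fcnf"), 20)
  expect_equal(sum(prof$condition == "nonf"), 20)

  sched3 <- exp3_schedule("fcnf")
  ts3 <- simulate_subject_timeseries(subject_params(seed = 2), sched3, 1)
  st3 <- stream_fc(ts3, sched3, weighted_cfg(), method = "rolling")
  prof3 <- position_profile(st3)
  expect_equal(sum(prof3$condition == "fcnf"), 40)
  expect_equal(sum(prof3$condition == "nonf"), 20)
})

test_that("initial fc is the flat average of the first two mini-blocks", {
  sched <- schedule_from_labels(rep(c("fixation", "fcnf", "nonf", "fcnf"),
                                    c(4, 3, 3, 3)))
  vals <- c(rep(NA, 4), 0.1, 0.2, 0.3, -0.1, -0.2, 0.0, 9, 9, 9)
  expect_equal(initial_fc(manual_stream(sched, vals)),
               mean(c(0.1, 0.2, 0.3, -0.1, -0.2, 0.0)))
  # constant stream value
  vals2 <- c(rep(NA, 4), rep(0.42, 9))
  expect_equal(initial_fc(manual_stream(sched, vals2)), 0.42)
  # block 1 entirely undefined: mean over block 2 with a warning
  vals3 <- c(rep(NA, 4), NA, NA, NA, -0.1, -0.3, 0.1, 9, 9, 9)
  expect_warning(v <- initial_fc(manual_stream(sched, vals3)),
                 "no defined fc")
  expect_equal(v, mean(c(-0.1, -0.3, 0.1)))
  # fewer than two mini-blocks
  one_block <- schedule_from_labels(rep(c("fixation", "fcnf"), c(2, 3)))
  expect_error(initial_fc(manual_stream(one_block, c(NA, NA, 1, 1, 1))),
               "fewer than two")
})

test_that("practice slope is the least-squares slope of per-run total fc", {
  sched <- schedule_from_labels(rep(c("fcnf", "nonf"), each = 2))
  mk <- function(v) manual_stream(sched, rep(v, 4))
  expect_equal(practice_slope(list(mk(-0.1), mk(-0.2), mk(-0.3))), -0.1)
  expect_equal(practice_slope(list(mk(0.2), mk(0.2), mk(0.2))), 0)
  expect_equal(practice_slope(list(mk(0.0), mk(0.1))), 0.1)
  expect_error(practice_slope(list(mk(0.1))), "two runs")
})

test_that("practice slope is shift-invariant and scale-equivariant", {
  sched <- schedule_from_labels(rep(c("fcnf", "nonf"), each = 2))
  set.seed(10)
  runs <- lapply(1:4, function(r) manual_stream(sched, rnorm(4, sd = 0.2)))
  base <- practice_slope(runs)
  shifted <- lapply(runs, function(s) { s$r_p <- s$r_p + 0.5; s })
  scaled <- lapply(runs, function(s) { s$r_p <- s$r_p * 3; s })
  expect_equal(practice_slope(shifted), base)
  expect_equal(practice_slope(scaled), 3 * base)
})

test_that("fc-NF-effect arithmetic and sign conventions hold", {
  sched <- schedule_from_labels(rep(c("fcnf", "nonf"), each = 3))
  st <- manual_stream(sched, c(-0.05, -0.05, -0.05, 0.10, 0.10, 0.10))
  expect_equal(fcnf_effect(st), 0.15)
  # identical distributions: effect 0
  st0 <- manual_stream(sched, rep(0.2, 6))
  expect_equal(fcnf_effect(st0), 0)
  # swapping the labels flips the sign
  swapped <- st
  swapped$condition <- ifelse(st$condition == "fcnf", "nonf", "fcnf")
  expect_equal(fcnf_effect(swapped), -fcnf_effect(st))
  # an empty condition errors
  fc_only <- manual_stream(schedule_from_labels(rep("fcnf", 3)),
                           c(0.1, 0.2, 0.3))
  expect_error(fcnf_effect(fc_only), "no defined fc")
})

test_that("a responsive subject yields a positive expected fc-NF-effect", {
  sched <- exp12_schedule("fcnf")
  effects <- vapply(1:100, function(seed) {
    p <- subject_params(delta_response = -0.25, seed = seed)
    ts <- simulate_subject_timeseries(p, sched, 1)
    fcnf_effect(stream_fc(ts, sched, weighted_cfg(), method = "rolling"))
  }, numeric(1))
  expect_gt(mean(effects), 0)
})

test_that("run-wise and pooled profiles agree with equal block counts", {
  sched <- exp12_schedule("fcnf")
  p <- subject_params(seed = 14)
  ts <- simulate_subject_timeseries(p, sched, 2)
  streams <- lapply(1:2, function(r) {
    stream_fc(ts[ts$run == r, ], sched, weighted_cfg(), method = "rolling")
  })
  pooled <- position_profile(dplyr::bind_rows(streams))
  by_run <- lapply(streams, position_profile)
  averaged <- (by_run[[1]]$mean_fc * by_run[[1]]$n_contributing +
               by_run[[2]]$mean_fc * by_run[[2]]$n_contributing) /
    (by_run[[1]]$n_contributing + by_run[[2]]$n_contributing)
  expect_equal(pooled$mean_fc, averaged)
  # equal contributing counts per run make the flat average equivalent
  expect_equal(by_run[[1]]$n_contributing, by_run[[2]]$n_contributing)
  expect_equal(pooled$mean_fc,
               (by_run[[1]]$mean_fc + by_run[[2]]$mean_fc) / 2)
})

test_that("metrics tables round-trip", {
  sched <- exp12_schedule("fcnf")
  sim <- simulate_cohort(cohort_params(n_subjects = 3, seed = 4), sched, 2)
  cm <- cohort_metrics(sim$timeseries, sim$schedules, weighted_cfg())
  mpath <- withr::local_tempfile(fileext = ".tsv")
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_tsv(cm$metrics, mpath)
  write_profiles_tsv(cm$profiles, ppath)
  expect_equal(as.data.frame(read_metrics_tsv(mpath)),
               as.data.frame(cm$metrics))
  expect_equal(as.data.frame(read_profiles_tsv(ppath)),
               as.data.frame(cm$profiles))
})
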
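#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage end-to-end: simulate the cohort, stream the windowed
#' partial correlations under the configured feedback mapping, reduce each
#' subject to the subject-level measures, run the group statistics
#' (profile-vs-window-count correlations for mean fc and for the frequency
#' of negative fc, the brain-behaviour correlations with and without
#' bootstrapped-Mahalanobis outlier removal, the practice-slope one-sample
#' t-test and the TCAQ paired t-test) and fit the three-way moderation of
#' the state-anxiety / fc-NF-effect relation by PFC and ACC GABA with its
#' simple slopes. All intermediate tables are written as tab-separated
#' files and the statistics as one JSON report; the run is fully
#' reproducible from (config, seed).
#'
#' @param config A `pipeline_config`, see [default_config()].
#' @param output_dir Directory for tables and the report (created if
#'   needed).
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config, output_dir) {
  config <- validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(config$seed)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] seed %d: %s", stage, seeds[[stage]],
                    sprintf(...)))
  }

  # simulate
  d <- config$design
  schedule <- build_run_schedule(d$fixation_len, d$n_pairs, d$fcnf_len,
                                 d$nonf_len, "fcnf")
  sim_args <- config$simulate
  sim_args$seed <- seeds[["simulate"]]
  cohort <- do.call(cohort_params, sim_args)
  sim <- simulate_cohort(cohort, schedule, n_runs = d$n_runs)
  log_stage("simulate", "%d subjects x %d runs x %d volumes",
            cohort$n_subjects, d$n_runs, nrow(schedule))
  write_timeseries_tsv(sim$timeseries, file.path(output_dir, "timeseries.tsv"))
  write_covariates_tsv(sim$covariates, file.path(output_dir, "covariates.tsv"))
  write_schedule_tsv(schedule, file.path(output_dir, "schedule.tsv"))

  # feedback / stream / metrics
  fb <- config$feedback
  fcfg <- feedback_config(fb$implementation, upper_bound = fb$upper_bound,
                          n_segments = fb$n_segments,
                          frozen_segment = fb$frozen_segment,
                          window_length = fb$window_length)
  cm <- cohort_metrics(sim$timeseries, sim$schedules, fcfg,
                       scope = config$stats$slope_scope)
  log_stage("metrics", "%d subject metric rows", nrow(cm$metrics))
  write_fc_stream_tsv(cm$streams, file.path(output_dir, "fc_streams.tsv"))
  write_metrics_tsv(cm$metrics, file.path(output_dir, "subject_metrics.tsv"))
  write_profiles_tsv(cm$profiles, file.path(output_dir, "profiles.tsv"))

  # group statistics
  st <- config$stats
  gp <- group_profile(cm$profiles, schedule, L = fb$window_length)
  readr::write_tsv(gp, file.path(output_dir, "group_profile.tsv"))
  prof_fc <- profile_vs_count(gp, "mean_fc")
  prof_neg <- profile_vs_count(gp, "n_negative")

  joined <- dplyr::left_join(cm$metrics, sim$covariates, by = "subject")
  joined$tcaq_change <- joined$tcaq_post - joined$tcaq_pre
  pairs <- list(
    c("initial_fc", "stai_t"), c("initial_fc", "tcaq_pre"),
    c("practice_slope", "tcaq_change"), c("fcnf_effect", "stai_s")
  )
  cor_rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    res <- correlate_measures(joined[[pr[1]]], joined[[pr[2]]],
                              remove_outliers = TRUE, B = st$bootstrap_B,
                              threshold = st$outlier_threshold,
                              seed = seeds[["groupstats"]] %% 100000L + i)
    tibble::tibble(measure_x = pr[1], measure_y = pr[2], n = res$n,
                   r = res$r, p = res$p,
                   n_outliers = length(res$outliers),
                   r_clean = res$r_after_removal,
                   p_clean = res$p_after_removal)
  })
  cors <- dplyr::bind_rows(cor_rows)
  if (st$correction == "BH") {
    cors$p_adj <- stats::p.adjust(cors$p, method = "BH")
  }
  readr::write_tsv(cors, file.path(output_dir, "correlations.tsv"))
  slope_test <- one_sample_t(cm$metrics$practice_slope, 0)
  tcaq_test <- paired_t(joined$tcaq_pre, joined$tcaq_post)
  log_stage("groupstats", "profile r = %.3f (fc), %.3f (neg freq)",
            prof_fc$r, prof_neg$r)

  # moderation
  fit <- fit_model3(joined$stai_s, joined$gaba_pfc, joined$gaba_acc,
                    joined$fcnf_effect)
  slopes <- simple_slopes(fit)
  readr::write_tsv(fit$coefficients,
                   file.path(output_dir, "moderation_coefficients.tsv"))
  readr::write_tsv(slopes, file.path(output_dir, "simple_slopes.tsv"))
  log_stage("moderation", "F(%d, %d) = %.3f", fit$df1, fit$df2, fit$f)

  report <- list(
    seed = config$seed,
    stage_seeds = as.list(seeds),
    design = config$design,
    profile_vs_count = list(
      mean_fc = prof_fc[c("r", "n", "p")],
      n_negative = prof_neg[c("r", "n", "p")]
    ),
    practice_slope_test = slope_test,
    tcaq_change_test = tcaq_test,
    correlations = cors,
    moderation = list(
      f = fit$f, df1 = fit$df1, df2 = fit$df2, p = fit$p,
      r_squared = fit$r_squared, n = fit$n,
      coefficients = fit$coefficients,
      simple_slopes = slopes
    )
  )
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
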
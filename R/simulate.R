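#' Subject-level generative parameters for synthetic ROI time series
#'
#' The generator produces the three ROI channels (PFC, amygdala, CST) as
#' correlated Gaussian innovation streams passed through an order-1
#' autoregression, plus a shared standard-Gaussian nuisance component. The
#' instantaneous PFC-amygdala innovation correlation is piecewise constant,
#' `rho(t) = rho_base + delta_response * [t in fc-NF block] +
#' run_drift * (run - 1)`, so `delta_response < 0` encodes a subject who
#' shifts connectivity toward negative values under feedback and `run_drift`
#' encodes practice-related change across runs.
#'
#' The CST channel is modelled as an almost-pure readout of the shared
#' nuisance (`cst = nuisance + cst_noise_sd * own noise`): the control ROI is
#' by design a measure of global, task-unrelated signal, and keeping its
#' independent noise small makes partialling it out remove the nuisance from
#' the PFC-amygdala correlation essentially exactly.
#'
#' @param rho_base Baseline innovation correlation, in (-1, 1).
#' @param delta_response Additive correlation shift during fc-NF blocks.
#' @param run_drift Additive correlation shift per run index (run 1 = 0).
#' @param gamma Loading of the shared nuisance on PFC and amygdala (>= 0).
#' @param ar_coef Temporal autocorrelation of each channel, in [0, 1).
#' @param noise_sd Innovation scale (> 0).
#' @param cst_noise_sd Independent measurement noise of the control channel.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(rho_base = 0.1, delta_response = -0.25,
                           run_drift = 0, gamma = 0.5, ar_coef = 0.3,
                           noise_sd = 1, cst_noise_sd = 0.05, seed = 1L) {
  stopifnot(abs(rho_base) < 1, ar_coef >= 0, ar_coef < 1, noise_sd > 0,
            gamma >= 0, cst_noise_sd >= 0)
  p <- list(rho_base = rho_base, delta_response = delta_response,
            run_drift = run_drift, gamma = gamma, ar_coef = ar_coef,
            noise_sd = noise_sd, cst_noise_sd = cst_noise_sd,
            seed = as.integer(seed))
  class(p) <- "subject_params"
  p
}

#' Simulate one subject's ROI time series
#'
#' Generates per-volume (PFC, amygdala, CST) samples for `n_runs` repetitions
#' of a run schedule, with block-dependent PFC-amygdala coupling, AR(1)
#' temporal structure and a shared nuisance component on all channels (see
#' [subject_params()] for the model). Correlated innovations are produced by
#' Gaussian mixing, `y = rho * x + sqrt(1 - rho^2) * e`, which fixes the
#' instantaneous correlation at exactly `rho(t)`.
#'
#' @param params A [subject_params()].
#' @param schedule A [build_run_schedule()] describing one run.
#' @param n_runs Number of runs to generate.
#' @return A tibble with columns `run`, `volume`, `condition`, `pfc`, `amy`,
#'   `cst`, one row per volume per run.
#' @export
simulate_subject_timeseries <- function(params, schedule, n_runs = 4) {
  stopifnot(inherits(params, "subject_params"), n_runs >= 1)
  validate_run_schedule(schedule)
  n <- nrow(schedule)
  is_fc <- schedule$condition == "fcnf"
  burn <- 50L  # AR(1) burn-in discarded so each run starts near stationarity

  runs <- withr::with_seed(params$seed, {
    lapply(seq_len(n_runs), function(r) {
      rho <- params$rho_base + params$delta_response * is_fc +
        params$run_drift * (r - 1)
      if (any(abs(rho) >= 1)) stop("invalid coupling", call. = FALSE)
      rho <- c(rep(rho[1], burn), rho)
      m <- n + burn
      ex <- rnorm(m, sd = params$noise_sd)
      ee <- rnorm(m, sd = params$noise_sd)
      ec <- rnorm(m, sd = params$noise_sd)
      ey <- rho * ex + sqrt(1 - rho^2) * ee
      ar1 <- function(innov) {
        as.numeric(stats::filter(innov, params$ar_coef, method = "recursive"))
      }
      g <- rnorm(m)
      keep <- (burn + 1):m
      tibble::tibble(
        run = r,
        volume = schedule$volume,
        condition = schedule$condition,
        pfc = (ar1(ex) + params$gamma * g)[keep],
        amy = (ar1(ey) + params$gamma * g)[keep],
        cst = (params$cst_noise_sd * ar1(ec) + g)[keep]
      )
    })
  })
  dplyr::bind_rows(runs)
}

#' Cohort-level generative parameters
#'
#' Defines the cohort size, the covariate distributions (state and trait
#' anxiety, thought-control ability before/after the session, PFC and ACC
#' GABA) and the link coefficients tying covariates to the subject-level
#' connectivity parameters. Links operate on z-scored covariates
#' (standardised by the stated population means/SDs):
#'
#' * `b_stait_rho` (> 0): trait anxiety raises the baseline coupling
#'   `rho_base` (more anxious subjects start with more positive fc).
#' * `b_tcaq_rho` (< 0): thought-control ability lowers `rho_base`.
#' * `b_stais_delta` (> 0): state anxiety attenuates the (negative) fc-NF
#'   response `delta_response`, shrinking the fc-NF-effect.
#' * `b_xw_delta`, `b_xz_delta`, `b_xwz_delta`: moderation of the state-
#'   anxiety link by PFC GABA (W), ACC GABA (Z) and their product.
#' * `b_drift_tcaq` (< 0): subjects whose fc drifts upward across runs gain
#'   less thought-control ability over the session.
#'
#' GABA covariate defaults (percent of total creatine) follow typical
#' adolescent MRS values: PFC 5.29 +/- 2.25, ACC 5.811 +/- 1.40.
#'
#' @param n_subjects Cohort size (>= 2).
#' @param stai_s_mean,stai_s_sd,stai_t_mean,stai_t_sd,tcaq_mean,tcaq_sd,gaba_pfc_mean,gaba_pfc_sd,gaba_acc_mean,gaba_acc_sd
#'   Covariate population moments (SDs > 0).
#' @param b_stait_rho,b_tcaq_rho,b_stais_delta,b_xw_delta,b_xz_delta,b_xwz_delta,b_drift_tcaq
#'   Link coefficients, see Details.
#' @param rho_base_mean,rho_base_sd Baseline coupling mean and residual SD.
#' @param delta_mean,delta_sd fc-NF response mean (negative = responsive
#'   cohort) and residual SD.
#' @param run_drift_sd Between-subject SD of the per-run drift (mean 0).
#' @param tcaq_change_mean,tcaq_change_sd Session change in TCAQ.
#' @param ar_coef,gamma,noise_sd,cst_noise_sd Passed to [subject_params()].
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 20,
                          stai_s_mean = 35, stai_s_sd = 8,
                          stai_t_mean = 38, stai_t_sd = 9,
                          tcaq_mean = 80, tcaq_sd = 12,
                          gaba_pfc_mean = 5.29, gaba_pfc_sd = 2.25,
                          gaba_acc_mean = 5.811, gaba_acc_sd = 1.40,
                          b_stait_rho = 0.08, b_tcaq_rho = -0.08,
                          b_stais_delta = 0.08, b_xw_delta = 0,
                          b_xz_delta = 0, b_xwz_delta = 0,
                          b_drift_tcaq = -4,
                          rho_base_mean = 0.1, rho_base_sd = 0.05,
                          delta_mean = -0.25, delta_sd = 0.05,
                          run_drift_sd = 0.01,
                          tcaq_change_mean = 0, tcaq_change_sd = 5,
                          ar_coef = 0.3, gamma = 0.5, noise_sd = 1,
                          cst_noise_sd = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 2, stai_s_sd > 0, stai_t_sd > 0, tcaq_sd > 0,
            gaba_pfc_sd > 0, gaba_acc_sd > 0)
  p <- as.list(environment())
  p$n_subjects <- as.integer(n_subjects)
  p$seed <- as.integer(seed)
  class(p) <- "cohort_params"
  p
}

#' Simulate a cohort: per-subject time series plus covariate table
#'
#' Draws Gaussian covariates, maps them through the configured links to the
#' subject-level connectivity parameters, counterbalances the start
#' condition across the cohort, and generates every subject's ROI time
#' series. The latent per-subject parameters are returned alongside the
#' observable covariates so that parameter-recovery experiments can compare
#' fitted coefficients with the generating truth.
#'
#' @param cohort A [cohort_params()].
#' @param schedule Run schedule of the design (the counterbalanced half of
#'   the cohort receives the label-flipped schedule).
#' @param n_runs Runs per subject.
#' @return A list with elements `timeseries` (tibble: `subject`, `run`,
#'   `volume`, `condition`, `pfc`, `amy`, `cst`), `covariates` (tibble:
#'   `subject`, `stai_s`, `stai_t`, `tcaq_pre`, `tcaq_post`, `gaba_pfc`,
#'   `gaba_acc`), `latents` (tibble of generating subject parameters and
#'   start conditions) and `schedules` (list: the two schedule variants).
#' @export
simulate_cohort <- function(cohort, schedule, n_runs = 4) {
  stopifnot(inherits(cohort, "cohort_params"))
  validate_run_schedule(schedule)
  n <- cohort$n_subjects

  cov_and_latents <- withr::with_seed(cohort$seed, {
    zS <- rnorm(n); zT <- rnorm(n); zC <- rnorm(n)
    zW <- rnorm(n); zZ <- rnorm(n)
    rho_base <- cohort$rho_base_mean + cohort$b_stait_rho * zT +
      cohort$b_tcaq_rho * zC + rnorm(n, sd = cohort$rho_base_sd)
    slope_x <- cohort$b_stais_delta + cohort$b_xw_delta * zW +
      cohort$b_xz_delta * zZ + cohort$b_xwz_delta * zW * zZ
    delta <- cohort$delta_mean + slope_x * zS +
      rnorm(n, sd = cohort$delta_sd)
    drift <- rnorm(n, sd = cohort$run_drift_sd)
    tcaq_change <- cohort$tcaq_change_mean +
      cohort$b_drift_tcaq * (drift / max(cohort$run_drift_sd, 1e-12)) +
      rnorm(n, sd = cohort$tcaq_change_sd)
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(
      covariates = tibble::tibble(
        subject = seq_len(n),
        stai_s = cohort$stai_s_mean + cohort$stai_s_sd * zS,
        stai_t = cohort$stai_t_mean + cohort$stai_t_sd * zT,
        tcaq_pre = cohort$tcaq_mean + cohort$tcaq_sd * zC,
        tcaq_post = cohort$tcaq_mean + cohort$tcaq_sd * zC + tcaq_change,
        gaba_pfc = cohort$gaba_pfc_mean + cohort$gaba_pfc_sd * zW,
        gaba_acc = cohort$gaba_acc_mean + cohort$gaba_acc_sd * zZ
      ),
      latents = tibble::tibble(
        subject = seq_len(n),
        rho_base = rho_base, delta_response = delta, run_drift = drift,
        seed = subject_seeds
      )
    )
  })
  covariates <- cov_and_latents$covariates
  latents <- cov_and_latents$latents

  starts <- assign_start_conditions(n, cohort$seed + 1L)
  latents$start_condition <- starts
  sched_first <- schedule$condition[schedule$condition != "fixation"][1]
  schedules <- list(schedule, alternate_start_schedule(schedule))
  names(schedules) <- c(sched_first, setdiff(c("fcnf", "nonf"), sched_first))

  series <- lapply(seq_len(n), function(i) {
    sp <- subject_params(
      rho_base = latents$rho_base[i],
      delta_response = latents$delta_response[i],
      run_drift = latents$run_drift[i],
      gamma = cohort$gamma, ar_coef = cohort$ar_coef,
      noise_sd = cohort$noise_sd, cst_noise_sd = cohort$cst_noise_sd,
      seed = latents$seed[i]
    )
    ts <- simulate_subject_timeseries(sp, schedules[[starts[i]]], n_runs)
    ts$subject <- i
    ts[, c("subject", "run", "volume", "condition", "pfc", "amy", "cst")]
  })

  list(
    timeseries = dplyr::bind_rows(series),
    covariates = covariates,
    latents = latents,
    schedules = schedules
  )
}

#' Write / read the tidy ROI time-series table
#'
#' Columns: `subject`, `run`, `volume`, `condition`, `pfc`, `amy`, `cst`.
#'
#' @param timeseries Tidy time-series tibble.
#' @param path File path.
#' @export
write_timeseries_tsv <- function(timeseries, path) {
  readr::write_tsv(timeseries, path)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_integer(), run = readr::col_integer(),
    volume = readr::col_integer(), condition = readr::col_character(),
    pfc = readr::col_double(), amy = readr::col_double(),
    cst = readr::col_double()
  ))
  out
}

#' Write / read the per-subject covariate table
#'
#' Columns: `subject`, `stai_s`, `stai_t`, `tcaq_pre`, `tcaq_post`,
#' `gaba_pfc`, `gaba_acc`.
#'
#' @param covariates Covariate tibble.
#' @param path File path.
#' @export
write_covariates_tsv <- function(covariates, path) {
  readr::write_tsv(covariates, path)
  invisible(path)
}

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_integer(), .default = readr::col_double()
  ))
}
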
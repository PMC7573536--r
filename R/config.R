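#' Default pipeline configuration
#'
#' Assembles the full configuration for [run_pipeline()]: the run design,
#' the feedback mapping, the synthetic-cohort generator settings and the
#' statistics options. Two presets mirror the two designs in play:
#' `"exp2"` — four 300-volume runs of seven 20-volume fc-NF / no-NF
#' mini-block pairs after a 20-volume fixation block; `"exp3"` — three
#' 320-volume runs of five pairs with 40-volume fc-NF mini-blocks.
#'
#' @param experiment `"exp2"` or `"exp3"`.
#' @param seed Global integer seed; stage seeds are derived from it (see
#'   [split_seed()]).
#' @return A nested list of class `pipeline_config` with entries `design`,
#'   `feedback`, `simulate`, `stats`, `seed`.
#' @export
default_config <- function(experiment = c("exp2", "exp3"), seed = 1L) {
  experiment <- match.arg(experiment)
  design <- if (experiment == "exp2") {
    list(fixation_len = 20L, n_pairs = 7L, fcnf_len = 20L, nonf_len = 20L,
         n_runs = 4L)
  } else {
    list(fixation_len = 20L, n_pairs = 5L, fcnf_len = 40L, nonf_len = 20L,
         n_runs = 3L)
  }
  cfg <- list(
    design = design,
    feedback = list(implementation = "weighted_negative", upper_bound = -0.3,
                    n_segments = 10L, frozen_segment = 6L,
                    window_length = 20L),
    simulate = formals_defaults(cohort_params,
                                drop = c("seed")),
    stats = list(bootstrap_B = 1000L,
                 outlier_threshold = qchisq(0.975, df = 2),
                 fisher_variant = "z", slope_scope = "all",
                 correction = "none"),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

formals_defaults <- function(fn, drop = character(0)) {
  fm <- formals(fn)
  fm <- fm[setdiff(names(fm), drop)]
  lapply(fm, eval, envir = baseenv())
}

#' Validate a pipeline configuration
#'
#' Checks all sections for unknown keys, missing fields and invalid values,
#' with explicit error messages, before any compute runs.
#'
#' @param config A configuration list.
#' @return The config, classed `pipeline_config`, invisibly.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  known_top <- c("design", "feedback", "simulate", "stats", "seed")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_top <- setdiff(known_top, names(config))
  if (length(missing_top) > 0) {
    stop("missing config sections: ", paste(missing_top, collapse = ", "),
         call. = FALSE)
  }

  check_section <- function(section, name, known, required = known) {
    unknown <- setdiff(names(section), known)
    if (length(unknown) > 0) {
      stop(sprintf("unknown keys in config$%s: %s", name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    miss <- setdiff(required, names(section))
    if (length(miss) > 0) {
      stop(sprintf("missing keys in config$%s: %s", name,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }

  d <- config$design
  check_section(d, "design",
                c("fixation_len", "n_pairs", "fcnf_len", "nonf_len", "n_runs"))
  if (d$n_pairs < 1) stop("config$design$n_pairs must be >= 1", call. = FALSE)
  if (d$n_runs < 1) stop("config$design$n_runs must be >= 1", call. = FALSE)
  if (d$fcnf_len < 1 || d$nonf_len < 1) {
    stop("mini-block lengths must be >= 1", call. = FALSE)
  }

  fb <- config$feedback
  check_section(fb, "feedback",
                c("implementation", "upper_bound", "n_segments",
                  "frozen_segment", "window_length"))
  if (!fb$implementation %in% c("negative", "weighted_negative", "positive")) {
    stop("config$feedback$implementation must be one of negative, ",
         "weighted_negative, positive", call. = FALSE)
  }
  if (fb$upper_bound == 0) {
    stop("config$feedback$upper_bound must be nonzero", call. = FALSE)
  }
  if (fb$frozen_segment < 1 || fb$frozen_segment > fb$n_segments) {
    stop("config$feedback$frozen_segment must lie in 1..n_segments",
         call. = FALSE)
  }
  if (fb$window_length < 3) {
    stop("config$feedback$window_length must be >= 3", call. = FALSE)
  }

  sim_known <- names(formals_defaults(cohort_params, drop = "seed"))
  check_section(config$simulate, "simulate", sim_known,
                required = "n_subjects")
  if (config$simulate$n_subjects < 2) {
    stop("config$simulate$n_subjects must be >= 2", call. = FALSE)
  }

  st <- config$stats
  check_section(st, "stats",
                c("bootstrap_B", "outlier_threshold", "fisher_variant",
                  "slope_scope", "correction"))
  if (!st$fisher_variant %in% c("z", "t")) {
    stop("config$stats$fisher_variant must be 'z' or 't'", call. = FALSE)
  }
  if (!st$slope_scope %in% c("all", "fcnf_only", "nonf_only")) {
    stop("config$stats$slope_scope must be all, fcnf_only or nonf_only",
         call. = FALSE)
  }
  if (!st$correction %in% c("none", "BH")) {
    stop("config$stats$correction must be 'none' or 'BH'", call. = FALSE)
  }
  if (st$bootstrap_B < 100) {
    stop("config$stats$bootstrap_B must be >= 100", call. = FALSE)
  }

  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    stop("config$seed must be a single integer", call. = FALSE)
  }
  if (!inherits(config, "pipeline_config")) {
    class(config) <- c("pipeline_config", class(config))
  }
  invisible(config)
}

#' Read / write the JSON pipeline configuration
#'
#' The configuration file is validated on load; unknown keys are rejected.
#' A descriptive schema ships at
#' `system.file("extdata", "config-schema.json", package = "fcnf")`.
#'
#' @param path JSON file path.
#' @param config A `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Derive per-stage seeds from the global seed
#'
#' One global seed fans out to stage-level seeds so that pipeline stages can
#' be rerun in isolation and still reproduce the full-pipeline numbers. The
#' splitting rule is fixed: seed the base RNG with the global seed and draw
#' the stage seeds as uniform integers in order (simulate, metrics,
#' groupstats, moderation).
#'
#' @param seed Global integer seed.
#' @return Named integer vector of stage seeds.
#' @export
split_seed <- function(seed) {
  stages <- c("simulate", "metrics", "groupstats", "moderation")
  withr::with_seed(as.integer(seed), {
    setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
  })
}
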
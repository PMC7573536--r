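# Independent oracles and small fixtures shared across test files.

# Brute-force partial correlation: correlate the least-squares residuals of
# x and y after removing c (the definition, independent of the closed form
# used by the package).
residual_partial <- function(x, y, c) {
  stats::cor(stats::resid(stats::lm(x ~ c)), stats::resid(stats::lm(y ~ c)))
}

# Standard experiment schedules.
exp12_schedule <- function(start = "fcnf") {
  build_run_schedule(20, 7, 20, 20, start)
}
exp3_schedule <- function(start = "fcnf") {
  build_run_schedule(20, 5, 40, 20, start)
}

weighted_cfg <- function() feedback_config("weighted_negative")

# Hand-built fc stream: a schedule with per-volume r_p values supplied
# directly, bypassing the engine, for metric arithmetic tests.
manual_stream <- function(schedule, r_p) {
  tibble::tibble(
    volume = schedule$volume,
    condition = schedule$condition,
    block = schedule$block,
    block_pos = schedule$block_pos,
    r_p = r_p
  )
}
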
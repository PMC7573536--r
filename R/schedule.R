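#' Build a block-design neurofeedback run schedule
#'
#' Construct the per-volume condition schedule for one neurofeedback run: an
#' initial fixation block followed by `n_pairs` alternating pairs of fc-NF and
#' no-NF mini-blocks. The standard design uses a 20-volume fixation block and
#' seven pairs of 20-volume mini-blocks (300 volumes per run); the
#' long-block variant uses five pairs with 40-volume fc-NF mini-blocks and
#' 20-volume no-NF mini-blocks over three runs.
#'
#' @param fixation_len Number of fixation volumes at the start of the run.
#' @param n_pairs Number of (fc-NF, no-NF) mini-block pairs.
#' @param fcnf_len Length of each fc-NF mini-block, in volumes.
#' @param nonf_len Length of each no-NF mini-block, in volumes.
#' @param start_condition Condition of the first mini-block after fixation,
#'   `"fcnf"` or `"nonf"`. Start conditions are counterbalanced across
#'   subjects; see [assign_start_conditions()].
#'
#' @return A `run_schedule`: a tibble with one row per volume and columns
#'   `volume` (1-based index), `condition` (`"fixation"`, `"fcnf"` or
#'   `"nonf"`), `block` (1-based block index, fixation included) and
#'   `block_pos` (1-based position within the block).
#'
#' @examples
#' sched <- build_run_schedule(20, 7, 20, 20, "fcnf")
#' nrow(sched)           # 300 volumes
#' table(sched$condition)
#' @export
build_run_schedule <- function(fixation_len = 20, n_pairs = 7,
                               fcnf_len = 20, nonf_len = 20,
                               start_condition = c("fcnf", "nonf")) {
  start_condition <- match.arg(start_condition)
  stopifnot(fixation_len >= 0, n_pairs >= 0, fcnf_len >= 1, nonf_len >= 1)
  if (n_pairs == 0 && fixation_len == 0) {
    stop("empty schedule: n_pairs = 0 with zero fixation", call. = FALSE)
  }
  other <- if (start_condition == "fcnf") "nonf" else "fcnf"
  len_of <- c(fcnf = fcnf_len, nonf = nonf_len)

  conds <- character(0)
  lens <- integer(0)
  if (fixation_len > 0) {
    conds <- "fixation"
    lens <- fixation_len
  }
  if (n_pairs > 0) {
    pair <- c(start_condition, other)
    conds <- c(conds, rep(pair, n_pairs))
    lens <- c(lens, rep(unname(len_of[pair]), n_pairs))
  }
  n_blocks <- length(conds)
  sched <- tibble::tibble(
    condition = rep(conds, lens),
    block = rep(seq_len(n_blocks), lens),
    block_pos = unlist(lapply(lens, seq_len), use.names = FALSE)
  )
  sched$volume <- seq_len(nrow(sched))
  sched <- sched[, c("volume", "condition", "block", "block_pos")]
  class(sched) <- c("run_schedule", class(sched))
  validate_run_schedule(sched)
}

#' Validate a run schedule
#'
#' Checks the structural invariants of a per-volume schedule: non-empty,
#' known condition labels, consecutive 1-based volumes, non-decreasing block
#' index, and a constant condition within each block.
#'
#' @param schedule A schedule tibble as produced by [build_run_schedule()].
#' @return The schedule, invisibly classed as `run_schedule`.
#' @export
validate_run_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1)
  need <- c("volume", "condition", "block", "block_pos")
  missing_cols <- setdiff(need, names(schedule))
  if (length(missing_cols) > 0) {
    stop("schedule is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(schedule$condition %in% .conditions)) {
    stop("unknown condition labels in schedule", call. = FALSE)
  }
  if (!identical(as.integer(schedule$volume), seq_len(nrow(schedule)))) {
    stop("schedule volumes must be consecutive starting at 1", call. = FALSE)
  }
  if (is.unsorted(schedule$block)) {
    stop("block index must be non-decreasing", call. = FALSE)
  }
  per_block <- tapply(schedule$condition, schedule$block,
                      function(x) length(unique(x)))
  if (any(per_block != 1)) {
    stop("volumes within one block must share a condition", call. = FALSE)
  }
  if (!inherits(schedule, "run_schedule")) {
    class(schedule) <- c("run_schedule", class(schedule))
  }
  invisible(schedule)
}

#' Composition of the moving correlation window
#'
#' Counts how many volumes of each condition fall inside the moving window
#' ending at volume `t`. The window covers volumes `t - L + 1` to `t`
#' inclusive: it contains the current volume, so at the first volume of an
#' fc-NF mini-block in the standard design the fc-NF:no-NF ratio is 1:19, at
#' the second 2:18, and at the last volume 20:0.
#'
#' @param schedule A `run_schedule`.
#' @param t Volume index at which the window ends (1-based).
#' @param L Window length in volumes.
#' @return A list of class `window_composition` with counts `n_fcnf`,
#'   `n_nonf`, `n_fixation` and the window length `L`.
#' @examples
#' sched <- build_run_schedule(20, 7, 20, 20, "fcnf")
#' window_composition(sched, t = 21, L = 20)$n_fcnf  # 1
#' window_composition(sched, t = 40, L = 20)$n_fcnf  # 20
#' @export
window_composition <- function(schedule, t, L = 20L) {
  validate_run_schedule(schedule)
  stopifnot(length(t) == 1, length(L) == 1, L >= 1)
  if (t > nrow(schedule)) stop("t beyond end of schedule", call. = FALSE)
  if (t < L) stop("window not yet filled", call. = FALSE)
  labels <- schedule$condition[(t - L + 1):t]
  out <- list(
    n_fcnf = sum(labels == "fcnf"),
    n_nonf = sum(labels == "nonf"),
    n_fixation = sum(labels == "fixation"),
    L = as.integer(L)
  )
  class(out) <- "window_composition"
  out
}

#' @export
print.window_composition <- function(x, ...) {
  cat(sprintf("window composition (L = %d): fc-NF %d, no-NF %d, fixation %d\n",
              x$L, x$n_fcnf, x$n_nonf, x$n_fixation))
  invisible(x)
}

#' Window composition at every defined volume
#'
#' Vectorised companion of [window_composition()]: per-condition counts of
#' the `L`-volume window ending at each volume `t >= L`.
#'
#' @inheritParams window_composition
#' @return A tibble with columns `volume`, `n_fcnf`, `n_nonf`, `n_fixation`,
#'   one row per volume from `L` to the run length.
#' @export
window_composition_all <- function(schedule, L = 20L) {
  validate_run_schedule(schedule)
  n <- nrow(schedule)
  if (n < L) stop("run shorter than the window", call. = FALSE)
  count_in_window <- function(lab) {
    ind <- cumsum(schedule$condition == lab)
    ind[L:n] - c(0L, ind)[(L:n) - L + 1L]
  }
  tibble::tibble(
    volume = L:n,
    n_fcnf = count_in_window("fcnf"),
    n_nonf = count_in_window("nonf"),
    n_fixation = count_in_window("fixation")
  )
}

#' Counterbalanced start-condition assignment
#'
#' Assigns each subject the condition of their first post-fixation mini-block
#' with an enforced 50/50 balance per cohort (the extra subject of an odd
#' cohort is assigned at random), as a seeded random permutation.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed; the assignment is reproducible given the seed.
#' @return Character vector of length `n_subjects` with values `"fcnf"` /
#'   `"nonf"`, balanced to within one subject.
#' @export
assign_start_conditions <- function(n_subjects, seed) {
  stopifnot(n_subjects >= 1)
  withr::with_seed(as.integer(seed), {
    half <- n_subjects %/% 2
    pool <- c(rep("fcnf", half), rep("nonf", half))
    if (n_subjects %% 2 == 1) pool <- c(pool, sample(c("fcnf", "nonf"), 1))
    sample(pool)
  })
}

#' Swap the fc-NF and no-NF labels of a schedule
#'
#' Exchanges the two mini-block labels volume by volume. With equal block
#' lengths this yields the opposite-start schedule; with unequal lengths it
#' does not preserve the per-condition block lengths — use
#' [alternate_start_schedule()] for counterbalancing.
#'
#' @param schedule A `run_schedule`.
#' @return The schedule with `fcnf` and `nonf` labels exchanged.
#' @export
flip_start_condition <- function(schedule) {
  validate_run_schedule(schedule)
  cond <- schedule$condition
  schedule$condition <- ifelse(cond == "fcnf", "nonf",
                               ifelse(cond == "nonf", "fcnf", cond))
  validate_run_schedule(schedule)
  schedule
}

#' Rebuild a schedule with the opposite start condition
#'
#' Recovers the design parameters (fixation length, pair count and the
#' per-condition mini-block lengths) from an alternating schedule and
#' rebuilds it starting with the other condition, preserving each
#' condition's block length. This is the counterbalancing operation for
#' designs with unequal fc-NF and no-NF block lengths.
#'
#' @param schedule A `run_schedule` built from alternating mini-block pairs.
#' @return The opposite-start `run_schedule`.
#' @export
alternate_start_schedule <- function(schedule) {
  validate_run_schedule(schedule)
  fixation_len <- sum(schedule$condition == "fixation")
  rl <- rle(schedule$condition[schedule$condition != "fixation"])
  if (length(unique(rl$lengths[rl$values == "fcnf"])) > 1 ||
      length(unique(rl$lengths[rl$values == "nonf"])) > 1) {
    stop("schedule is not an alternating fixed-length block design",
         call. = FALSE)
  }
  n_pairs <- sum(rl$values == "fcnf")
  if (n_pairs != sum(rl$values == "nonf")) {
    stop("schedule does not pair fc-NF and no-NF blocks", call. = FALSE)
  }
  other <- setdiff(c("fcnf", "nonf"), rl$values[1])
  build_run_schedule(fixation_len, n_pairs,
                     rl$lengths[rl$values == "fcnf"][1],
                     rl$lengths[rl$values == "nonf"][1],
                     other)
}

#' Write / read a schedule as a two-column tab-separated table
#'
#' The on-disk dialect is the minimal (volume, condition) table; block
#' structure is recovered on read from label changes, so the round trip is
#' lossless for schedules built from contiguous blocks.
#'
#' @param schedule A `run_schedule`.
#' @param path File path.
#' @return `write_schedule_tsv()` returns `path` invisibly;
#'   `read_schedule_tsv()` returns a `run_schedule`.
#' @export
write_schedule_tsv <- function(schedule, path) {
  validate_run_schedule(schedule)
  readr::write_tsv(schedule[, c("volume", "condition")], path)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    volume = readr::col_integer(), condition = readr::col_character()
  ))
  schedule_from_labels(tab$condition)
}

#' Rebuild a schedule from its per-volume labels
#'
#' @param labels Character vector of per-volume condition labels.
#' @return A `run_schedule` with blocks inferred from label changes.
#' @export
schedule_from_labels <- function(labels) {
  stopifnot(length(labels) >= 1, all(labels %in% .conditions))
  block <- cumsum(c(TRUE, labels[-1] != labels[-length(labels)]))
  block_pos <- stats::ave(seq_along(labels), block, FUN = seq_along)
  sched <- tibble::tibble(
    volume = seq_along(labels),
    condition = labels,
    block = as.integer(block),
    block_pos = as.integer(block_pos)
  )
  class(sched) <- c("run_schedule", class(sched))
  validate_run_schedule(sched)
  sched
}

#' Write / read a schedule as a compact JSON block list
#'
#' Each block is stored as `{"condition": ..., "length": ...}`; the dialect
#' round-trips losslessly with the tab-separated form.
#'
#' @inheritParams write_schedule_tsv
#' @export
write_schedule_json <- function(schedule, path) {
  validate_run_schedule(schedule)
  rl <- rle(schedule$condition)
  blocks <- data.frame(condition = rl$values, length = rl$lengths)
  jsonlite::write_json(list(blocks = blocks), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  blocks <- obj$blocks
  schedule_from_labels(rep(blocks$condition, blocks$length))
}
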
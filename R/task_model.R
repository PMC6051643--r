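## Task structure: the motor gamble offers participants face, the 42-trial
## schedule, expected values, screen binning, and empirical success-rate
## estimation.

#' The six value combinations of the motor gambling task
#'
#' Reward trials: skip for a certain +10, or gamble for 20/60/100 on motor
#' success (0 on failure). Punishment trials: skip for a certain -10, or gamble
#' to avoid loss (0 on success, -20/-60/-100 on failure).
#'
#' @return A data frame with columns `domain`, `certain_value`,
#'   `success_value`, `fail_value` (6 rows).
#' @export
value_combinations <- function() {
  data.frame(
    domain        = rep(c("reward", "punishment"), each = 3L),
    certain_value = rep(c(10, -10), each = 3L),
    success_value = c(20, 60, 100, 0, 0, 0),
    fail_value    = c(0, 0, 0, -20, -60, -100),
    stringsAsFactors = FALSE
  )
}

#' Build one participant's 42-trial schedule
#'
#' Six value combinations crossed with seven target-size levels (level 1
#' largest/easiest). Trials are arranged in 7 blocks of 6: blocks 1-3 present
#' the three largest targets (one level per block, levels 1-3 permuted at
#' random across those blocks), blocks 4-6 present levels 4-6 likewise, and
#' block 7 the smallest target. Within a block the six value combinations
#' appear once each in random order. A uniform trajectory angle in [0, 360)
#' degrees is attached to every trial.
#'
#' @param seed Integer RNG seed; the schedule is deterministic given the seed.
#' @return A data frame with 42 rows and columns `block`, `target_level`,
#'   `domain`, `certain_value`, `success_value`, `fail_value`,
#'   `trajectory_angle`.
#' @export
build_schedule <- function(seed) {
  combos <- value_combinations()
  with_seed(seed, {
    levels_by_block <- c(sample(1:3), sample(4:6), 7L)
    rows <- lapply(seq_len(7L), function(b) {
      blk <- combos[sample.int(6L), , drop = FALSE]
      blk$block <- b
      blk$target_level <- levels_by_block[b]
      blk
    })
    out <- do.call(rbind, rows)
    out$trajectory_angle <- stats::runif(nrow(out), 0, 360)
  })
  rownames(out) <- NULL
  out[, c("block", "target_level", "domain", "certain_value",
          "success_value", "fail_value", "trajectory_angle")]
}

#' Expected values of a gamble offer
#'
#' `EV_gamble = p * O1 + (1 - p) * O2`; the certain option's expected value is
#' its outcome `Oc` (received with probability 1).
#'
#' @param p Success probability (vectorised).
#' @param O1,O2 Gamble outcomes on success / failure (points).
#' @param Oc Certain outcome (points).
#' @return A data frame with columns `ev_gamble`, `ev_certain`.
#' @export
expected_values <- function(p, O1, O2, Oc) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  data.frame(ev_gamble = p * O1 + (1 - p) * O2, ev_certain = Oc)
}

#' Bin a device screen size to the nearest standard bin centre
#'
#' Bin centres are 4, 6, 8 and 10 inches; exact midpoints are assigned to the
#' smaller bin.
#'
#' @param inches Positive screen diagonal in inches (vectorised).
#' @return Integer vector of bin centres.
#' @export
bin_screen <- function(inches) {
  if (any(!is.finite(inches) | inches <= 0)) {
    stop("screen size must be a positive number of inches")
  }
  centres <- c(4L, 6L, 8L, 10L)
  idx <- vapply(inches, function(x) {
    d <- abs(centres - x)
    which(d == min(d))[1L]  # ties -> smaller centre
  }, integer(1))
  centres[idx]
}

#' Estimate motor success probabilities from observed gambled trials
#'
#' In `"group"` mode the success probability for a cell is the average motor
#' success over all gambled trials of all participants sharing the same age
#' group, screen-size bin and target level. In `"individual"` mode rates are
#' estimated per (participant, target level) from that participant's own
#' gambled trials only. Cells with no gambled trials are absent from the
#' table (missing, never zero); lookups against them yield `NA`.
#'
#' @param trials Trial-by-trial data frame (see [read_trials()] for the
#'   schema); only rows with `choice == 1` and a recorded `motor_success`
#'   contribute.
#' @param mode `"group"` or `"individual"`.
#' @return A data frame of class `success_table` with columns `age_group`,
#'   `screen_bin`, `target_level`, `rate`, `n` (group mode) or
#'   `participant_id`, `target_level`, `rate`, `n` (individual mode).
#' @export
estimate_success_table <- function(trials, mode = c("group", "individual")) {
  mode <- match.arg(mode)
  g <- trials[trials$choice == 1 & !is.na(trials$motor_success), , drop = FALSE]
  if (nrow(g) == 0L) stop("no gambled trials with recorded motor success")
  if (mode == "group") {
    g$screen_bin <- bin_screen(g$screen_inches)
    tab <- stats::aggregate(
      motor_success ~ age_group + screen_bin + target_level,
      data = g, FUN = mean
    )
    cnt <- stats::aggregate(
      motor_success ~ age_group + screen_bin + target_level,
      data = g, FUN = length
    )
    tab$n <- cnt$motor_success
  } else {
    tab <- stats::aggregate(motor_success ~ participant_id + target_level,
                            data = g, FUN = mean)
    cnt <- stats::aggregate(motor_success ~ participant_id + target_level,
                            data = g, FUN = length)
    tab$n <- cnt$motor_success
  }
  names(tab)[names(tab) == "motor_success"] <- "rate"
  attr(tab, "mode") <- mode
  class(tab) <- c("success_table", class(tab))
  tab
}

#' Look up success probabilities for a set of trials
#'
#' @param table A `success_table` (from [estimate_success_table()] or
#'   [sample_success_surface()]).
#' @param trials Trial rows carrying `age_group`, `screen_inches` (group mode)
#'   or `participant_id` (individual mode) and `target_level`.
#' @return Numeric vector of success probabilities, `NA` where the table has
#'   no matching cell.
#' @export
lookup_success <- function(table, trials) {
  mode <- attr(table, "mode") %||% "group"
  if (mode == "group") {
    key_t <- paste(table$age_group, table$screen_bin, table$target_level)
    key_q <- paste(trials$age_group, bin_screen(trials$screen_inches),
                   trials$target_level)
  } else {
    key_t <- paste(table$participant_id, table$target_level)
    key_q <- paste(trials$participant_id, trials$target_level)
  }
  table$rate[match(key_q, key_t)]
}

#' Read / write the trial-by-trial CSV table
#'
#' One row per trial with columns `participant_id`, `age_group`, `gender`,
#' `education`, `screen_inches`, `block`, `target_level`, `domain`,
#' `certain_value`, `success_value`, `fail_value`, `choice`, `motor_success`,
#' `points_delta`. `motor_success` is empty on skipped trials.
#'
#' @param path File path.
#' @return `read_trials()` returns the data frame; `write_trials()` invisibly
#'   returns `path`.
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_trials
#' @param trials Trial table to write.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_trials
#' @param table Success table to write (group mode).
#' @export
write_success_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
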
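# Task engine: schedules, outcome realization, point tally and top-up phase.

#' Sample correct categories under the task's 80/20 law
#'
#' Stimuli S1 and S3 belong to category A with probability 0.8 (B with 0.2);
#' S2 and S4 belong to category A with probability 0.2.
#'
#' @param stimulus character vector of stimulus labels (`"S1"`..`"S4"`).
#' @param seed optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return character vector of `"A"`/`"B"` category assignments.
#' @export
sample_category <- function(stimulus, seed = NULL) {
  stopifnot(all(stimulus %in% STIMULI))
  draw <- function() {
    p <- P_CATEGORY_A[stimulus]
    ifelse(runif(length(stimulus)) < p, "A", "B")
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Build a task schedule
#'
#' Generates the 160-trial training schedule: four blocks of 40 trials.  In
#' the intermixed condition each of the four stimuli appears 10 times per
#' block.  In the separated conditions the first-trained stimulus pair fills
#' blocks 1-2 (20 appearances per stimulus per block) and the other pair
#' fills blocks 3-4; `reward_first` trains S1/S2 first, `punish_first`
#' trains S3/S4 first.  Within-block order is a seeded uniform shuffle and
#' the correct category of every trial is sampled i.i.d. from the stimulus's
#' 80/20 law.
#'
#' @param condition `"intermixed"`, `"reward_first"` or `"punish_first"`.
#' @param seed non-negative integer seed; identical `(condition, seed)` give
#'   bit-identical schedules.
#' @param n_repeats number of 160-trial cycles to concatenate (default 1).
#'   Values above 1 produce extended schedules (blocks numbered past 4) used
#'   for parameter-recovery experiments; the standard session is 1.
#' @return a `trial_schedule` data.frame with columns `index` (0-based),
#'   `block`, `stimulus`, `trial_type`, `correct_category`, `is_topup`.
#' @export
build_schedule <- function(condition, seed, n_repeats = 1L) {
  condition <- match.arg(condition, CONDITIONS)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(n_repeats), n_repeats >= 1)
  n_repeats <- as.integer(n_repeats)

  block_stimuli <- function(block) {
    switch(condition,
      intermixed   = rep(STIMULI, each = 10L),
      reward_first = if (block %in% c(1L, 2L)) rep(c("S1", "S2"), each = 20L)
                     else rep(c("S3", "S4"), each = 20L),
      punish_first = if (block %in% c(1L, 2L)) rep(c("S3", "S4"), each = 20L)
                     else rep(c("S1", "S2"), each = 20L))
  }

  sched <- withr::with_seed(as.integer(seed), {
    blocks <- seq_len(4L * n_repeats)
    stim <- unlist(lapply(blocks, function(b) {
      base_block <- ((b - 1L) %% 4L) + 1L
      sample(block_stimuli(base_block))
    }))
    data.frame(
      index = seq_along(stim) - 1L,
      block = rep(blocks, each = 40L),
      stimulus = stim,
      trial_type = unname(TRIAL_TYPE_MAP[stim]),
      correct_category = ifelse(runif(length(stim)) < P_CATEGORY_A[stim],
                                "A", "B"),
      is_topup = FALSE,
      stringsAsFactors = FALSE
    )
  })
  structure(sched, class = c("trial_schedule", "data.frame"),
            condition = condition, seed = as.integer(seed))
}

#' Realize the outcome of a single trial
#'
#' Reward-type trials (S1/S2) pay +25 points when the response matches the
#' trial's correct category and give no feedback otherwise; punishment-type
#' trials (S3/S4) cost 25 points when the response does not match and give
#' no feedback otherwise.
#'
#' @param trial one-row data.frame (or list) with `trial_type` and
#'   `correct_category`.
#' @param response `"A"` or `"B"`.
#' @return list with `outcome` (`"reward"`, `"punishment"` or `"none"`) and
#'   `points_delta` (+25, -25 or 0).
#' @export
realize_outcome <- function(trial, response) {
  stopifnot(response %in% RESPONSES)
  correct <- response == trial$correct_category
  if (trial$trial_type == "reward") {
    if (correct) list(outcome = "reward", points_delta = 25L)
    else list(outcome = "none", points_delta = 0L)
  } else {
    if (!correct) list(outcome = "punishment", points_delta = -25L)
    else list(outcome = "none", points_delta = 0L)
  }
}

# Vectorized outcome realization used by the session builders.
realize_outcomes_vec <- function(trial_type, correct_category, response) {
  correct <- response == correct_category
  outcome <- ifelse(trial_type == "reward",
                    ifelse(correct, "reward", "none"),
                    ifelse(correct, "none", "punishment"))
  delta <- ifelse(outcome == "reward", 25L, ifelse(outcome == "punishment",
                                                   -25L, 0L))
  list(outcome = outcome, points_delta = as.integer(delta))
}

new_session_record <- function(df, condition) {
  structure(df, class = c("session_record", "data.frame"),
            condition = condition)
}

#' Running point tally of a session
#'
#' The tally starts at 500 points and moves by the per-trial point deltas.
#'
#' @param record a `session_record`.
#' @return integer vector, one entry per trial (after that trial's outcome).
#' @export
tally_trajectory <- function(record) {
  POINTS_START + cumsum(as.integer(record$points_delta))
}

#' Append top-up trials to a below-start session
#'
#' If the tally after the 160 main trials has fallen below the 500-point
#' start, additional reward-type trials with S1 and S2 are appended until the
#' tally reaches 525 points.  Top-up trials are flagged `is_topup = TRUE` and
#' excluded by every downstream fitting and metric operation.
#'
#' @param record a `session_record` with 160 main trials.
#' @param responder function mapping a one-row trial data.frame to `"A"` or
#'   `"B"` (see [optimal_responder()]).
#' @param seed integer seed for the top-up category draws and stimulus picks.
#' @param max_topup iteration cap; a responder that never earns points makes
#'   the phase non-convergent and raises an error at this cap.
#' @return the (possibly extended) `session_record`.
#' @export
apply_topup <- function(record, responder, seed, max_topup = 1000L) {
  stopifnot(inherits(record, "session_record"))
  main <- record[!record$is_topup, , drop = FALSE]
  stopifnot(nrow(main) == 160L)
  tally <- POINTS_START + sum(as.integer(record$points_delta))
  if (tally >= POINTS_START) return(record)

  extra <- withr::with_seed(as.integer(seed), {
    rows <- vector("list", 0L)
    idx <- max(record$index)
    n_added <- 0L
    while (tally < TOPUP_TARGET) {
      if (n_added >= max_topup) {
        stop("top-up phase did not converge within ", max_topup,
             " appended trials (responder never earns points)")
      }
      idx <- idx + 1L
      stim <- sample(c("S1", "S2"), 1L)
      trial <- data.frame(
        index = idx, block = NA_integer_, stimulus = stim,
        trial_type = "reward",
        correct_category = if (runif(1L) < P_CATEGORY_A[[stim]]) "A" else "B",
        is_topup = TRUE, stringsAsFactors = FALSE)
      resp <- responder(trial)
      out <- realize_outcome(trial, resp)
      trial$response <- resp
      trial$outcome <- out$outcome
      trial$points_delta <- out$points_delta
      tally <- tally + out$points_delta
      n_added <- n_added + 1L
      rows[[n_added]] <- trial
    }
    do.call(rbind, rows)
  })
  if (!is.null(extra) && nrow(extra)) {
    for (col in setdiff(names(record), names(extra))) {
      fill <- if (col %in% c("subject_id", "condition")) record[[col]][1L]
              else record[[col]][NA_integer_]
      extra[[col]] <- rep(fill, nrow(extra))
    }
    extra <- extra[, names(record), drop = FALSE]
    out <- rbind(as.data.frame(record), extra)
  } else {
    out <- as.data.frame(record)
  }
  new_session_record(out, attr(record, "condition"))
}

#' Always-optimal responder
#'
#' Responds `"A"` to S1/S3 and `"B"` to S2/S4 on every trial.
#'
#' @return a responder function for [apply_topup()].
#' @export
optimal_responder <- function() {
  function(trial) unname(OPTIMAL_MAP[[trial$stimulus]])
}

#' Uniform random responder
#' @return a responder function choosing `"A"`/`"B"` with probability 0.5.
#' @export
random_responder <- function() {
  function(trial) sample(RESPONSES, 1L)
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> condition=%s, %d trials, seed=%s\n",
              attr(x, "condition"), nrow(x), attr(x, "seed")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' @export
print.session_record <- function(x, ...) {
  n_main <- sum(!x$is_topup)
  tally <- POINTS_START + sum(as.integer(x$points_delta))
  cat(sprintf(
    "<session_record> condition=%s, %d main + %d top-up trials, final tally=%d\n",
    attr(x, "condition"), n_main, sum(x$is_topup), tally))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
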
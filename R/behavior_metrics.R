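# Model-free behavioral summaries: percent optimal responding, win-stay /
# lose-shift transitions tracked per stimulus, performance bias and R0 bias.

main_trials <- function(record) {
  df <- as.data.frame(record)
  if ("is_topup" %in% names(df)) df <- df[!df$is_topup, , drop = FALSE]
  df
}

is_optimal_response <- function(stimulus, response) {
  response == unname(OPTIMAL_MAP[stimulus])
}

#' Percent optimal responding
#'
#' A response is optimal when it matches the fixed optimal map (A for S1/S3,
#' B for S2/S4), regardless of the realized outcome.  Strata with no trials
#' are reported as missing (`NA`), not 0.
#'
#' @param record a `session_record` (top-up trials excluded).
#' @param by_block stratify by training block.
#' @param by_type stratify by trial type (reward vs punishment).
#' @return data.frame with the stratifiers, `n_trials` and `percent_optimal`
#'   (0-100).
#' @export
percent_optimal <- function(record, by_block = TRUE, by_type = TRUE) {
  df <- main_trials(record)
  df$optimal <- is_optimal_response(df$stimulus, df$response)
  strata <- list()
  if (by_block) strata$block <- sort(unique(df$block))
  if (by_type) strata$trial_type <- c("reward", "punishment")
  if (!length(strata)) {
    return(data.frame(n_trials = nrow(df),
                      percent_optimal = 100 * mean(df$optimal)))
  }
  cells <- expand.grid(strata, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells$n_trials <- NA_integer_
  cells$percent_optimal <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(df))
    if (by_block) sel <- sel & df$block == cells$block[i]
    if (by_type) sel <- sel & df$trial_type == cells$trial_type[i]
    cells$n_trials[i] <- sum(sel)
    if (any(sel)) cells$percent_optimal[i] <- 100 * mean(df$optimal[sel])
  }
  cells
}

#' Win-stay and lose-shift behavior
#'
#' Transitions are computed per stimulus: the relevant "prior trial" is the
#' previous trial *with that stimulus*, not the globally previous trial.
#' A win event is a reward or a no-feedback outcome on a punishment-type
#' trial (avoided punishment); a lose event is a punishment or a no-feedback
#' outcome on a reward-type trial (missed reward).  Win-stay counts repeats
#' of the prior response after win events; lose-shift counts switches after
#' lose events.  Events on a stimulus's last trial have no successor and are
#' not opportunities.
#'
#' @param record a `session_record` (top-up trials excluded).
#' @return data.frame, one row per trial type, with win-stay / lose-shift
#'   counts, opportunity counts and rates (`NA` when no opportunities).
#' @export
win_stay_lose_shift <- function(record) {
  df <- main_trials(record)
  acc <- data.frame(trial_type = c("reward", "punishment"),
                    win_stay = 0L, win_opportunities = 0L,
                    lose_shift = 0L, lose_opportunities = 0L,
                    stringsAsFactors = FALSE)
  for (stim in unique(df$stimulus)) {
    sub <- df[df$stimulus == stim, , drop = FALSE]
    if (nrow(sub) < 2L) next
    type <- unname(TRIAL_TYPE_MAP[[stim]])
    row <- which(acc$trial_type == type)
    prior_out <- sub$outcome[-nrow(sub)]
    prior_type <- sub$trial_type[-nrow(sub)]
    prior_resp <- sub$response[-nrow(sub)]
    next_resp <- sub$response[-1L]
    win <- prior_out == "reward" |
      (prior_out == "none" & prior_type == "punishment")
    lose <- prior_out == "punishment" |
      (prior_out == "none" & prior_type == "reward")
    stay <- next_resp == prior_resp
    acc$win_opportunities[row] <- acc$win_opportunities[row] + sum(win)
    acc$win_stay[row] <- acc$win_stay[row] + sum(win & stay)
    acc$lose_opportunities[row] <- acc$lose_opportunities[row] + sum(lose)
    acc$lose_shift[row] <- acc$lose_shift[row] + sum(lose & !stay)
  }
  acc$win_stay_rate <- ifelse(acc$win_opportunities > 0,
                              acc$win_stay / acc$win_opportunities, NA_real_)
  acc$lose_shift_rate <- ifelse(acc$lose_opportunities > 0,
                                acc$lose_shift / acc$lose_opportunities,
                                NA_real_)
  acc
}

#' Performance bias
#'
#' Difference (in percentage points) between percent optimal on reward-based
#' and punishment-based trials in the final training block: positive means
#' better reward learning, negative better punishment learning.  For the
#' separated conditions block 4 lacks one trial type, so each type's final
#' *trained* block is used (blocks 2 and 4 as appropriate) and the result is
#' labeled `"separated_final_blocks"` to avoid conflation.
#'
#' @param record a `session_record`.
#' @return one-row data.frame with `bias`, `reward_pct`, `punishment_pct`,
#'   `definition` and the blocks used.
#' @export
performance_bias <- function(record) {
  df <- main_trials(record)
  condition <- attr(record, "condition") %||%
    (if ("condition" %in% names(df)) df$condition[1L] else "intermixed")
  separated <- condition %in% c("reward_first", "punish_first")
  final_block <- function(type) {
    blocks <- df$block[df$trial_type == type]
    if (!length(blocks)) return(NA_integer_)
    max(blocks)
  }
  b_rew <- final_block("reward")
  b_pun <- final_block("punishment")
  pct <- function(type, blk) {
    if (is.na(blk)) return(NA_real_)
    sel <- df$trial_type == type & df$block == blk
    if (!any(sel)) return(NA_real_)
    100 * mean(is_optimal_response(df$stimulus[sel], df$response[sel]))
  }
  if (!separated) b_rew <- b_pun <- max(df$block)
  p_r <- pct("reward", b_rew)
  p_p <- pct("punishment", b_pun)
  data.frame(bias = p_r - p_p, reward_pct = p_r, punishment_pct = p_p,
             reward_block = b_rew, punishment_block = b_pun,
             definition = if (separated) "separated_final_blocks"
             else "final_block", stringsAsFactors = FALSE)
}

#' R0 bias of a fitted subject
#'
#' The difference between the fitted values of the no-feedback outcome on
#' reward-based and punishment-based trials, `r0_rew - r0_pun`, in `[-2, 2]`.
#'
#' @param fit a `fit_result` (or any list/row with `r0_rew` and `r0_pun`,
#'   e.g. one row of a [fit_cohort()] table).
#' @return numeric difference.
#' @export
r0_bias <- function(fit) {
  p <- if (inherits(fit, "fit_result")) fit$params else fit
  if (is.null(p$r0_rew) || is.null(p$r0_pun) ||
      is.na(p$r0_rew) || is.na(p$r0_pun))
    stop("fit does not define both r0_rew and r0_pun")
  p$r0_rew - p$r0_pun
}

#' Behavioral summary of one subject
#'
#' Bundles [percent_optimal()], [win_stay_lose_shift()] and
#' [performance_bias()] into a single flat row, the per-subject unit of the
#' cohort-level metric tables.
#'
#' @param record a `session_record`.
#' @return one-row data.frame.
#' @export
behavior_summary <- function(record) {
  df <- main_trials(record)
  id <- if ("subject_id" %in% names(df)) df$subject_id[1L] else NA_character_
  wsls <- win_stay_lose_shift(record)
  bias <- performance_bias(record)
  overall <- percent_optimal(record, by_block = FALSE, by_type = TRUE)
  row <- data.frame(subject_id = id, stringsAsFactors = FALSE)
  for (type in c("reward", "punishment")) {
    w <- wsls[wsls$trial_type == type, ]
    o <- overall[overall$trial_type == type, ]
    row[[paste0("pct_optimal_", type)]] <- o$percent_optimal
    row[[paste0("win_stay_", type)]] <- w$win_stay
    row[[paste0("win_stay_rate_", type)]] <- w$win_stay_rate
    row[[paste0("lose_shift_", type)]] <- w$lose_shift
    row[[paste0("lose_shift_rate_", type)]] <- w$lose_shift_rate
  }
  row$performance_bias <- bias$bias
  row$bias_definition <- bias$definition
  row
}
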
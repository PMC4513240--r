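# Gain-loss Q-learning observation model: softmax choice rule, outcome
# valuation (including the free-valued no-feedback outcome), prediction-error
# update, and the sequential choice likelihood.  This file is the single
# implementation of the model; the synthetic agents and the grid search both
# call into it (or into the C++ mirror checked against it).

#' Construct a parameter vector for a model variant
#'
#' Five nested variants of the gain-loss Q-learning model:
#' \describe{
#'   \item{`five_param`}{LR+, LR-, beta, R0rew, R0pun all free (k = 5).}
#'   \item{`r0_shared`}{one shared R0 = R0rew = R0pun (k = 4).}
#'   \item{`r0_inv`}{R0rew free, R0pun = -R0rew (k = 4).}
#'   \item{`r0_zero`}{R0rew = R0pun = 0 (k = 3).}
#'   \item{`single_lr`}{LR+ = LR-, R0 fixed at 0 (k = 2).}
#' }
#' Constraints are applied (a constrained field may be omitted) and checked
#' when supplied explicitly.
#'
#' @param variant one of the five variant names.
#' @param lr_plus learning rate for positive prediction errors, in `[0, 1]`.
#' @param lr_minus learning rate for negative prediction errors, in `[0, 1]`.
#' @param beta softmax temperature in `[0, 1]`; 0 is the argmax limit.
#' @param r0_rew value of the no-feedback outcome on reward-type trials, in
#'   `[-1, 1]`.
#' @param r0_pun value of the no-feedback outcome on punishment-type trials.
#' @return a `param_vector` list with fields `variant`, `lr_plus`, `lr_minus`,
#'   `beta`, `r0_rew`, `r0_pun` and `k` (number of free parameters).
#' @export
param_vector <- function(variant, lr_plus, lr_minus = NULL, beta = 0.1,
                         r0_rew = NULL, r0_pun = NULL) {
  variant <- match.arg(variant, VARIANTS)
  if (variant == "single_lr") {
    if (is.null(lr_minus)) lr_minus <- lr_plus
    if (lr_plus != lr_minus)
      stop("single_lr requires lr_plus == lr_minus")
    if (!is.null(r0_rew) && r0_rew != 0 || !is.null(r0_pun) && r0_pun != 0)
      stop("single_lr fixes r0_rew = r0_pun = 0")
    r0_rew <- r0_pun <- 0
  }
  if (is.null(lr_minus)) stop("lr_minus must be supplied for variant ", variant)
  switch(variant,
    five_param = {
      if (is.null(r0_rew) || is.null(r0_pun))
        stop("five_param requires r0_rew and r0_pun")
    },
    r0_shared = {
      if (is.null(r0_rew) && is.null(r0_pun))
        stop("r0_shared requires an R0 value")
      if (is.null(r0_rew)) r0_rew <- r0_pun
      if (is.null(r0_pun)) r0_pun <- r0_rew
      if (r0_rew != r0_pun) stop("r0_shared requires r0_rew == r0_pun")
    },
    r0_inv = {
      if (is.null(r0_rew) && is.null(r0_pun))
        stop("r0_inv requires an R0rew value")
      if (is.null(r0_rew)) r0_rew <- -r0_pun
      if (is.null(r0_pun)) r0_pun <- -r0_rew
      if (r0_rew != -r0_pun) stop("r0_inv requires r0_rew == -r0_pun")
    },
    r0_zero = {
      if (!is.null(r0_rew) && r0_rew != 0 || !is.null(r0_pun) && r0_pun != 0)
        stop("r0_zero fixes r0_rew = r0_pun = 0")
      r0_rew <- r0_pun <- 0
    },
    single_lr = NULL)
  vals <- c(lr_plus = lr_plus, lr_minus = lr_minus, beta = beta,
            r0_rew = r0_rew, r0_pun = r0_pun)
  if (any(vals[c("lr_plus", "lr_minus", "beta")] < 0 |
          vals[c("lr_plus", "lr_minus", "beta")] > 1))
    stop("learning rates and beta must lie in [0, 1]")
  if (any(abs(vals[c("r0_rew", "r0_pun")]) > 1))
    stop("R0 values must lie in [-1, 1]")
  structure(list(variant = variant, lr_plus = lr_plus, lr_minus = lr_minus,
                 beta = beta, r0_rew = r0_rew, r0_pun = r0_pun,
                 k = n_free_params(variant)),
            class = "param_vector")
}

#' Number of free parameters of a model variant
#' @param variant variant name.
#' @return integer: 5, 4, 4, 3 or 2.
#' @export
n_free_params <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  c(five_param = 5L, r0_shared = 4L, r0_inv = 4L, r0_zero = 3L,
    single_lr = 2L)[[variant]]
}

#' @export
print.param_vector <- function(x, ...) {
  cat(sprintf(
    "<param_vector> %s (k=%d): LR+=%.3g LR-=%.3g beta=%.3g R0rew=%.3g R0pun=%.3g\n",
    x$variant, x$k, x$lr_plus, x$lr_minus, x$beta, x$r0_rew, x$r0_pun))
  invisible(x)
}

#' Softmax probability of choosing response A
#'
#' `Pr(A) = exp(q_a/beta) / (exp(q_a/beta) + exp(q_b/beta))`, evaluated in a
#' numerically stable form.  `beta = 0` is taken as the argmax limit: 1 when
#' `q_a > q_b`, 0 when `q_a < q_b`, 0.5 on a tie.
#'
#' @param q_a,q_b action values of responses A and B.
#' @param beta softmax temperature, `>= 0`.
#' @return probability of response A; `Pr(B) = 1 - Pr(A)`.
#' @export
choice_probability <- function(q_a, q_b, beta) {
  if (beta < 0) stop("beta must be >= 0")
  if (beta == 0) {
    return(ifelse(q_a > q_b, 1, ifelse(q_a < q_b, 0, 0.5)))
  }
  stats::plogis((q_a - q_b) / beta)
}

#' Value of a trial outcome
#'
#' Reward feedback is worth +1, punishment feedback -1, and the ambiguous
#' no-feedback outcome is worth `r0_rew` on reward-type trials (a missed
#' reward) or `r0_pun` on punishment-type trials (an avoided punishment).
#'
#' @param outcome `"reward"`, `"punishment"` or `"none"`.
#' @param trial_type `"reward"` or `"punishment"`.
#' @param params a `param_vector`.
#' @return scalar outcome value R(t) in `[-1, 1]`.
#' @export
outcome_value <- function(outcome, trial_type, params) {
  switch(outcome,
    reward = 1,
    punishment = -1,
    none = if (trial_type == "reward") params$r0_rew else params$r0_pun,
    stop("unknown outcome code: ", outcome))
}

#' Prediction error
#' @param R outcome value R(t).
#' @param q_chosen current Q-value of the chosen (stimulus, response) pair.
#' @return `R - q_chosen`.
#' @export
prediction_error <- function(R, q_chosen) R - q_chosen

#' Update the chosen action value
#'
#' `q <- q + a * PE`, with learning rate `a = lr_plus` when PE > 0 and
#' `a = lr_minus` when PE < 0.  A zero prediction error leaves the value
#' unchanged (neither rate is defined for PE = 0, and any choice would be
#' observationally identical).
#'
#' @param q_chosen current Q-value of the chosen pair; only this cell changes.
#' @param PE prediction error.
#' @param params a `param_vector`.
#' @return updated Q-value.
#' @export
q_update <- function(q_chosen, PE, params) {
  if (PE > 0) q_chosen + params$lr_plus * PE
  else if (PE < 0) q_chosen + params$lr_minus * PE
  else q_chosen
}

window_rows <- function(n, window) {
  window <- match.arg(window, WINDOWS)
  switch(window,
    all = seq_len(n),
    first80 = seq_len(min(80L, n)),
    last80 = if (n <= 80L) seq_len(n) else (n - 79L):n)
}

#' Negative log likelihood of a recorded session
#'
#' Reconstructs the Q-state trajectory over the scored window (Q initialized
#' to 0 at the window start), scoring the probability of each observed
#' response from the pre-trial state before applying that trial's update.
#' Top-up trials are never scored.  If any scored probability is exactly 0
#' (possible only at `beta = 0`), the negLLE is `+Inf`.
#'
#' @param record a `session_record` (or trial data.frame with `stimulus`,
#'   `trial_type`, `response`, `outcome`, `is_topup` columns).
#' @param params a `param_vector`.
#' @param window `"all"`, `"first80"` or `"last80"` (positions among the
#'   non-top-up trials).
#' @return a `likelihood_trace`: per-trial table (`p_obs`, `R`, `PE`), total
#'   `negLLE`, `n` trials scored, plus the parameters and window.
#' @export
neg_log_likelihood <- function(record, params, window = "all") {
  stopifnot(inherits(params, "param_vector"))
  df <- as.data.frame(record)
  need <- c("stimulus", "trial_type", "response", "outcome")
  if (!all(need %in% names(df)))
    stop("record lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if ("is_topup" %in% names(df)) df <- df[!df$is_topup, , drop = FALSE]
  if (!all(df$stimulus %in% STIMULI)) stop("unknown stimulus codes in record")
  if (!all(df$outcome %in% OUTCOMES)) stop("unknown outcome codes in record")
  if (!all(df$response %in% RESPONSES)) stop("unknown response codes in record")
  df <- df[window_rows(nrow(df), window), , drop = FALSE]
  n <- nrow(df)
  if (n == 0L) stop("empty scoring window")

  q <- matrix(0, nrow = 4L, ncol = 2L,
              dimnames = list(STIMULI, RESPONSES))
  p_obs <- R_t <- PE_t <- numeric(n)
  for (t in seq_len(n)) {
    s <- df$stimulus[t]
    r <- df$response[t]
    pA <- choice_probability(q[s, "A"], q[s, "B"], params$beta)
    p_obs[t] <- if (r == "A") pA else 1 - pA
    R <- outcome_value(df$outcome[t], df$trial_type[t], params)
    PE <- prediction_error(R, q[s, r])
    q[s, r] <- q_update(q[s, r], PE, params)
    R_t[t] <- R
    PE_t[t] <- PE
  }
  negll <- if (any(p_obs == 0)) Inf else -sum(log(p_obs))
  structure(list(
    trials = data.frame(index = if ("index" %in% names(df)) df$index
                        else seq_len(n) - 1L,
                        stimulus = df$stimulus, response = df$response,
                        outcome = df$outcome, p_obs = p_obs, R = R_t,
                        PE = PE_t, stringsAsFactors = FALSE),
    negLLE = negll, n = n, params = params, window = window,
    q_final = q), class = "likelihood_trace")
}

#' @export
print.likelihood_trace <- function(x, ...) {
  cat(sprintf("<likelihood_trace> negLLE=%.4f over n=%d trials (%s window), p(choice)=%.4f\n",
              x$negLLE, x$n, x$window, p_choice(x$negLLE, x$n)))
  invisible(x)
}

#' Geometric-mean per-trial choice probability
#'
#' `p(choice) = exp(-negLLE/n)`; 0.5 is chance for a binary choice and 1
#' means perfect replication of the observed choices.
#'
#' @param negLLE total negative log likelihood (`>= 0`, may be `Inf`).
#' @param n number of trials scored, `>= 1`.
#' @return probability in `(0, 1]` (0 when `negLLE` is infinite).
#' @export
p_choice <- function(negLLE, n) {
  if (n < 1) stop("n must be >= 1")
  if (is.infinite(negLLE)) return(0)
  exp(-negLLE / n)
}
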
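# Synthetic subjects: Q-learning agents driven by the shared observation
# model (one implementation, two call sites) and degenerate responders used
# for the "theoretically optimal performance" simulation.

#' Specify a synthetic agent
#'
#' @param kind `"qlearner"` (choices sampled from the softmax over learned
#'   Q-values), `"optimal"` (always the optimal response), `"epsilon_optimal"`
#'   (optimal with probability `1 - epsilon`) or `"random"` (0.5/0.5).
#' @param params a [param_vector()]; required for `kind = "qlearner"`.
#' @param epsilon probability of a non-optimal response for
#'   `"epsilon_optimal"`, in `[0, 1]`; default 0.05 ("nearly always" optimal).
#' @return an `agent_spec`.
#' @export
agent <- function(kind = c("qlearner", "optimal", "epsilon_optimal", "random"),
                  params = NULL, epsilon = 0.05) {
  kind <- match.arg(kind)
  if (kind == "qlearner") {
    if (!inherits(params, "param_vector"))
      stop("qlearner agents require a param_vector")
  }
  if (kind == "optimal") epsilon <- 0
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  structure(list(kind = kind, params = params, epsilon = epsilon),
            class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf("<agent_spec> kind=%s", x$kind))
  if (x$kind == "epsilon_optimal") cat(sprintf(" (epsilon=%.3g)", x$epsilon))
  cat("\n")
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Simulate one subject on a schedule
#'
#' Responses are sampled from the agent's policy; outcomes follow
#' [realize_outcome()].  For a `qlearner` the per-trial choice probabilities
#' come from [choice_probability()] applied to the Q-trajectory maintained
#' with [outcome_value()] / [prediction_error()] / [q_update()], so the
#' trajectory is identical to the one [neg_log_likelihood()] reconstructs
#' from the resulting record.
#'
#' @param agent an [agent()] spec.
#' @param schedule a [build_schedule()] result.
#' @param seed integer seed for the response draws.
#' @param subject_id identifier stored in the record.
#' @param topup if `TRUE` and the final tally is below 500, the top-up phase
#'   is appended (the agent keeps playing; a `qlearner` keeps learning).
#'   Top-up trials are flagged and excluded from all analyses.
#' @return a `session_record`; for a `qlearner` the attribute `"agent_prob"`
#'   holds the probability with which each emitted response was sampled.
#' @export
simulate_subject <- function(agent, schedule, seed, subject_id = "sim1",
                             topup = FALSE) {
  stopifnot(inherits(agent, "agent_spec"))
  sched <- as.data.frame(schedule)
  withr::local_seed(as.integer(seed))

  q <- matrix(0, nrow = 4L, ncol = 2L, dimnames = list(STIMULI, RESPONSES))
  respond <- function(stim) {
    switch(agent$kind,
      qlearner = {
        pA <- choice_probability(q[stim, "A"], q[stim, "B"],
                                 agent$params$beta)
        r <- if (runif(1L) < pA) "A" else "B"
        list(response = r, prob = if (r == "A") pA else 1 - pA)
      },
      optimal = ,
      epsilon_optimal = {
        opt <- OPTIMAL_MAP[[stim]]
        flip <- agent$epsilon > 0 && runif(1L) < agent$epsilon
        r <- if (flip) setdiff(RESPONSES, opt) else opt
        list(response = r, prob = if (r == opt) 1 - agent$epsilon
             else agent$epsilon)
      },
      random = {
        r <- if (runif(1L) < 0.5) "A" else "B"
        list(response = r, prob = 0.5)
      })
  }
  learn <- function(stim, resp, outcome, trial_type) {
    if (agent$kind != "qlearner") return(invisible(NULL))
    R <- outcome_value(outcome, trial_type, agent$params)
    PE <- prediction_error(R, q[stim, resp])
    q[stim, resp] <<- q_update(q[stim, resp], PE, agent$params)
  }

  play <- function(trial) {
    ch <- respond(trial$stimulus)
    out <- realize_outcome(trial, ch$response)
    learn(trial$stimulus, ch$response, out$outcome, trial$trial_type)
    c(list(response = ch$response, prob = ch$prob), out)
  }

  n <- nrow(sched)
  response <- outcome <- character(n)
  prob <- numeric(n)
  delta <- integer(n)
  for (t in seq_len(n)) {
    res <- play(sched[t, ])
    response[t] <- res$response
    outcome[t] <- res$outcome
    delta[t] <- res$points_delta
    prob[t] <- res$prob
  }
  df <- data.frame(
    subject_id = subject_id,
    condition = attr(schedule, "condition") %||% NA_character_,
    index = sched$index, block = sched$block, stimulus = sched$stimulus,
    trial_type = sched$trial_type, correct_category = sched$correct_category,
    response = response, outcome = outcome, points_delta = delta,
    is_topup = sched$is_topup, stringsAsFactors = FALSE)

  tally <- POINTS_START + sum(delta)
  if (topup && tally < POINTS_START) {
    idx <- max(df$index)
    n_added <- 0L
    while (tally < TOPUP_TARGET) {
      if (n_added >= 1000L)
        stop("top-up phase did not converge within 1000 appended trials")
      idx <- idx + 1L
      stim <- sample(c("S1", "S2"), 1L)
      trial <- list(index = idx, stimulus = stim, trial_type = "reward",
                    correct_category = if (runif(1L) < P_CATEGORY_A[[stim]])
                      "A" else "B")
      res <- play(trial)
      df <- rbind(df, data.frame(
        subject_id = subject_id, condition = df$condition[1L],
        index = idx, block = NA_integer_, stimulus = stim,
        trial_type = "reward", correct_category = trial$correct_category,
        response = res$response, outcome = res$outcome,
        points_delta = res$points_delta, is_topup = TRUE,
        stringsAsFactors = FALSE))
      tally <- tally + res$points_delta
      n_added <- n_added + 1L
    }
  }
  rec <- new_session_record(df, attr(schedule, "condition"))
  attr(rec, "agent_prob") <- prob
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a synthetic cohort
#'
#' Each free parameter of the chosen variant is either fixed or sampled
#' uniformly over the corresponding fitting grid ("grid-uniform"), so every
#' true parameter is recoverable exactly by the grid search.  The default
#' law restricts beta to `[0.05, 0.5]`: near-zero or large temperatures make
#' all parameters weakly identifiable.
#'
#' @param n_subjects number of subjects, `>= 1`.
#' @param condition task condition for every subject.
#' @param variant generating model variant.
#' @param fixed named list of parameters held at a fixed (on-grid) value;
#'   the rest are sampled grid-uniformly.
#' @param beta_range inclusive bounds restricting the sampled beta grid.
#' @param seed root seed; subjects get child seeds via [derive_seed()].
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, condition = "intermixed",
                        variant = "r0_zero", fixed = list(),
                        beta_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(n_subjects >= 1)
  variant <- match.arg(variant, VARIANTS)
  condition <- match.arg(condition, CONDITIONS)
  grids <- default_grids()
  for (nm in names(fixed)) {
    g <- if (nm %in% c("r0_rew", "r0_pun")) grids$r0 else grids$lr
    if (min(abs(g - fixed[[nm]])) > 1e-9)
      stop("fixed parameter ", nm, " = ", fixed[[nm]], " is off-grid")
  }
  structure(list(n_subjects = as.integer(n_subjects), condition = condition,
                 variant = variant, fixed = fixed, beta_range = beta_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Sample one on-grid param_vector under a cohort law (RNG state is the
# caller's responsibility).
sample_params <- function(spec) {
  grids <- default_grids()
  beta_grid <- grids$beta[grids$beta >= spec$beta_range[1] &
                          grids$beta <= spec$beta_range[2]]
  pick <- function(nm, g) {
    if (!is.null(spec$fixed[[nm]])) spec$fixed[[nm]] else sample(g, 1L)
  }
  lr_plus <- pick("lr_plus", grids$lr)
  lr_minus <- if (spec$variant == "single_lr") lr_plus
              else pick("lr_minus", grids$lr)
  beta <- pick("beta", beta_grid)
  r0_rew <- switch(spec$variant,
    five_param = pick("r0_rew", grids$r0),
    r0_shared = pick("r0_rew", grids$r0),
    r0_inv = pick("r0_rew", grids$r0),
    0)
  r0_pun <- switch(spec$variant,
    five_param = pick("r0_pun", grids$r0),
    r0_shared = r0_rew,
    r0_inv = -r0_rew,
    0)
  param_vector(spec$variant, lr_plus = lr_plus, lr_minus = lr_minus,
               beta = beta, r0_rew = r0_rew, r0_pun = r0_pun)
}

#' Simulate a cohort of Q-learning subjects
#'
#' @param spec a [cohort_spec()].
#' @param n_repeats schedule length multiplier passed to [build_schedule()].
#' @return list with `records` (list of `session_record`) and `true_params`
#'   (data.frame, one row per subject).  Fully reproducible from the spec's
#'   seed; subject `i` uses child seeds `derive_seed(seed, i, 1:2)` for its
#'   schedule and choices, so adding subjects leaves earlier ones unchanged.
#' @export
simulate_cohort <- function(spec, n_repeats = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- vector("list", spec$n_subjects)
  rows <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    pars <- withr::with_seed(derive_seed(spec$seed, i, 0L),
                             sample_params(spec))
    sched <- build_schedule(spec$condition, derive_seed(spec$seed, i, 1L),
                            n_repeats = n_repeats)
    id <- sprintf("sub%03d", i)
    records[[i]] <- simulate_subject(agent("qlearner", params = pars),
                                     sched, derive_seed(spec$seed, i, 2L),
                                     subject_id = id)
    rows[[i]] <- data.frame(subject_id = id, variant = spec$variant,
                            lr_plus = pars$lr_plus, lr_minus = pars$lr_minus,
                            beta = pars$beta, r0_rew = pars$r0_rew,
                            r0_pun = pars$r0_pun, stringsAsFactors = FALSE)
  }
  list(records = records, true_params = do.call(rbind, rows))
}
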
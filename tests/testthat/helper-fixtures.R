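# Shared test fixtures: hand-built session records and small grids.

OPT_MAP <- c(S1 = "A", S2 = "B", S3 = "A", S4 = "B")

# Build a session record by hand from parallel vectors.  correct_category
# defaults to whatever makes the stated outcome true.
make_record <- function(stimulus, response, outcome,
                        condition = "intermixed", subject_id = "hand1",
                        block = NULL) {
  n <- length(stimulus)
  trial_type <- ifelse(stimulus %in% c("S1", "S2"), "reward", "punishment")
  correct <- character(n)
  for (t in seq_len(n)) {
    other <- setdiff(c("A", "B"), response[t])
    correct[t] <- switch(outcome[t],
      reward = response[t],                       # reward trial, matched
      punishment = other,                         # punishment trial, mismatch
      none = if (trial_type[t] == "reward") other else response[t])
  }
  delta <- ifelse(outcome == "reward", 25L,
                  ifelse(outcome == "punishment", -25L, 0L))
  df <- data.frame(
    subject_id = subject_id, condition = condition,
    index = seq_len(n) - 1L,
    block = if (is.null(block)) ceiling(seq_len(n) / max(1, ceiling(n / 4)))
            else block,
    stimulus = stimulus, trial_type = trial_type,
    correct_category = correct, response = response, outcome = outcome,
    points_delta = delta, is_topup = FALSE, stringsAsFactors = FALSE)
  structure(df, class = c("session_record", "data.frame"),
            condition = condition)
}

# reduced 5-values-per-axis grids for naive-oracle comparisons
small_grids <- function() {
  list(lr = seq(0, 1, length.out = 5),
       beta = seq(0, 1, length.out = 5),
       r0 = seq(-1, 1, length.out = 5))
}

# a deterministic mixed bag of simulated records
random_records <- function(n, seed = 1) {
  kinds <- c("random", "qlearner", "epsilon_optimal")
  lapply(seq_len(n), function(i) {
    kind <- kinds[(i - 1L) %% length(kinds) + 1L]
    ag <- switch(kind,
      random = agent("random"),
      epsilon_optimal = agent("epsilon_optimal", epsilon = 0.1),
      qlearner = agent("qlearner", params = param_vector(
        "five_param", lr_plus = 0.4, lr_minus = 0.2, beta = 0.2,
        r0_rew = 0.3, r0_pun = -0.4)))
    s <- build_schedule("intermixed", derive_seed(seed, i, 1L))
    simulate_subject(ag, s, derive_seed(seed, i, 2L),
                     subject_id = sprintf("r%02d", i))
  })
}
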
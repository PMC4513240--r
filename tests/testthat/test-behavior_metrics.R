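# Model-free summaries: percent optimal, win-stay/lose-shift, biases.

test_that("percent optimal is 100 for optimal agents and counted regardless of outcome", {
  rec <- simulate_subject(agent("optimal"), build_schedule("intermixed", 13),
                          seed = 14)
  po <- percent_optimal(rec)
  expect_equal(nrow(po), 8L)   # 4 blocks x 2 types
  expect_true(all(po$percent_optimal == 100))
  # optimal responses that drew the unlucky 20% outcome still count: this
  # optimal agent received some no-feedback and some punishments
  expect_true(any(rec$outcome != "reward"))

  # random responding sits near 50% per type on a long schedule
  long <- build_schedule("intermixed", 15, n_repeats = 10)
  rr <- simulate_subject(agent("random"), long, seed = 16)
  po2 <- percent_optimal(rr, by_block = FALSE, by_type = TRUE)
  expect_true(all(abs(po2$percent_optimal - 50) <
                    100 * 3 * sqrt(0.25 / 800)))
})

test_that("empty strata are reported missing, not zero", {
  rec <- simulate_subject(agent("optimal"),
                          build_schedule("reward_first", 17), seed = 18)
  po <- percent_optimal(rec)
  pun_b1 <- po[po$block == 1 & po$trial_type == "punishment", ]
  expect_equal(pun_b1$n_trials, 0L)
  expect_true(is.na(pun_b1$percent_optimal))
})

test_that("win-stay and lose-shift follow their per-stimulus definitions", {
  # S1: A rewarded, then A again -> one win-stay in one opportunity
  r1 <- make_record(c("S1", "S1"), c("A", "A"), c("reward", "reward"))
  w1 <- win_stay_lose_shift(r1)
  rew <- w1[w1$trial_type == "reward", ]
  expect_equal(rew$win_opportunities, 1L)
  expect_equal(rew$win_stay, 1L)

  # S3: A punished, then B -> one lose-shift in one opportunity
  r2 <- make_record(c("S3", "S3"), c("A", "B"), c("punishment", "none"))
  w2 <- win_stay_lose_shift(r2)
  pun <- w2[w2$trial_type == "punishment", ]
  expect_equal(pun$lose_opportunities, 1L)
  expect_equal(pun$lose_shift, 1L)

  # S1: A with no feedback (non-reward) is a lose event; B is a shift
  r3 <- make_record(c("S1", "S1"), c("A", "B"), c("none", "none"))
  w3 <- win_stay_lose_shift(r3)
  rew3 <- w3[w3$trial_type == "reward", ]
  expect_equal(rew3$lose_opportunities, 1L)
  expect_equal(rew3$lose_shift, 1L)
  expect_equal(rew3$win_opportunities, 0L)
  expect_true(is.na(rew3$win_stay_rate))

  # no-feedback on a punishment trial (avoided punisher) is a win event
  r4 <- make_record(c("S3", "S3"), c("A", "A"), c("none", "none"))
  w4 <- win_stay_lose_shift(r4)
  pun4 <- w4[w4$trial_type == "punishment", ]
  expect_equal(pun4$win_opportunities, 1L)
  expect_equal(pun4$win_stay, 1L)

  # transitions are per stimulus: an interleaved S2 trial does not break the
  # S1 chain, and contributes no transition of its own
  r5 <- make_record(c("S1", "S2", "S1"), c("A", "B", "A"),
                    c("reward", "reward", "reward"))
  w5 <- win_stay_lose_shift(r5)
  expect_equal(w5$win_stay[w5$trial_type == "reward"], 1L)
  expect_equal(w5$win_opportunities[w5$trial_type == "reward"], 1L)
})

test_that("win/lose events and stays/shifts are conserved on random records", {
  # independent per-trial oracle: walk trials keeping the previous trial per
  # stimulus, classify events, and compare with the vectorized implementation
  oracle <- function(rec) {
    df <- as.data.frame(rec)[!rec$is_topup, ]
    last <- list()
    acc <- c(ws_r = 0, wo_r = 0, ls_r = 0, lo_r = 0,
             ws_p = 0, wo_p = 0, ls_p = 0, lo_p = 0)
    for (t in seq_len(nrow(df))) {
      s <- df$stimulus[t]
      if (!is.null(last[[s]])) {
        prev <- last[[s]]
        win <- prev$outcome == "reward" ||
          (prev$outcome == "none" && prev$trial_type == "punishment")
        sfx <- if (df$trial_type[t] == "reward") "r" else "p"
        stay <- df$response[t] == prev$response
        if (win) {
          acc[paste0("wo_", sfx)] <- acc[paste0("wo_", sfx)] + 1
          if (stay) acc[paste0("ws_", sfx)] <- acc[paste0("ws_", sfx)] + 1
        } else {
          acc[paste0("lo_", sfx)] <- acc[paste0("lo_", sfx)] + 1
          if (!stay) acc[paste0("ls_", sfx)] <- acc[paste0("ls_", sfx)] + 1
        }
      }
      last[[s]] <- df[t, ]
    }
    acc
  }
  for (rec in random_records(3, seed = 55)) {
    w <- win_stay_lose_shift(rec)
    o <- oracle(rec)
    rew <- w[w$trial_type == "reward", ]
    pun <- w[w$trial_type == "punishment", ]
    expect_equal(rew$win_stay, unname(o["ws_r"]))
    expect_equal(rew$win_opportunities, unname(o["wo_r"]))
    expect_equal(rew$lose_shift, unname(o["ls_r"]))
    expect_equal(rew$lose_opportunities, unname(o["lo_r"]))
    expect_equal(pun$win_stay, unname(o["ws_p"]))
    expect_equal(pun$lose_shift, unname(o["ls_p"]))
    # every event with a successor is either a stay or a shift
    expect_lte(rew$win_stay, rew$win_opportunities)
    expect_lte(pun$lose_shift, pun$lose_opportunities)
    # win and lose opportunities partition same-stimulus transitions
    n_trans <- sum(table(rec$stimulus[!rec$is_topup]) - 1L)
    expect_equal(rew$win_opportunities + rew$lose_opportunities +
                   pun$win_opportunities + pun$lose_opportunities, n_trans)
  }
})

test_that("agents valuing R0rew > 0 and R0pun < 0 reproduce the human win-stay/lose-shift asymmetry", {
  # within-cohort contrast: more win-stay after an explicit reward than after
  # an avoided punishment, and more lose-shift after an explicit punishment
  # than after a missed reward
  ws_r <- ws_p <- ls_p <- ls_r <- numeric(10)
  pv <- param_vector("five_param", lr_plus = 0.3, lr_minus = 0.3,
                     beta = 0.15, r0_rew = 0.5, r0_pun = -0.5)
  for (i in 1:10) {
    s <- build_schedule("intermixed", derive_seed(2, i, 1))
    rec <- simulate_subject(agent("qlearner", params = pv), s,
                            seed = derive_seed(2, i, 2))
    w <- win_stay_lose_shift(rec)
    ws_r[i] <- w$win_stay_rate[w$trial_type == "reward"]
    ws_p[i] <- w$win_stay_rate[w$trial_type == "punishment"]
    ls_p[i] <- w$lose_shift_rate[w$trial_type == "punishment"]
    ls_r[i] <- w$lose_shift_rate[w$trial_type == "reward"]
  }
  expect_gt(mean(ws_r), mean(ws_p, na.rm = TRUE))
  expect_gt(mean(ls_p), mean(ls_r, na.rm = TRUE))
})

test_that("performance bias is the final-block reward minus punishment difference", {
  # construct block-4 performance directly: 90% vs 70% -> +20
  stim <- c(rep("S1", 10), rep("S3", 10))
  resp <- c(rep("A", 9), "B", rep("A", 7), rep("B", 3))
  outc <- ifelse(stim == "S1", ifelse(resp == "A", "reward", "none"),
                 ifelse(resp == "A", "none", "punishment"))
  rec <- make_record(stim, resp, outc, block = rep(4L, 20))
  b <- performance_bias(rec)
  expect_equal(b$bias, 20)
  expect_equal(b$reward_pct, 90)
  expect_equal(b$punishment_pct, 70)

  # 60% vs 80% -> -20
  resp2 <- c(rep("A", 6), rep("B", 4), rep("A", 8), rep("B", 2))
  outc2 <- ifelse(stim == "S1", ifelse(resp2 == "A", "reward", "none"),
                  ifelse(resp2 == "A", "none", "punishment"))
  b2 <- performance_bias(make_record(stim, resp2, outc2,
                                     block = rep(4L, 20)))
  expect_equal(b2$bias, -20)

  # separated condition: each type's final trained block, labeled distinctly
  rec3 <- simulate_subject(agent("optimal"),
                           build_schedule("punish_first", 19), seed = 20)
  b3 <- performance_bias(rec3)
  expect_equal(b3$definition, "separated_final_blocks")
  expect_equal(b3$punishment_block, 2L)
  expect_equal(b3$reward_block, 4L)
  expect_equal(b3$bias, 0)
})

test_that("R0 bias is the difference of the fitted no-feedback values", {
  expect_equal(r0_bias(list(r0_rew = 0.5, r0_pun = -0.5)), 1.0)
  expect_equal(r0_bias(list(r0_rew = 0.4, r0_pun = -0.4)), 0.8)
  shared <- param_vector("r0_shared", lr_plus = 0.2, lr_minus = 0.2,
                         beta = 0.1, r0_rew = 0.3)
  expect_equal(r0_bias(structure(list(params = shared),
                                 class = "fit_result")), 0)
  expect_error(r0_bias(list(r0_rew = 0.2)), "r0_pun")
})

test_that("behavior_summary flattens the per-subject metrics", {
  rec <- simulate_subject(agent("epsilon_optimal", epsilon = 0.2),
                          build_schedule("intermixed", 23), seed = 24,
                          subject_id = "subX")
  row <- behavior_summary(rec)
  expect_equal(nrow(row), 1L)
  expect_equal(row$subject_id, "subX")
  expect_true(all(c("pct_optimal_reward", "win_stay_rate_punishment",
                    "performance_bias") %in% names(row)))
  expect_true(row$pct_optimal_reward > 50)
})
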
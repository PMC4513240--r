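# Observation model: softmax, outcome values, updates, sequential likelihood.

test_that("softmax choice rule matches its closed form and limits", {
  expect_equal(choice_probability(0.7, 0.7, 0.3), 0.5)
  expect_equal(choice_probability(1, 0, 1), exp(1) / (exp(1) + 1),
               tolerance = 1e-12)
  # argmax limit at beta = 0
  expect_identical(choice_probability(1, 0, 0), 1)
  expect_identical(choice_probability(0, 1, 0), 0)
  expect_identical(choice_probability(0.4, 0.4, 0), 0.5)
  # numerically stable for extreme ratios
  expect_equal(choice_probability(1, -1, 1e-4), 1)
  expect_equal(choice_probability(-1, 1, 1e-4), 0)
  expect_error(choice_probability(0, 0, -0.1))
})

test_that("outcome value, prediction error and update follow the model", {
  pv <- param_vector("five_param", lr_plus = 0.1, lr_minus = 0.5,
                     beta = 0.2, r0_rew = 0.4, r0_pun = -0.3)
  expect_equal(outcome_value("reward", "reward", pv), 1)
  expect_equal(outcome_value("punishment", "punishment", pv), -1)
  expect_equal(outcome_value("none", "punishment", pv), -0.3)
  expect_equal(outcome_value("none", "reward", pv), 0.4)
  shared <- param_vector("r0_shared", lr_plus = 0.1, lr_minus = 0.1,
                         beta = 0.2, r0_rew = 0.4)
  expect_equal(outcome_value("none", "reward", shared), 0.4)
  expect_equal(outcome_value("none", "punishment", shared), 0.4)

  expect_equal(prediction_error(1, 0), 1)
  expect_equal(prediction_error(-1, 0.5), -1.5)
  expect_equal(prediction_error(0.4, 0.4), 0)

  expect_equal(q_update(0, 1, pv), 0.1)        # positive PE uses LR+
  expect_equal(q_update(0.5, -0.6, pv), 0.2)   # negative PE uses LR-
  expect_equal(q_update(0.3, 0, pv), 0.3)      # zero PE: no update
})

test_that("parameter vectors enforce variant constraints and ranges", {
  expect_error(param_vector("five_param", lr_plus = 0.5, lr_minus = 0.5,
                            beta = 0.1), "r0_rew")
  inv <- param_vector("r0_inv", lr_plus = 0.2, lr_minus = 0.2, beta = 0.1,
                      r0_rew = 0.4)
  expect_equal(inv$r0_pun, -0.4)
  expect_error(param_vector("r0_inv", lr_plus = 0.2, lr_minus = 0.2,
                            beta = 0.1, r0_rew = 0.4, r0_pun = 0.4))
  sl <- param_vector("single_lr", lr_plus = 0.3)
  expect_equal(sl$lr_minus, 0.3)
  expect_equal(c(sl$r0_rew, sl$r0_pun), c(0, 0))
  expect_error(param_vector("r0_zero", lr_plus = 0.3, lr_minus = 0.3,
                            beta = 0.1, r0_rew = 0.2))
  expect_error(param_vector("five_param", lr_plus = 1.2, lr_minus = 0.5,
                            beta = 0.1, r0_rew = 0, r0_pun = 0))
  expect_equal(vapply(c("five_param", "r0_shared", "r0_inv", "r0_zero",
                        "single_lr"), n_free_params, integer(1)),
               c(five_param = 5L, r0_shared = 4L, r0_inv = 4L,
                 r0_zero = 3L, single_lr = 2L))
})

test_that("frozen learning rates give the chance likelihood in closed form", {
  rec <- simulate_subject(agent("random"), build_schedule("intermixed", 2),
                          seed = 9)
  pv <- param_vector("five_param", lr_plus = 0, lr_minus = 0, beta = 0.5,
                     r0_rew = 0.3, r0_pun = -0.2)
  tr <- neg_log_likelihood(rec, pv)
  expect_equal(tr$negLLE, 160 * log(2), tolerance = 1e-12)
  expect_equal(p_choice(tr$negLLE, tr$n), 0.5, tolerance = 1e-12)
  # window consistency: the two 80-trial windows sum to the full session
  t1 <- neg_log_likelihood(rec, pv, "first80")
  t2 <- neg_log_likelihood(rec, pv, "last80")
  expect_equal(t1$n, 80L)
  expect_equal(t2$n, 80L)
  expect_equal(t1$negLLE + t2$negLLE, tr$negLLE, tolerance = 1e-10)
})

test_that("the five-trial worked example matches the hand computation", {
  # S1 trials: A/reward, A/reward, B/none, A/reward, A/none with
  # LR+ = LR- = 0.5, beta = 0.5, r0_rew = 0.  Expected probabilities,
  # computed by hand from the softmax and update rules:
  #   0.5, 1/(1+e^-1), 1 - 1/(1+e^-1.5), 1/(1+e^-1.5), 1/(1+e^-1.75)
  # negLLE frozen from that independent arithmetic.
  rec <- make_record(rep("S1", 5), c("A", "A", "B", "A", "A"),
                     c("reward", "reward", "none", "reward", "none"))
  pv <- param_vector("five_param", lr_plus = 0.5, lr_minus = 0.5, beta = 0.5,
                     r0_rew = 0, r0_pun = 0)
  tr <- neg_log_likelihood(rec, pv)
  expect_equal(tr$trials$p_obs,
               c(0.5, 1 / (1 + exp(-1)), 1 - 1 / (1 + exp(-1.5)),
                 1 / (1 + exp(-1.5)), 1 / (1 + exp(-1.75))),
               tolerance = 1e-12)
  expect_equal(tr$negLLE, 3.069459574481760, tolerance = 1e-10)
})

test_that("the simulator and the likelihood share one Q-learning core", {
  pv <- param_vector("five_param", lr_plus = 0.35, lr_minus = 0.15,
                     beta = 0.2, r0_rew = 0.5, r0_pun = -0.5)
  for (seed in 1:5) {
    sched <- build_schedule("intermixed", derive_seed(seed, 0, 1))
    rec <- simulate_subject(agent("qlearner", params = pv), sched,
                            seed = derive_seed(seed, 0, 2))
    tr <- neg_log_likelihood(rec, pv)
    expect_equal(tr$trials$p_obs, attr(rec, "agent_prob"), tolerance = 1e-12)
  }
})

test_that("choice probabilities normalize and Q-values stay within [-1, 1]", {
  withr::with_seed(31, {
    for (i in 1:20) {
      qa <- runif(1, -1, 1); qb <- runif(1, -1, 1); b <- runif(1, 0, 1)
      expect_equal(choice_probability(qa, qb, b) +
                     choice_probability(qb, qa, b), 1, tolerance = 1e-12)
    }
  })
  recs <- random_records(4, seed = 17)
  pvs <- list(
    param_vector("five_param", lr_plus = 1, lr_minus = 1, beta = 0.1,
                 r0_rew = 1, r0_pun = -1),
    param_vector("five_param", lr_plus = 0.9, lr_minus = 0.7, beta = 0.6,
                 r0_rew = -1, r0_pun = 1))
  for (rec in recs) for (pv in pvs) {
    tr <- neg_log_likelihood(rec, pv)
    expect_true(all(tr$trials$p_obs >= 0 & tr$trials$p_obs <= 1))
    expect_true(all(abs(tr$q_final) <= 1 + 1e-12))
  }
})

test_that("likelihood rejects malformed input and p_choice maps edge cases", {
  pv <- param_vector("r0_zero", lr_plus = 0.1, lr_minus = 0.1, beta = 0.1)
  rec <- make_record("S1", "A", "reward")
  bad <- rec; bad$stimulus <- "S9"
  expect_error(neg_log_likelihood(bad, pv), "stimulus")
  bad2 <- rec; bad2$outcome <- "jackpot"
  expect_error(neg_log_likelihood(bad2, pv), "outcome")
  expect_error(p_choice(10, 0))
  expect_equal(p_choice(0, 80), 1)
  expect_equal(p_choice(80 * log(2), 80), 0.5, tolerance = 1e-12)
  expect_equal(p_choice(Inf, 160), 0)
})
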
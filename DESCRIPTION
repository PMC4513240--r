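Package: qcatlearn
Title: Q-Learning Models of Probabilistic Reward and Punishment Category
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and trial-by-trial model fitting for a probabilistic
    category-learning task with intermixed or blocked reward- and
    punishment-based trials and an ambiguous no-feedback outcome.  Provides
    the task engine (seeded schedules, 80/20 category law, point tally and
    top-up phase), synthetic Q-learning and heuristic agents, a gain-loss
    Q-learning observation model with separately valued no-feedback outcomes
    (R0rew, R0pun) across five nested variants, exhaustive grid-search
    maximum-likelihood fitting with tie diagnostics, AIC/BIC and
    random-effects Bayesian model selection (protected exceedance
    probabilities), and model-free behavioral summaries (percent optimal,
    win-stay/lose-shift, performance bias, R0 bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
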
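# Model comparison: AIC/BIC and random-effects Bayesian model selection
# (variational Dirichlet scheme with exceedance and protected exceedance
# probabilities, and the Bayes omnibus risk).

#' Akaike information criterion
#' @param negLLE negative log likelihood, `>= 0`.
#' @param k number of free parameters (non-negative integer).
#' @return `2 * negLLE + 2 * k`.
#' @export
aic <- function(negLLE, k) {
  stopifnot(all(negLLE >= 0), all(k >= 0))
  2 * negLLE + 2 * k
}

#' Bayesian information criterion
#' @param negLLE negative log likelihood, `>= 0`.
#' @param k number of free parameters.
#' @param x number of trials, `>= 1`.
#' @return `2 * negLLE + k * log(x)`.
#' @export
bic <- function(negLLE, k, x) {
  if (any(x < 1)) stop("x (number of trials) must be >= 1")
  stopifnot(all(negLLE >= 0), all(k >= 0))
  2 * negLLE + k * log(x)
}

#' Per-subject, per-model evidence table
#'
#' Adds `k` (free parameters of the variant), AIC, BIC and a log-evidence
#' approximation to a cohort fit table.  The default evidence is the
#' Laplace-style `-BIC/2`; `-AIC/2` is available as a sensitivity option.
#'
#' @param fits data.frame from [fit_cohort()] (needs `subject_id`, `variant`,
#'   `negLLE`, `n_trials`).
#' @param evidence `"bic"` or `"aic"`.
#' @return the table with columns `k`, `AIC`, `BIC`, `log_evidence` added.
#' @export
evidence_table <- function(fits, evidence = c("bic", "aic")) {
  evidence <- match.arg(evidence)
  stopifnot(all(c("subject_id", "variant", "negLLE", "n_trials") %in%
                  names(fits)))
  fits$k <- vapply(fits$variant, n_free_params, integer(1))
  fits$AIC <- aic(fits$negLLE, fits$k)
  fits$BIC <- bic(fits$negLLE, fits$k, fits$n_trials)
  fits$log_evidence <- if (evidence == "bic") -fits$BIC / 2 else -fits$AIC / 2
  fits
}

# subjects x models matrix of log evidences from a long evidence table
lme_matrix <- function(ev) {
  subjects <- unique(ev$subject_id)
  models <- unique(ev$variant)
  m <- matrix(NA_real_, length(subjects), length(models),
              dimnames = list(subjects, models))
  for (r in seq_len(nrow(ev)))
    m[ev$subject_id[r], ev$variant[r]] <- ev$log_evidence[r]
  if (anyNA(m)) stop("evidence table is not complete over subjects x models")
  m
}

dirichlet_expect_log <- function(alpha) digamma(alpha) - digamma(sum(alpha))

log_dirichlet_norm <- function(alpha) lgamma(sum(alpha)) - sum(lgamma(alpha))

#' Random-effects Bayesian model selection
#'
#' Treats the generating model as a random effect across subjects: model
#' frequencies get a Dirichlet prior (concentration 1 per model) and the
#' posterior is found by the standard variational scheme.  Exceedance
#' probabilities (probability that each model is the most frequent in the
#' population) are estimated by seeded Monte-Carlo sampling of the posterior
#' Dirichlet; the Bayes omnibus risk (BOR) is the posterior probability that
#' all model frequencies are equal, and the protected exceedance probability
#' is `xp * (1 - BOR) + BOR / M`.
#'
#' @param evidence either a subjects-by-models matrix of log evidences or a
#'   long table from [evidence_table()].
#' @param n_samples Monte-Carlo samples for the exceedance probabilities.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param tol convergence tolerance on the Dirichlet concentrations.
#' @param max_iter iteration cap for the variational loop.
#' @return a `bms_result` with `alpha` (posterior concentrations),
#'   `expected_freq`, `xp`, `bor` and `pxp`, each named by model.
#' @export
bms <- function(evidence, n_samples = 200000L, seed = 1L, tol = 1e-6,
                max_iter = 10000L) {
  lme <- if (is.matrix(evidence)) evidence else lme_matrix(evidence)
  if (!all(is.finite(lme))) stop("non-finite log evidence")
  n <- nrow(lme)
  M <- ncol(lme)
  if (M < 2L) stop("need at least two models")
  if (n < 1L) stop("need at least one subject")

  alpha0 <- rep(1, M)
  alpha <- alpha0
  g <- matrix(0, n, M)
  for (it in seq_len(max_iter)) {
    elog <- dirichlet_expect_log(alpha)
    u <- sweep(lme, 2L, elog, `+`)
    u <- u - apply(u, 1L, max)
    g <- exp(u)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  expected_freq <- alpha / sum(alpha)

  # Exceedance probabilities by Monte Carlo over the posterior Dirichlet.
  xp <- withr::with_seed(as.integer(seed), {
    draws <- matrix(rgamma(n_samples * M, shape = rep(alpha, each = n_samples)),
                    nrow = n_samples)
    win <- max.col(draws, ties.method = "first")
    tabulate(win, nbins = M) / n_samples
  })

  # Bayes omnibus risk: null model H0 fixes equal frequencies r_k = 1/M.
  f0 <- sum(log(rowSums(exp(lme - apply(lme, 1L, max))) / M) +
              apply(lme, 1L, max))
  elog <- dirichlet_expect_log(alpha)
  f1 <- sum(g * lme) + sum(sweep(g, 2L, elog, `*`)) -
    sum(g[g > 0] * log(g[g > 0])) +
    log_dirichlet_norm(alpha0) + sum((alpha0 - 1) * elog) -
    (log_dirichlet_norm(alpha) + sum((alpha - 1) * elog))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- xp * (1 - bor) + bor / M

  models <- colnames(lme) %||% paste0("model", seq_len(M))
  structure(list(alpha = setNames(alpha, models),
                 expected_freq = setNames(expected_freq, models),
                 xp = setNames(xp, models), bor = bor,
                 pxp = setNames(pxp, models), n_subjects = n,
                 n_samples = as.integer(n_samples), iterations = it),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("<bms_result> %d subjects, %d models, BOR=%.4f\n",
              x$n_subjects, length(x$alpha), x$bor))
  tab <- data.frame(alpha = x$alpha, expected_freq = x$expected_freq,
                    xp = x$xp, pxp = x$pxp)
  print(round(tab, 4))
  invisible(x)
}
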
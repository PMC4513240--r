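# Grid-search maximum-likelihood fitting: the task's standard grids (LR+, LR-,
# beta from 0 to 1 in steps of 0.05; R0 from -1 to +1 in steps of 0.1),
# exhaustive search, tie diagnostics and a documented deterministic
# tie-break generalizing the "neutral R0rew = 0" rule.

#' Default fitting grids
#'
#' 21 values per axis: learning rates and beta from 0 to 1 in steps of 0.05,
#' R0 from -1 to +1 in steps of 0.1 (endpoints inclusive).
#'
#' @return list with numeric vectors `lr`, `beta`, `r0`.
#' @export
default_grids <- function() {
  list(lr = seq(0, 1, length.out = 21L),
       beta = seq(0, 1, length.out = 21L),
       r0 = seq(-1, 1, length.out = 21L))
}

#' Parameter grid of a model variant
#'
#' The Cartesian product of the per-parameter grids with the variant's
#' constraints applied (constrained parameters are not free axes).  The grid
#' is kept in compact axis form; use [grid_size()] for the number of points
#' and `as.data.frame()` to materialize it (only sensible for reduced grids).
#'
#' @param variant variant name.
#' @param grids per-axis grids as from [default_grids()].
#' @return a `param_grid` object.
#' @export
parameter_grid <- function(variant, grids = default_grids()) {
  variant <- match.arg(variant, VARIANTS)
  stopifnot(all(c("lr", "beta", "r0") %in% names(grids)))
  free <- switch(variant,
    five_param = c("lr_plus", "lr_minus", "beta", "r0_rew", "r0_pun"),
    r0_shared = c("lr_plus", "lr_minus", "beta", "r0"),
    r0_inv = c("lr_plus", "lr_minus", "beta", "r0_rew"),
    r0_zero = c("lr_plus", "lr_minus", "beta"),
    single_lr = c("lr", "beta"))
  axes <- lapply(free, function(nm) {
    if (startsWith(nm, "r0")) grids$r0
    else if (nm == "beta") grids$beta
    else grids$lr
  })
  names(axes) <- free
  structure(list(variant = variant, axes = axes, grids = grids),
            class = "param_grid")
}

#' Number of points in a parameter grid
#' @param grid a [parameter_grid()] object.
#' @return integer count (product of the free-axis lengths).
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "param_grid"))
  prod(vapply(grid$axes, length, integer(1)))
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("<param_grid> %s: %s free axes, %s points\n", x$variant,
              length(x$axes), format(grid_size(x), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.param_grid <- function(x, ...) {
  df <- expand.grid(x$axes, KEEP.OUT.ATTRS = FALSE)
  # expand constrained columns to the full five-field parameterization
  out <- switch(x$variant,
    five_param = df,
    r0_shared = data.frame(df[c("lr_plus", "lr_minus", "beta")],
                           r0_rew = df$r0, r0_pun = df$r0),
    r0_inv = data.frame(df[c("lr_plus", "lr_minus", "beta")],
                        r0_rew = df$r0_rew, r0_pun = -df$r0_rew),
    r0_zero = data.frame(df, r0_rew = 0, r0_pun = 0),
    single_lr = data.frame(lr_plus = df$lr, lr_minus = df$lr,
                           beta = df$beta, r0_rew = 0, r0_pun = 0))
  out$variant <- x$variant
  out[c("variant", "lr_plus", "lr_minus", "beta", "r0_rew", "r0_pun")]
}

# Encode a record's window trials for the C++ search.
encode_record <- function(record, window) {
  df <- as.data.frame(record)
  if ("is_topup" %in% names(df)) df <- df[!df$is_topup, , drop = FALSE]
  if (!all(df$stimulus %in% STIMULI)) stop("unknown stimulus codes in record")
  if (!all(df$outcome %in% OUTCOMES)) stop("unknown outcome codes in record")
  df <- df[window_rows(nrow(df), window), , drop = FALSE]
  if (nrow(df) == 0L) stop("empty scoring window")
  list(stim = match(df$stimulus, STIMULI),
       resp = match(df$response, RESPONSES),
       outc = match(df$outcome, OUTCOMES),
       n = nrow(df))
}

# Deterministic tie-break: among minimal-negLLE points prefer the smallest
# |r0_rew|, then |r0_pun|, then beta, lr_plus, lr_minus; residual sign ties
# resolved by the signed values.  Generalizes the convention of assigning
# the neutral R0rew = 0 when a whole R0rew half-range ties.
break_ties <- function(tied) {
  ord <- order(abs(tied$r0_rew), abs(tied$r0_pun), tied$beta, tied$lr_plus,
               tied$lr_minus, tied$r0_rew, tied$r0_pun)
  tied[ord[1L], , drop = FALSE]
}

# Summarize the tie set: count, and when the ties vary along exactly one
# parameter, that parameter's name and tied range.
summarize_ties <- function(tied, n_ties, truncated) {
  axes <- c("lr_plus", "lr_minus", "beta", "r0_rew", "r0_pun")
  varying <- axes[vapply(axes, function(a) length(unique(tied[[a]])) > 1L,
                         logical(1))]
  list(count = n_ties,
       truncated = truncated,
       axis = if (length(varying) == 1L) varying else NA_character_,
       range = if (length(varying) == 1L)
         range(tied[[varying]]) else c(NA_real_, NA_real_))
}

#' Fit one subject by exhaustive grid search
#'
#' Evaluates the session's negative log likelihood at every grid point of
#' the variant and returns the minimum.  The default engine factorizes the
#' search (the likelihood splits exactly into a reward-trial and a
#' punishment-trial term, each free of the other type's R0) and runs in
#' C++; `engine = "naive"` loops over the materialized grid through
#' [neg_log_likelihood()] and is retained as the independent oracle for
#' reduced grids.
#'
#' @param record a `session_record` (top-up trials are excluded).
#' @param variant model variant to fit.
#' @param window `"all"`, `"first80"` or `"last80"`.
#' @param grids per-axis grids, defaulting to [default_grids()].
#' @param engine `"factorized"` (default) or `"naive"`.
#' @param tie_tol absolute negLLE tolerance for tie detection (1e-9).
#' @param max_ties cap on stored tied grid points (count is always exact).
#' @return a `fit_result`: best `param_vector`, `negLLE`, `p_choice`,
#'   `n_trials`, and `tie_set` (count; axis and range when the ties lie
#'   along a single parameter).
#' @export
fit_subject <- function(record, variant, window = "all",
                        grids = default_grids(),
                        engine = c("factorized", "naive"),
                        tie_tol = 1e-9, max_ties = 200000L) {
  variant <- match.arg(variant, VARIANTS)
  window <- match.arg(window, WINDOWS)
  engine <- match.arg(engine)
  subject_id <- if ("subject_id" %in% names(record))
    record$subject_id[1L] else NA_character_

  if (engine == "factorized") {
    enc <- encode_record(record, window)
    r0_free <- variant %in% c("five_param", "r0_shared", "r0_inv")
    r0_grid <- if (r0_free) grids$r0 else 0
    if (variant == "r0_inv" &&
        max(abs(sort(r0_grid) + rev(sort(r0_grid)))) > 1e-12)
      stop("r0_inv requires a symmetric R0 grid")
    if (!r0_free && min(abs(grids$r0)) > 1e-12)
      stop("R0 grid must contain 0 for variants fixing R0")
    res <- .grid_search_cpp(enc$stim, enc$resp, enc$outc,
                            grids$lr, grids$beta, r0_grid, r0_grid,
                            match(variant, VARIANTS), tie_tol,
                            as.integer(max_ties))
    ties <- as.data.frame(res$ties)
    tied <- data.frame(lr_plus = grids$lr[ties$lr_plus],
                       lr_minus = grids$lr[ties$lr_minus],
                       beta = grids$beta[ties$beta],
                       r0_rew = r0_grid[ties$r0_rew],
                       r0_pun = if (variant == "r0_inv")
                         -r0_grid[ties$r0_rew] else r0_grid[ties$r0_pun])
    if (variant == "single_lr") tied$lr_minus <- tied$lr_plus
    negll <- res$negLLE
    n_ties <- res$n_ties
    truncated <- res$truncated
    n_trials <- enc$n
  } else {
    grid_df <- as.data.frame(parameter_grid(variant, grids))
    vals <- numeric(nrow(grid_df))
    n_trials <- NA_integer_
    for (g in seq_len(nrow(grid_df))) {
      pv <- param_vector(variant,
                         lr_plus = grid_df$lr_plus[g],
                         lr_minus = grid_df$lr_minus[g],
                         beta = grid_df$beta[g],
                         r0_rew = grid_df$r0_rew[g],
                         r0_pun = grid_df$r0_pun[g])
      tr <- neg_log_likelihood(record, pv, window)
      vals[g] <- tr$negLLE
      n_trials <- tr$n
    }
    negll <- min(vals)
    keep <- vals <= negll + tie_tol
    tied <- grid_df[keep, c("lr_plus", "lr_minus", "beta", "r0_rew",
                            "r0_pun")]
    n_ties <- sum(keep)
    truncated <- FALSE
  }

  best <- break_ties(tied)
  params <- param_vector(variant, lr_plus = best$lr_plus,
                         lr_minus = best$lr_minus, beta = best$beta,
                         r0_rew = best$r0_rew, r0_pun = best$r0_pun)
  structure(list(subject_id = subject_id, variant = variant, window = window,
                 params = params, negLLE = negll,
                 p_choice = p_choice(negll, n_trials), n_trials = n_trials,
                 tie_set = summarize_ties(tied, n_ties, truncated)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s [%s, %s]: negLLE=%.4f p(choice)=%.4f n=%d ties=%d\n",
    x$subject_id, x$variant, x$window, x$negLLE, x$p_choice, x$n_trials,
    x$tie_set$count))
  print(x$params)
  invisible(x)
}

#' Fit a cohort across variants and windows
#'
#' @param records list of `session_record`s.
#' @param variants character vector of variant names.
#' @param windows character vector of window names.
#' @param grids,engine passed to [fit_subject()].
#' @return data.frame with one row per (subject, variant, window): the
#'   best-fit parameters, `negLLE`, `p_choice`, `n_trials`, tie count and
#'   (when one parameter carries the ties) the tied axis and range.
#' @export
fit_cohort <- function(records, variants = "five_param", windows = "all",
                       grids = default_grids(),
                       engine = "factorized") {
  stopifnot(length(records) >= 1L)
  rows <- list()
  for (i in seq_along(records)) {
    for (v in variants) {
      for (w in windows) {
        fit <- tryCatch(
          fit_subject(records[[i]], v, w, grids = grids, engine = engine),
          error = function(e) {
            id <- if ("subject_id" %in% names(records[[i]]))
              records[[i]]$subject_id[1L] else as.character(i)
            stop("fit failed for subject ", id, " (", v, ", ", w, "): ",
                 conditionMessage(e), call. = FALSE)
          })
        rows[[length(rows) + 1L]] <- fit_result_row(fit)
      }
    }
  }
  do.call(rbind, rows)
}

fit_result_row <- function(fit) {
  data.frame(subject_id = fit$subject_id, variant = fit$variant,
             window = fit$window, lr_plus = fit$params$lr_plus,
             lr_minus = fit$params$lr_minus, beta = fit$params$beta,
             r0_rew = fit$params$r0_rew, r0_pun = fit$params$r0_pun,
             negLLE = fit$negLLE, p_choice = fit$p_choice,
             n_trials = fit$n_trials, n_ties = fit$tie_set$count,
             tie_axis = fit$tie_set$axis,
             tie_lo = fit$tie_set$range[1], tie_hi = fit$tie_set$range[2],
             stringsAsFactors = FALSE)
}
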
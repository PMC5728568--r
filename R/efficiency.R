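slope_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Coding efficiency: entropy gained per unit of probability mass
#'
#' Efficiency `E` is the slope of the ordinary least-squares regression of
#' per-pair entropy change `delta_H` on the summed marginal-probability
#' change `delta_p1ij` — how many bits the population gains per unit of
#' added active-state probability (a spiking-cost proxy). The 95% CI is a
#' percentile bootstrap over pairs (resampled with replacement).
#'
#' @param deltas Data frame with columns `delta_H` and `delta_p1ij`, one
#'   row per pair (see [pair_deltas()]).
#' @param bootstrap_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap stream.
#' @param intercept Fit an intercept (default `TRUE`); set `FALSE` for a
#'   through-origin slope.
#' @return An object of class `efficiency_fit`: E, intercept, ci95,
#'   n_pairs, bootstrap slopes and the data. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @examples
#' d <- data.frame(delta_p1ij = 1:10 / 10, delta_H = 0.2 + 1:10 / 10)
#' fit_efficiency(d, bootstrap_reps = 50)
#' @export
fit_efficiency <- function(deltas, bootstrap_reps = 1000, seed = 1L,
                           intercept = TRUE) {
  d <- as_tibble(deltas)
  d <- d[complete.cases(d[, c("delta_H", "delta_p1ij")]), ]
  if (nrow(d) < 3) {
    abort("need at least 3 pairs", class = "neff_validation_error")
  }
  if (sd(d$delta_p1ij) == 0) {
    abort("degenerate predictor: all delta_p1ij equal",
          class = "neff_validation_error")
  }
  x <- d$delta_p1ij; y <- d$delta_H
  if (intercept) {
    E <- slope_ols(x, y)
    a <- mean(y) - E * mean(x)
  } else {
    E <- sum(x * y) / sum(x^2)
    a <- 0
  }
  withr_seed(seed)
  n <- length(x)
  boot <- vapply(seq_len(bootstrap_reps), function(r) {
    i <- sample.int(n, n, replace = TRUE)
    if (sd(x[i]) == 0) return(NA_real_)
    if (intercept) slope_ols(x[i], y[i]) else sum(x[i] * y[i]) / sum(x[i]^2)
  }, numeric(1))
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  res <- structure(
    list(E = E, intercept = a, ci95 = ci, n_pairs = n,
         bootstrap_reps = bootstrap_reps, seed = seed,
         boot = boot, data = d,
         ci_contains_E = ci[1] <= E && E <= ci[2]),
    class = "efficiency_fit")
  if (!res$ci_contains_E) {
    warn("bootstrap percentile CI does not bracket the point estimate")
  }
  res
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("<efficiency_fit> E = %.3f bits/unit p1, 95%% CI [%.3f, %.3f], n = %d pairs\n",
              x$E, x$ci95[1], x$ci95[2], x$n_pairs))
  invisible(x)
}

#' @rdname fit_efficiency
#' @param x,object An `efficiency_fit`.
#' @param ... Unused.
#' @export
tidy.efficiency_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "delta_p1ij"),
         estimate = c(x$intercept, x$E),
         conf.low = c(NA_real_, x$ci95[1]),
         conf.high = c(NA_real_, x$ci95[2]))
}

#' @rdname fit_efficiency
#' @export
glance.efficiency_fit <- function(x, ...) {
  r2 <- cor(x$data$delta_p1ij, x$data$delta_H)^2
  tibble(E = x$E, conf.low = x$ci95[1], conf.high = x$ci95[2],
         intercept = x$intercept, n_pairs = x$n_pairs,
         r.squared = r2, bootstrap_reps = x$bootstrap_reps)
}

#' Efficiency along the trial
#'
#' Binarizes the session once over a common baseline `t0` and a grid of
#' analysis times, then fits the efficiency regression at each time against
#' the baseline, separately per condition. In GO trials efficiency rises
#' after tone onset; NOGO trials stay flat.
#'
#' @param session A [spike_session()].
#' @param window_length Analysis window, seconds (e.g. the
#'   [select_window()] choice).
#' @param times Analysis-time grid, seconds.
#' @param t0 Common baseline time, seconds (default -1).
#' @param conditions Conditions to analyse.
#' @param bootstrap_reps,seed Passed to [fit_efficiency()].
#' @param pool Threshold pool passed to [binarize()].
#' @return A tibble of class `efficiency_timecourse`: condition, time, E,
#'   conf.low, conf.high, n_pairs.
#' @export
efficiency_timecourse <- function(session, window_length, times, t0 = -1,
                                  conditions = c("GO", "NOGO"),
                                  bootstrap_reps = 200, seed = 1L,
                                  pool = "all_correct") {
  st <- binarize(session, window_length, sort(unique(c(t0, times))),
                 pool = pool)
  out <- map(conditions, function(cc) {
    map(times, function(tt) {
      fit <- fit_efficiency(pair_deltas(st, t0 = t0, t1 = tt,
                                        condition = cc),
                            bootstrap_reps = bootstrap_reps, seed = seed)
      tibble(condition = cc, time = tt, E = fit$E,
             conf.low = fit$ci95[1], conf.high = fit$ci95[2],
             n_pairs = fit$n_pairs)
    }) |> list_rbind()
  }) |> list_rbind()
  structure(out, window_length = window_length, t0 = t0,
            class = c("efficiency_timecourse", class(out)))
}

#' Session performance against mean pairwise entropy
#'
#' Ordinary least-squares regression of behavioural performance on each
#' session's mean pairwise entropy (at the tone-evaluation time), with a
#' percentile bootstrap CI over sessions.
#'
#' @param sessions Data frame with numeric columns `performance` and
#'   `mean_H` (one row per session).
#' @param bootstrap_reps,seed Bootstrap settings.
#' @return One-row tibble: slope, conf.low, conf.high, intercept,
#'   n_sessions.
#' @export
performance_entropy_regression <- function(sessions, bootstrap_reps = 1000,
                                           seed = 1L) {
  d <- as_tibble(sessions)
  if (nrow(d) < 3) {
    abort("need at least 3 sessions", class = "neff_validation_error")
  }
  if (sd(d$mean_H) == 0) {
    abort("constant entropy across sessions",
          class = "neff_validation_error")
  }
  b <- slope_ols(d$mean_H, d$performance)
  a <- mean(d$performance) - b * mean(d$mean_H)
  withr_seed(seed)
  n <- nrow(d)
  boot <- vapply(seq_len(bootstrap_reps), function(r) {
    i <- sample.int(n, n, replace = TRUE)
    if (sd(d$mean_H[i]) == 0) return(NA_real_)
    slope_ols(d$mean_H[i], d$performance[i])
  }, numeric(1))
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  tibble(slope = b, conf.low = ci[1], conf.high = ci[2],
         intercept = a, n_sessions = n)
}
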
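#' Binarize a session's spike counts around their trial mean
#'
#' Implements the two-state neuron code: at each analysis time `t`, a
#' neuron's state is 1 on trials where its spike count in the half-open
#' window `[t - W/2, t + W/2)` strictly exceeds the across-trials mean
#' count for that neuron and time, and 0 otherwise. Only correct trials
#' enter the analysis. The comparison is strict, so when every trial has
#' the same count all states are 0.
#'
#' The trial set over which the threshold mean is computed is controlled by
#' `pool`: `"all_correct"` (default) pools correct GO and NOGO trials, so
#' binarization itself cannot manufacture condition information;
#' `"per_condition"` computes one mean per condition.
#'
#' @param session A [spike_session()].
#' @param window_length Analysis window length `W`, seconds.
#' @param analysis_times Numeric vector of window centres, seconds relative
#'   to tone onset. Every window must lie inside the recorded epoch.
#' @param pool `"all_correct"` or `"per_condition"`.
#' @return A tibble of class `binary_states` with columns neuron_id,
#'   trial_index, condition, analysis_time, count, state; attributes
#'   `window_length`, `analysis_times`, `pool` and `thresholds` (the
#'   per-(neuron, time) mean counts).
#' @examples
#' s <- generate_spike_session(synthetic_spec(n_neurons = 4, n_trials = 10))
#' head(binarize(s, 0.32, c(-1, 0.5)))
#' @export
binarize <- function(session, window_length, analysis_times,
                     pool = c("all_correct", "per_condition")) {
  pool <- match.arg(pool)
  stopifnot(window_length > 0, length(analysis_times) >= 1)
  lo <- analysis_times - window_length / 2
  hi <- analysis_times + window_length / 2
  bad <- lo < session$epoch[1] - 1e-9 | hi > session$epoch[2] + 1e-9
  if (any(bad)) {
    abort(paste0("window extends outside the recorded epoch at time(s): ",
                 paste(analysis_times[bad], collapse = ", ")),
          class = "neff_validation_error")
  }
  keep <- trial_pool(session)
  if (!length(keep)) {
    abort("no correct trials to binarize", class = "neff_validation_error")
  }
  sp <- filter(session$spikes, .data$trial_index %in% keep)
  cnt <- map(seq_along(analysis_times), function(i) {
    in_win <- sp |>
      filter(.data$time_ms / 1000 >= lo[i],
             .data$time_ms / 1000 < hi[i]) |>
      count(.data$neuron_id, .data$trial_index, name = "count")
    crossing(neuron_id = session$neurons, trial_index = keep) |>
      left_join(in_win, by = c("neuron_id", "trial_index")) |>
      mutate(count = dplyr::coalesce(.data$count, 0L),
             analysis_time = analysis_times[i])
  }) |> list_rbind() |>
    left_join(session$trials[, c("trial_index", "condition")],
              by = "trial_index")
  grp <- if (pool == "all_correct") c("neuron_id", "analysis_time")
         else c("neuron_id", "analysis_time", "condition")
  thr <- cnt |>
    group_by(across(all_of(grp))) |>
    summarise(mean_count = mean(.data$count), .groups = "drop")
  out <- cnt |>
    left_join(thr, by = grp) |>
    mutate(state = as.integer(.data$count > .data$mean_count)) |>
    select("neuron_id", "trial_index", "condition", "analysis_time",
           "count", "state") |>
    arrange(.data$analysis_time, .data$neuron_id, .data$trial_index)
  structure(out, window_length = window_length,
            analysis_times = analysis_times, pool = pool,
            thresholds = thr, session_id = session$session_id,
            class = c("binary_states", class(out)))
}

#' Probability of the active state
#'
#' `p1` is the fraction of trials on which a neuron's binary state is 1.
#'
#' @param states Integer/logical vector of binary states across trials.
#' @return A probability in `[0, 1]`.
#' @export
estimate_p1 <- function(states) {
  if (!length(states)) {
    abort("no trials", class = "neff_validation_error")
  }
  mean(as.integer(states))
}

#' Expected active-state probability for Poisson spike counts
#'
#' If a neuron's window count is Poisson with mean `mu`, the probability of
#' exceeding its mean is `P(N > mu) = 1 - F(floor(mu))`, where `F` is the
#' Poisson CDF. The value approaches 0.5 from below as `mu` grows and the
#' count distribution becomes symmetric; it is 0 at `mu = 0`.
#'
#' @param mean_count Non-negative numeric vector of mean window counts.
#' @return Probabilities, same length as `mean_count`.
#' @examples
#' expected_poisson_p1(c(0, 1, 5, 100))
#' @export
expected_poisson_p1 <- function(mean_count) {
  if (any(mean_count < 0)) {
    abort("mean_count must be non-negative", class = "neff_validation_error")
  }
  1 - ppois(floor(mean_count), mean_count)
}

#' Fano factor of the binary state
#'
#' Variance-to-mean ratio of a Bernoulli state under the population
#' variance convention, which makes it exactly `1 - p1`: the state's
#' variance is `p1 (1 - p1)` and its mean is `p1`.
#'
#' @param states Binary state vector across trials.
#' @return `1 - p1`. Errors when `p1 = 0` (ratio undefined at mean 0).
#' @export
fano_factor <- function(states) {
  p1 <- estimate_p1(states)
  if (p1 == 0) {
    abort("Fano factor undefined: p1 is 0", class = "neff_validation_error")
  }
  1 - p1
}
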
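#' Control analysis: entropy and efficiency around a task-unrelated event
#'
#' Checks whether entropy/efficiency changes track *any* firing-rate change
#' or specifically the reward-predicting cue, using a reward-unrelated
#' event — by default the end-of-trial (EoT) mechanical relay. Correct
#' trials are split by the sign of the population firing-rate change
#' between a baseline window and the window centred on the event
#' (Increasing vs Decreasing). Within each group, binary states at the
#' event and at the baseline are computed with group-specific trial-mean
#' thresholds; per-pair `delta_H` is compared between groups with an exact
#' two-sided sign test, and the efficiency slopes are compared through
#' their bootstrap CIs.
#'
#' @param session A [spike_session()]; for `event = "eot"`, trials must
#'   carry `eot_time_ms`.
#' @param window Analysis window length, seconds (default 0.32).
#' @param event `"eot"` or `"custom"`.
#' @param event_times For `"custom"`, numeric vector of event times
#'   (seconds), one per trial in `session$trials` order.
#' @param t_baseline Baseline window centre, seconds (default -1).
#' @param bootstrap_reps,seed Bootstrap settings for the per-group
#'   efficiency fits.
#' @return A list of class `event_split`: per-group trial counts and mean
#'   rate change, the paired per-pair `delta_H` table, `sign_test`
#'   (htest), per-group `efficiency` fits and `E_ci_overlap`.
#' @export
event_split_analysis <- function(session, window = 0.32,
                                 event = c("eot", "custom"),
                                 event_times = NULL, t_baseline = -1,
                                 bootstrap_reps = 500, seed = 1L) {
  event <- match.arg(event)
  tr <- session$trials
  if (event == "eot") {
    if (all(is.na(tr$eot_time_ms))) {
      abort("session has no end-of-trial event times",
            class = "neff_validation_error")
    }
    ev <- tr$eot_time_ms / 1000
  } else {
    if (is.null(event_times) || length(event_times) != nrow(tr)) {
      abort("event_times must supply one time per trial",
            class = "neff_validation_error")
    }
    ev <- as.numeric(event_times)
  }
  keep <- trial_pool(session)
  ev <- ev[match(keep, tr$trial_index)]
  cnt_at <- function(centres) {
    # per (neuron, trial) spike count in windows centred per trial
    lo <- centres - window / 2; hi <- centres + window / 2
    sp <- filter(session$spikes, .data$trial_index %in% keep)
    ctr <- tibble(trial_index = keep, lo = lo, hi = hi)
    sp |>
      inner_join(ctr, by = "trial_index") |>
      filter(.data$time_ms / 1000 >= .data$lo,
             .data$time_ms / 1000 < .data$hi) |>
      count(.data$neuron_id, .data$trial_index, name = "count") |>
      complete(neuron_id = session$neurons, trial_index = keep,
               fill = list(count = 0L))
  }
  c_ev <- cnt_at(ev)
  c_bl <- cnt_at(rep(t_baseline, length(keep)))
  drate <- c_ev |>
    rename(count_ev = "count") |>
    inner_join(rename(c_bl, count_bl = "count"),
               by = c("neuron_id", "trial_index")) |>
    group_by(.data$trial_index) |>
    summarise(delta_rate = mean(.data$count_ev - .data$count_bl) / window,
              .groups = "drop")
  inc <- drate$trial_index[drate$delta_rate > 0]
  dec <- drate$trial_index[drate$delta_rate < 0]
  if (!length(inc) || !length(dec)) {
    abort("one trial group (Increasing/Decreasing) is empty",
          class = "neff_validation_error")
  }
  group_deltas <- function(trials_g) {
    states_of <- function(cnts) {
      cnts |>
        filter(.data$trial_index %in% trials_g) |>
        group_by(.data$neuron_id) |>
        mutate(state = as.integer(.data$count > mean(.data$count))) |>
        ungroup() |>
        arrange(.data$neuron_id, .data$trial_index)
    }
    triples <- function(st) {
      S <- do.call(cbind, split(st$state, st$neuron_id))
      n <- nrow(S); ids <- colnames(S)
      C11 <- crossprod(S); m1 <- colSums(S)
      idx <- which(upper.tri(C11), arr.ind = TRUE)
      n11 <- C11[idx]; n1i <- m1[idx[, 1]]; n1j <- m1[idx[, 2]]
      occ <- (n11 > 0) + (n1i - n11 > 0) + (n1j - n11 > 0) +
        (n - n1i - n1j + n11 > 0)
      tibble(neuron_i = ids[idx[, 1]], neuron_j = ids[idx[, 2]],
             p1i = n1i / n, p1j = n1j / n, p11 = n11 / n,
             n_trials = n, n_occupied = as.integer(occ))
    }
    delta_metrics(triples(states_of(c_ev)), triples(states_of(c_bl)))
  }
  d_inc <- group_deltas(inc)
  d_dec <- group_deltas(dec)
  paired <- inner_join(
    select(d_inc, "neuron_i", "neuron_j", dH_inc = "delta_H"),
    select(d_dec, "neuron_i", "neuron_j", dH_dec = "delta_H"),
    by = c("neuron_i", "neuron_j"))
  diff <- paired$dH_inc - paired$dH_dec
  nz <- diff[diff != 0]
  sign_test <- binom.test(sum(nz > 0), length(nz), p = 0.5,
                          alternative = "two.sided")
  fit_inc <- fit_efficiency(d_inc, bootstrap_reps = bootstrap_reps,
                            seed = seed)
  fit_dec <- fit_efficiency(d_dec, bootstrap_reps = bootstrap_reps,
                            seed = seed + 1L)
  overlap <- fit_inc$ci95[1] <= fit_dec$ci95[2] &&
    fit_dec$ci95[1] <= fit_inc$ci95[2]
  structure(
    list(groups = tibble(
           group = c("Increasing", "Decreasing"),
           n_trials = c(length(inc), length(dec)),
           mean_delta_rate = c(
             mean(drate$delta_rate[drate$trial_index %in% inc]),
             mean(drate$delta_rate[drate$trial_index %in% dec]))),
         deltas = paired,
         sign_test = sign_test,
         efficiency = list(Increasing = fit_inc, Decreasing = fit_dec),
         E_ci_overlap = overlap,
         window = window, t_baseline = t_baseline),
    class = "event_split")
}

#' @export
print.event_split <- function(x, ...) {
  cat("<event_split>\n")
  print(x$groups)
  cat(sprintf("  sign test on paired delta_H: p = %.4g\n",
              x$sign_test$p.value))
  cat(sprintf("  E (Increasing) = %.3f [%.3f, %.3f]; E (Decreasing) = %.3f [%.3f, %.3f]; CIs %s\n",
              x$efficiency$Increasing$E, x$efficiency$Increasing$ci95[1],
              x$efficiency$Increasing$ci95[2],
              x$efficiency$Decreasing$E, x$efficiency$Decreasing$ci95[1],
              x$efficiency$Decreasing$ci95[2],
              if (x$E_ci_overlap) "overlap" else "do not overlap"))
  invisible(x)
}
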
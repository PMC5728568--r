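#' Trial-structured spike sessions
#'
#' A `spike_session` bundles everything one recording session contributes to
#' the analysis: a trial table (condition, outcome, optional end-of-trial
#' event time), per-(neuron, trial) spike timestamps, and the session's
#' behavioural performance. Time zero is stimulus (tone) onset in every
#' trial; all timestamps are seconds relative to onset, held internally on a
#' 1 ms integer grid so that file round trips are bit-exact.
#'
#' @param session_id Single string identifying the session.
#' @param trials Data frame with columns `trial_index` (integer),
#'   `condition` (`"GO"` or `"NOGO"`), `outcome` (`"correct"` or
#'   `"incorrect"`), and optionally `eot_time_ms` (integer ms, end-of-trial
#'   relay event).
#' @param spikes Data frame with columns `neuron_id`, `trial_index`,
#'   `time_ms` (integer milliseconds relative to stimulus onset). Timestamps
#'   must be strictly increasing within each (neuron, trial).
#' @param performance Fraction of correct trials in `[0, 1]`.
#' @param epoch Length-2 numeric, the recorded epoch in seconds relative to
#'   onset (spikes outside it are invalid).
#'
#' @return An object of class `spike_session`: a list with elements
#'   `session_id`, `trials` (tibble), `spikes` (tibble), `neurons`
#'   (character), `performance`, `epoch`.
#' @examples
#' s <- spike_session(
#'   "demo",
#'   trials = data.frame(trial_index = 1:2, condition = c("GO", "NOGO"),
#'                       outcome = "correct"),
#'   spikes = data.frame(neuron_id = "n1", trial_index = c(1L, 1L, 2L),
#'                       time_ms = c(-250L, 120L, 40L)),
#'   performance = 0.8
#' )
#' s
#' @export
spike_session <- function(session_id, trials, spikes, performance = NA_real_,
                          epoch = c(-1, 1.5)) {
  trials <- as_tibble(trials)
  spikes <- as_tibble(spikes)
  if (!"eot_time_ms" %in% names(trials)) trials$eot_time_ms <- NA_integer_
  trials <- trials[, c("trial_index", "condition", "outcome", "eot_time_ms")]
  trials$trial_index <- as.integer(trials$trial_index)
  if (nrow(spikes) == 0L) {
    spikes <- tibble(neuron_id = character(), trial_index = integer(),
                     time_ms = integer())
  }
  spikes$trial_index <- as.integer(spikes$trial_index)
  spikes$time_ms <- as.integer(round(spikes$time_ms))
  spikes$neuron_id <- as.character(spikes$neuron_id)
  spikes <- spikes[order(spikes$neuron_id, spikes$trial_index,
                         spikes$time_ms), , drop = FALSE]
  out <- structure(
    list(session_id = as.character(session_id)[1],
         trials = trials,
         spikes = spikes[, c("neuron_id", "trial_index", "time_ms")],
         neurons = sort(unique(spikes$neuron_id)),
         performance = as.numeric(performance),
         epoch = as.numeric(epoch)),
    class = "spike_session")
  validate_spike_session(out)
}

#' Validate a spike session's invariants
#'
#' Checks label sets, timestamp monotonicity, trial-table referential
#' integrity and the performance range; returns the session invisibly or
#' aborts with an informative error.
#'
#' @param session A `spike_session`.
#' @return `session`, invisibly usable (returned visibly for chaining).
#' @export
validate_spike_session <- function(session) {
  tr <- session$trials
  sp <- session$spikes
  if (anyDuplicated(tr$trial_index)) {
    abort("duplicated trial_index in trial table", class = "neff_format_error")
  }
  bad_cond <- setdiff(unique(tr$condition), c("GO", "NOGO"))
  if (length(bad_cond)) {
    abort(paste0("invalid condition label(s): ",
                 paste(bad_cond, collapse = ", "),
                 " (allowed: GO, NOGO)"),
          class = "neff_format_error")
  }
  bad_out <- setdiff(unique(tr$outcome), c("correct", "incorrect"))
  if (length(bad_out)) {
    abort(paste0("invalid outcome label(s): ",
                 paste(bad_out, collapse = ", "),
                 " (allowed: correct, incorrect)"),
          class = "neff_format_error")
  }
  if (!is.na(session$performance) &&
      (session$performance < 0 || session$performance > 1)) {
    abort("performance must lie in [0, 1]", class = "neff_validation_error")
  }
  orphan <- setdiff(unique(sp$trial_index), tr$trial_index)
  if (length(orphan)) {
    abort(paste0("spikes reference unknown trial(s): ",
                 paste(orphan, collapse = ", ")),
          class = "neff_validation_error")
  }
  if (nrow(sp)) {
    chk <- sp |>
      group_by(.data$neuron_id, .data$trial_index) |>
      summarise(mono = all(diff(.data$time_ms) > 0), .groups = "drop") |>
      filter(!.data$mono)
    if (nrow(chk)) {
      abort(paste0("non-monotone timestamps for neuron ", chk$neuron_id[1],
                   ", trial ", chk$trial_index[1]),
            class = "neff_validation_error")
    }
    rng <- range(sp$time_ms) / 1000
    if (rng[1] < session$epoch[1] || rng[2] >= session$epoch[2]) {
      abort("spike timestamps fall outside the recorded epoch",
            class = "neff_validation_error")
    }
  }
  session
}

#' @export
print.spike_session <- function(x, ...) {
  cat("<spike_session> ", x$session_id, "\n", sep = "")
  cat("  neurons: ", length(x$neurons),
      "   trials: ", nrow(x$trials),
      "   spikes: ", nrow(x$spikes), "\n", sep = "")
  cat("  epoch: [", x$epoch[1], ", ", x$epoch[2], "] s",
      "   performance: ", x$performance, "\n", sep = "")
  tab <- table(x$trials$condition, x$trials$outcome)
  print(tab)
  invisible(x)
}

# trial indices selected by a pooling rule
trial_pool <- function(session, pool = c("all_correct", "per_condition"),
                       condition = NULL) {
  tr <- session$trials
  keep <- tr$outcome == "correct"
  if (!is.null(condition)) keep <- keep & tr$condition %in% condition
  tr$trial_index[keep]
}
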
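#' Threshold spike detection on a filtered trace
#'
#' Detects putative spikes as excursions of the band-limited voltage trace
#' beyond an amplitude threshold `Thr = k * sigma`, where the noise scale is
#' the median-based robust estimator `sigma = median(|x|) / 0.6745` (the
#' median absolute value of a zero-mean Gaussian equals 0.6745 sigma).
#' Detection operates on `|trace|`; each supra-threshold excursion is
#' collapsed to its first sample, so one index is returned per excursion.
#'
#' @param trace Numeric vector, a single-channel band-limited voltage trace.
#' @param config A [detection_config()].
#' @return Integer vector of sample indices (1-based), one per excursion.
#'   An all-zero trace yields `integer(0)`.
#' @examples
#' x <- rnorm(5000)
#' x[2500] <- 10
#' detect_spikes(x)
#' @export
detect_spikes <- function(trace, config = detection_config()) {
  if (!length(trace)) abort("empty trace", class = "neff_validation_error")
  sigma <- median(abs(trace)) / config$sigma_divisor
  thr <- config$threshold_multiplier * sigma
  above <- abs(trace) > thr
  which(above & !c(FALSE, above[-length(above)]))
}

#' Spike-detection configuration
#'
#' @param threshold_multiplier Threshold in units of the robust noise scale
#'   (default 4, i.e. `Thr = 4 sigma`).
#' @param sigma_divisor Divisor mapping `median(|x|)` to sigma for Gaussian
#'   noise (0.6745).
#' @param band Passband in Hz, metadata only (the detector assumes the
#'   trace is already filtered; see [bandpass_filter()]).
#' @param sampling_rate Samples per second.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold_multiplier = 4,
                             sigma_divisor = 0.6745,
                             band = c(300, 3000),
                             sampling_rate = 30000) {
  stopifnot(threshold_multiplier > 0, sigma_divisor > 0, sampling_rate > 0)
  structure(list(threshold_multiplier = threshold_multiplier,
                 sigma_divisor = sigma_divisor,
                 band = band, sampling_rate = sampling_rate),
            class = "detection_config")
}

#' Zero-phase band-pass filter for extracellular traces
#'
#' Thin convenience wrapper: 4th-order Butterworth, applied forward and
#' backward (`signal::filtfilt`) so the filter adds no phase delay. The
#' detector itself ([detect_spikes()]) does not call this; filtering is the
#' caller's responsibility.
#'
#' @param trace Numeric vector.
#' @param sampling_rate Samples per second.
#' @param band Passband in Hz (default 300-3000 Hz).
#' @return Filtered numeric vector of the same length.
#' @export
bandpass_filter <- function(trace, sampling_rate, band = c(300, 3000)) {
  if (!requireNamespace("signal", quietly = TRUE)) {
    abort("the 'signal' package is required for bandpass_filter()")
  }
  ny <- sampling_rate / 2
  bf <- signal::butter(4, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, trace))
}

# per-(neuron, trial, bin) spike counts on a half-open bin grid
bin_counts <- function(session, bin_width, range, trials_keep) {
  edges <- seq(range[1], range[2], by = bin_width)
  n_bins <- length(edges) - 1L
  sp <- session$spikes |>
    filter(.data$trial_index %in% trials_keep) |>
    mutate(t_s = .data$time_ms / 1000) |>
    filter(.data$t_s >= range[1], .data$t_s < range[2]) |>
    mutate(bin = findInterval(.data$t_s, edges,
                              rightmost.closed = FALSE))
  grid <- crossing(neuron_id = session$neurons,
                   trial_index = trials_keep,
                   bin = seq_len(n_bins))
  cnt <- sp |>
    count(.data$neuron_id, .data$trial_index, .data$bin, name = "count")
  grid |>
    left_join(cnt, by = c("neuron_id", "trial_index", "bin")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L),
           bin_start_s = edges[.data$bin])
}

#' Peristimulus time histogram
#'
#' Bins spikes on a half-open grid `[left, right)` aligned to stimulus onset
#' and converts counts to mean rates: `rate = total spikes in bin /
#' (n_trials * bin_width)`. Correct trials only. Total counts are conserved:
#' `sum(rate) * bin_width * n_trials` equals the number of in-range spikes.
#'
#' @param session A [spike_session()].
#' @param bin_width Bin width in seconds (default 0.010 s).
#' @param range Length-2 numeric, analysis range in seconds.
#' @param group_by_condition If `TRUE` (default) one histogram per
#'   condition; otherwise one pooled histogram (`condition = "all"`).
#' @return A tibble of class `psth`: neuron_id, condition, bin_start_s,
#'   rate_hz, n_trials; attributes `bin_width`, `zscored = FALSE`.
#' @export
compute_psth <- function(session, bin_width = 0.010,
                         range = c(-0.5, 1.5),
                         group_by_condition = TRUE) {
  if (range[1] < session$epoch[1] || range[2] > session$epoch[2]) {
    abort("requested range is not covered by the recorded epoch",
          class = "neff_validation_error")
  }
  groups <- if (group_by_condition) c("GO", "NOGO") else list(c("GO", "NOGO"))
  out <- map(groups, function(cond) {
    keep <- trial_pool(session, condition = cond)
    if (!length(keep)) {
      abort(paste0("no correct trials in group ",
                   paste(cond, collapse = "+")),
            class = "neff_validation_error")
    }
    bin_counts(session, bin_width, range, keep) |>
      group_by(.data$neuron_id, .data$bin_start_s) |>
      summarise(rate_hz = sum(.data$count) / (length(keep) * bin_width),
                .groups = "drop") |>
      mutate(condition = if (length(cond) == 1) cond else "all",
             n_trials = length(keep))
  }) |> list_rbind()
  if (!nrow(out) || !length(session$neurons)) {
    abort("session has no neurons", class = "neff_validation_error")
  }
  structure(out[, c("neuron_id", "condition", "bin_start_s",
                    "rate_hz", "n_trials")],
            bin_width = bin_width, zscored = FALSE, range = range,
            class = c("psth", class(out)))
}

#' Z-scored peristimulus time histogram
#'
#' Per neuron, per-bin spike counts are centred on the mean baseline count
#' and divided by the baseline standard deviation, with baseline statistics
#' pooled across baseline bins and correct trials. Neurons whose baseline
#' is constant (zero variance) cannot be normalised and are dropped with a
#' warning.
#'
#' @inheritParams compute_psth
#' @param bin_width Bin width in seconds (default 0.1 s).
#' @param baseline Length-2 numeric, baseline window in seconds (default
#'   `c(-0.5, 0)`, the pre-stimulus half second).
#' @return A tibble of class `psth` with column `z` instead of `rate_hz`;
#'   attribute `zscored = TRUE`.
#' @export
zscore_psth <- function(session, bin_width = 0.1, range = c(-0.5, 1.5),
                        baseline = c(-0.5, 0), group_by_condition = TRUE) {
  if (baseline[1] < session$epoch[1] || baseline[2] > session$epoch[2]) {
    abort("baseline window outside the recorded epoch",
          class = "neff_validation_error")
  }
  keep <- trial_pool(session)
  if (!length(keep)) {
    abort("no correct trials", class = "neff_validation_error")
  }
  cnt <- bin_counts(session, bin_width, range, keep) |>
    left_join(session$trials[, c("trial_index", "condition")],
              by = "trial_index")
  base <- cnt |>
    filter(.data$bin_start_s >= baseline[1],
           .data$bin_start_s + bin_width <= baseline[2] + 1e-9) |>
    group_by(.data$neuron_id) |>
    summarise(mu = mean(.data$count), sigma = sd(.data$count),
              .groups = "drop")
  dead <- base$neuron_id[base$sigma == 0 | is.na(base$sigma)]
  if (length(dead)) {
    warn(paste0("excluding neuron(s) with constant baseline: ",
                paste(dead, collapse = ", ")))
    base <- filter(base, !.data$neuron_id %in% dead)
  }
  if (!group_by_condition) cnt$condition <- "all"
  out <- cnt |>
    inner_join(base, by = "neuron_id") |>
    group_by(.data$neuron_id, .data$condition, .data$bin_start_s) |>
    summarise(z = (mean(.data$count) - .data$mu[1]) / .data$sigma[1],
              n_trials = n(), .groups = "drop")
  structure(out, bin_width = bin_width, zscored = TRUE, range = range,
            baseline = baseline, class = c("psth", class(out)))
}
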
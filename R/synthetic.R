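#' Synthetic-session specification
#'
#' Parameters of the synthetic spike-session generator. Defaults emulate
#' the statistical regime of rodent prefrontal recordings during an
#' auditory GO/NOGO task: low-baseline, Poisson-like firing (5 Hz), a
#' sustained multiplicative rate increase during the 1 s GO tone, weak
#' pairwise correlations induced by a shared afferent drive, and a
#' mechanical end-of-trial (EoT) relay event after the response window.
#'
#' @param n_neurons Number of simultaneously recorded units.
#' @param n_trials Trials per condition (GO and NOGO each).
#' @param baseline_rate Baseline firing rate, Hz. Either a single mean
#'   rate — each neuron then draws its own baseline from a lognormal
#'   around it (see `rate_sdlog`) — or a vector of per-neuron rates
#'   (recycled to `n_neurons`), in which case no lognormal spread is
#'   added.
#' @param go_gain Multiplicative rate factor during the tone (0-1 s) in GO
#'   trials for tone-excited neurons; NOGO trials are unmodulated.
#' @param rate_sdlog Log-scale SD of the per-neuron baseline-rate spread
#'   (default 0.5; ignored when `baseline_rate` is a vector).
#' @param responsive_fractions Length-2 numeric: fractions of neurons whose
#'   tone response is excitatory (rate times `go_gain`) and suppressive
#'   (rate divided by `go_gain`); the remainder do not respond. Default
#'   `c(0.3, 0.125)`, a minority-responsive cortical population.
#' @param shared_input_fraction In `[0, 1]`; fraction of each neuron's
#'   spikes inherited from a shared mother Poisson process (thinning
#'   construction). The binary-state correlation grows monotonically with
#'   this dial and is 0 at 0.
#' @param trial_epoch Recorded epoch in seconds relative to tone onset;
#'   must contain the 1 s tone. The default is wide enough for the full
#'   pipeline (baseline windows at -1 s and the EoT event).
#' @param performance Per-trial probability of a correct outcome.
#' @param eot_time End-of-trial relay event time, seconds (tone 0-1 s,
#'   2 s response window, so 3 s by default).
#' @param eot_gain Rate factor during the 0.3 s after the EoT event,
#'   applied in a random half of trials (1 = no event modulation).
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_neurons = 20, n_trials = 60,
                           baseline_rate = 5, go_gain = 2,
                           rate_sdlog = 0.5,
                           responsive_fractions = c(0.3, 0.125),
                           shared_input_fraction = 0.2,
                           trial_epoch = c(-1.5, 3.5),
                           performance = 0.85,
                           eot_time = 3.0, eot_gain = 1,
                           seed = 1L) {
  stopifnot(all(baseline_rate >= 0), go_gain > 0, rate_sdlog >= 0,
            length(responsive_fractions) == 2,
            sum(responsive_fractions) <= 1,
            all(responsive_fractions >= 0),
            shared_input_fraction >= 0, shared_input_fraction <= 1,
            performance >= 0, performance <= 1)
  if (trial_epoch[1] > 0 || trial_epoch[2] < 1) {
    abort("epoch too short to contain the 1 s tone",
          class = "neff_validation_error")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# piecewise-constant rate profile for one trial, as (start, end, rate)
rate_segments <- function(spec, condition, eot_modulated, base_rate,
                          tone_gain) {
  ep <- spec$trial_epoch
  brk <- sort(unique(c(ep[1], 0, 1,
                       min(spec$eot_time, ep[2]),
                       min(spec$eot_time + 0.3, ep[2]), ep[2])))
  brk <- brk[brk >= ep[1] & brk <= ep[2]]
  seg <- tibble(start = brk[-length(brk)], end = brk[-1])
  seg$rate <- base_rate
  if (condition == "GO") {
    tone <- seg$start >= 0 & seg$end <= 1
    seg$rate[tone] <- base_rate * tone_gain
  }
  if (eot_modulated && spec$eot_gain != 1) {
    ev <- seg$start >= spec$eot_time - 1e-9 &
      seg$end <= spec$eot_time + 0.3 + 1e-9
    seg$rate[ev] <- seg$rate[ev] * spec$eot_gain
  }
  seg[seg$end > seg$start, ]
}

poisson_times <- function(seg) {
  unlist(lapply(seq_len(nrow(seg)), function(i) {
    n <- rpois(1, seg$rate[i] * (seg$end[i] - seg$start[i]))
    if (n == 0) return(numeric(0))
    runif(n, seg$start[i], seg$end[i])
  }))
}

#' Generate a synthetic trial-structured spike session
#'
#' Inhomogeneous-Poisson spike trains with the structure described in
#' [synthetic_spec()]. Pairwise correlations use the standard
#' shared-mother-process thinning construction: per trial one stationary
#' mother Poisson process at the session-mean baseline rate is drawn, each
#' neuron keeps each mother spike independently with probability
#' `shared_input_fraction`, and tops its train up with an independent
#' inhomogeneous Poisson process at its own profile minus the shared
#' component (clamped at 0), so every neuron's marginal rate follows its
#' profile while coincidences scale with the dial. Timestamps are floored
#' to the 1 ms grid (grid collisions are deduplicated).
#'
#' @param spec A [synthetic_spec()].
#' @return A [spike_session()]. Deterministic given `spec$seed`.
#' @export
generate_spike_session <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed)
  n_tr <- 2L * spec$n_trials
  cond <- rep(c("GO", "NOGO"), each = spec$n_trials)
  cond <- sample(cond)  # interleave conditions
  outcome <- ifelse(runif(n_tr) < spec$performance, "correct", "incorrect")
  eot_mod <- runif(n_tr) < 0.5
  trials <- tibble(trial_index = seq_len(n_tr), condition = cond,
                   outcome = outcome,
                   eot_time_ms = as.integer(round(spec$eot_time * 1000)))
  a <- spec$shared_input_fraction
  n <- spec$n_neurons
  neuron_ids <- sprintf("n%03d", seq_len(n))
  # per-neuron baseline rates and tone-response classes
  if (length(spec$baseline_rate) > 1) {
    base <- rep_len(spec$baseline_rate, n)
  } else if (spec$rate_sdlog > 0) {
    base <- spec$baseline_rate *
      exp(rnorm(n, -spec$rate_sdlog^2 / 2, spec$rate_sdlog))
  } else {
    base <- rep(spec$baseline_rate, n)
  }
  cls <- sample(c("up", "down", "flat"), n, replace = TRUE,
                prob = c(spec$responsive_fractions,
                         1 - sum(spec$responsive_fractions)))
  gain <- c(up = spec$go_gain, down = 1 / spec$go_gain, flat = 1)[cls]
  r0 <- mean(base)          # stationary mother rate
  ep <- spec$trial_epoch
  ep_ms <- round(ep * 1000)
  sp_list <- vector("list", n_tr)
  for (k in seq_len(n_tr)) {
    mother <- if (a > 0) {
      nm <- rpois(1, r0 * (ep[2] - ep[1]))
      runif(nm, ep[1], ep[2])
    } else numeric(0)
    per_neuron <- lapply(seq_len(n), function(i) {
      own_seg <- rate_segments(spec, cond[k], eot_mod[k], base[i], gain[i])
      own_seg$rate <- pmax(own_seg$rate - a * r0, 0)
      keep <- if (length(mother)) mother[runif(length(mother)) < a]
              else numeric(0)
      ts <- c(keep, poisson_times(own_seg))
      ts_ms <- sort(unique(as.integer(floor(ts * 1000))))
      ts_ms <- ts_ms[ts_ms >= ep_ms[1] & ts_ms < ep_ms[2]]
      if (!length(ts_ms)) return(NULL)
      tibble(neuron_id = neuron_ids[i], trial_index = k, time_ms = ts_ms)
    })
    sp_list[[k]] <- list_rbind(per_neuron[!vapply(per_neuron, is.null,
                                                  logical(1))])
  }
  spikes <- list_rbind(sp_list)
  # keep silent neurons on the roster via a session-level override
  s <- spike_session(session_id = sprintf("synth-seed%d", spec$seed),
                     trials = trials, spikes = spikes,
                     performance = mean(outcome == "correct"),
                     epoch = spec$trial_epoch)
  s$neurons <- neuron_ids
  s
}

# local seed scope: set the RNG without clobbering the caller's stream
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
}

#' Draw binary-state ensembles from target pair probability triples
#'
#' For each target triple `(p1i, p1j, p11)` draws `n_trials` independent
#' trials of the two-neuron joint state from the implied 4-cell
#' distribution `P(1,1) = p11`, `P(1,0) = p1i - p11`, `P(0,1) = p1j - p11`,
#' `P(0,0) = 1 - p1i - p1j + p11`. Triples must satisfy the Frechet bounds
#' `max(0, p1i + p1j - 1) <= p11 <= min(p1i, p1j)`.
#'
#' @param triples Data frame with numeric columns `p1i`, `p1j`, `p11` (one
#'   row per pair).
#' @param n_trials Trials to draw per pair.
#' @param seed Integer seed.
#' @return A tibble (pair, trial, state_i, state_j), `pair` indexing rows
#'   of `triples`.
#' @examples
#' generate_binary_pairs(data.frame(p1i = .5, p1j = .5, p11 = .25), 8, seed = 1)
#' @export
generate_binary_pairs <- function(triples, n_trials, seed = 1L) {
  triples <- as_tibble(triples)
  check_triple(triples$p1i, triples$p1j, triples$p11)
  withr_seed(seed)
  map(seq_len(nrow(triples)), function(r) {
    p <- triples[r, ]
    cells <- c(p$p11, p$p1i - p$p11, p$p1j - p$p11,
               1 - p$p1i - p$p1j + p$p11)
    draw <- sample.int(4L, n_trials, replace = TRUE, prob = cells)
    tibble(pair = r, trial = seq_len(n_trials),
           state_i = as.integer(draw %in% c(1L, 2L)),
           state_j = as.integer(draw %in% c(1L, 3L)))
  }) |> list_rbind()
}

check_triple <- function(p1i, p1j, p11) {
  ok <- p1i >= 0 & p1i <= 1 & p1j >= 0 & p1j <= 1 &
    p11 >= pmax(0, p1i + p1j - 1) - 1e-12 &
    p11 <= pmin(p1i, p1j) + 1e-12
  if (!all(ok)) {
    abort(paste0("triple(s) violate the Frechet bounds at row(s): ",
                 paste(which(!ok), collapse = ", ")),
          class = "neff_validation_error")
  }
  invisible(TRUE)
}

#' Write a synthetic deposited-style summary fixture
#'
#' Emulates the two-structure summary deposit that accompanies the raw
#' recordings: a `PSTH` structure (per-neuron average firing rates in 25 ms
#' non-overlapping bins, -0.5 s to 1.5 s from tone onset, GO and NOGO
#' groups) and a `BinaryData` structure (per-neuron binary state per
#' correct trial, 320 ms window centred at +0.5 s). The file is a JSON
#' container readable by [read_deposited_fixture()]. The canonical deposit
#' has 95 cells; other `n_neurons` values are permitted but noted.
#'
#' @param path Output file path.
#' @param spec A [synthetic_spec()]; the deposit layout calls for
#'   `n_neurons = 95`.
#' @return `path`, invisibly. Deterministic given `spec$seed`.
#' @export
generate_fixture_file <- function(path, spec = synthetic_spec(n_neurons = 95)) {
  if (spec$n_neurons != 95) {
    rlang::inform(paste0("fixture generated with ", spec$n_neurons,
                         " neurons (canonical deposit has 95)"))
  }
  s <- generate_spike_session(spec)
  ps <- compute_psth(s, bin_width = 0.025, range = c(-0.5, 1.5))
  edges <- sort(unique(ps$bin_start_s))
  mats <- lapply(c("GO", "NOGO"), function(cc) {
    w <- ps |> filter(.data$condition == cc) |>
      pivot_wider(id_cols = "neuron_id", names_from = "bin_start_s",
                  values_from = "rate_hz") |>
      arrange(.data$neuron_id)
    unname(as.matrix(w[, -1]))
  })
  st <- binarize(s, window_length = 0.32, analysis_times = 0.5)
  sm <- st |>
    pivot_wider(id_cols = "neuron_id", names_from = "trial_index",
                values_from = "state") |>
    arrange(.data$neuron_id)
  tr_idx <- as.integer(names(sm)[-1])
  tr_cond <- s$trials$condition[match(tr_idx, s$trials$trial_index)]
  obj <- list(
    PSTH = list(neuron_id = sort(unique(ps$neuron_id)),
                bin_width_s = 0.025,
                bin_start_s = edges,
                rates_hz = setNames(mats, c("GO", "NOGO")),
                note = "synthetic emulation of the deposited summary"),
    BinaryData = list(neuron_id = sm$neuron_id,
                      trial_index = tr_idx,
                      condition = tr_cond,
                      window_s = 0.32, analysis_time_s = 0.5,
                      states = unname(as.matrix(sm[, -1]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
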
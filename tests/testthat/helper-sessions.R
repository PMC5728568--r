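# hand-built sessions with exactly known spike counts

tiny_session <- function(epoch = c(-1.5, 2)) {
  spike_session(
    "tiny",
    trials = data.frame(trial_index = 1:4,
                        condition = c("GO", "GO", "NOGO", "NOGO"),
                        outcome = "correct"),
    spikes = data.frame(
      neuron_id = rep(c("a", "b"), c(5, 3)),
      trial_index = c(1L, 1L, 2L, 3L, 4L, 1L, 2L, 3L),
      time_ms = c(-250L, 120L, 40L, 500L, -900L, 5L, 300L, -100L)),
    performance = 1, epoch = epoch)
}

# one neuron whose window counts at time 0 (W = 1 s) are exactly `counts`
counted_session <- function(counts, condition = rep("GO", length(counts))) {
  n_tr <- length(counts)
  sp <- do.call(rbind, lapply(seq_len(n_tr), function(k) {
    if (counts[k] == 0) return(NULL)
    data.frame(neuron_id = "u1", trial_index = k,
               time_ms = seq(-400L, 400L, length.out = counts[k]))
  }))
  spike_session(
    "counted",
    trials = data.frame(trial_index = seq_len(n_tr), condition = condition,
                        outcome = "correct"),
    spikes = if (is.null(sp)) data.frame(neuron_id = character(),
                                         trial_index = integer(),
                                         time_ms = integer()) else sp,
    performance = 1, epoch = c(-1.5, 2))
}

# random session for round-trip properties
random_session <- function(n_neurons = 3, n_trials = 6, seed = 7) {
  generate_spike_session(synthetic_spec(
    n_neurons = n_neurons, n_trials = n_trials, baseline_rate = 8,
    seed = seed))
}
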
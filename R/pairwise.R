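#' Closed-form pairwise entropy of a binary neuron pair
#'
#' The joint distribution of two binary states is fully determined by the
#' triple `(p1i, p1j, p11)`; its Shannon entropy is the entropy of the four
#' cell probabilities `{p11, p1i - p11, p1j - p11, 1 - p1i - p1j + p11}`,
#' in bits, with `0 log 0 := 0`. Maximal (2 bits) uniquely at
#' `(0.5, 0.5, 0.25)`; invariant under swapping the two neurons.
#'
#' @param p1i,p1j Marginal active-state probabilities.
#' @param p11 Joint probability that both states are 1. All three are
#'   recycled and must satisfy the Frechet bounds.
#' @return Entropy in bits, in `[0, 2]`.
#' @examples
#' pair_entropy(0.5, 0.5, 0.25)  # 2 bits
#' pair_entropy(0.5, 0.5, 0.5)   # 1 bit
#' @export
pair_entropy <- function(p1i, p1j, p11) {
  check_triple(p1i, p1j, p11)
  q11 <- p11
  q10 <- p1i - p11
  q01 <- p1j - p11
  q00 <- 1 - p1i - p1j + p11
  -(xlog2x(q11) + xlog2x(q10) + xlog2x(q01) + xlog2x(pmax(q00, 0)))
}

#' Closed-form pairwise correlation of a binary neuron pair
#'
#' Pearson correlation of two binary states, written in terms of the
#' probability triple: `rho = (p11 - p1i p1j) / sqrt(p1i (1-p1i) p1j
#' (1-p1j))`. Equals the trial-sum Pearson formula applied to the same
#' data. Zero exactly when the joint factorises (`p11 = p1i p1j`).
#'
#' @inheritParams pair_entropy
#' @return Correlation in `[-1, 1]`. Errors if a marginal is 0 or 1
#'   (degenerate: correlation undefined).
#' @export
pair_correlation <- function(p1i, p1j, p11) {
  check_triple(p1i, p1j, p11)
  if (any(p1i <= 0 | p1i >= 1 | p1j <= 0 | p1j >= 1)) {
    abort("degenerate marginal (0 or 1): correlation undefined",
          class = "neff_validation_error")
  }
  (p11 - p1i * p1j) / sqrt(p1i * (1 - p1i) * p1j * (1 - p1j))
}

#' First-order sampling-bias correction for plug-in entropy
#'
#' The plug-in entropy estimator is biased downward by approximately
#' `(R - 1) / (2 N ln 2)` bits, where `R` is the number of occupied
#' response states (here at most 4) and `N` the number of trials (the
#' first-order analytical correction of Panzeri & Treves). The correction
#' is added to the raw estimate; `R` is counted naively as the number of
#' cells with nonzero empirical probability.
#'
#' @param H_raw Raw plug-in entropy, bits.
#' @param n_occupied_states Occupied cells, in `1..4`.
#' @param n_trials Number of trials `N`.
#' @return Corrected entropy, bits.
#' @examples
#' bias_correct_entropy(1.9, 4, 100) - 1.9  # ~0.0216 bits
#' @export
bias_correct_entropy <- function(H_raw, n_occupied_states, n_trials) {
  if (any(n_occupied_states < 1 | n_occupied_states > 4)) {
    abort("n_occupied_states must be in 1..4",
          class = "neff_validation_error")
  }
  if (any(n_trials < 1)) {
    abort("n_trials must be >= 1", class = "neff_validation_error")
  }
  H_raw + (n_occupied_states - 1) / (2 * n_trials * log(2))
}

#' Empirical probability triple of a neuron pair
#'
#' @param states_i,states_j Binary state vectors of equal length (one entry
#'   per trial).
#' @return One-row tibble: p1i, p1j, p11, n_trials, n_occupied (cells of
#'   the empirical 2 x 2 table with nonzero probability).
#' @examples
#' estimate_pair(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
estimate_pair <- function(states_i, states_j) {
  if (length(states_i) != length(states_j)) {
    abort("state vectors differ in length", class = "neff_validation_error")
  }
  if (!length(states_i)) {
    abort("no trials", class = "neff_validation_error")
  }
  xi <- as.integer(states_i); xj <- as.integer(states_j)
  n <- length(xi)
  n11 <- sum(xi & xj)
  n1i <- sum(xi); n1j <- sum(xj)
  occ <- sum(c(n11, n1i - n11, n1j - n11, n - n1i - n1j + n11) > 0)
  tibble(p1i = n1i / n, p1j = n1j / n, p11 = n11 / n,
         n_trials = n, n_occupied = occ)
}

#' All pairwise probability triples from binarized states
#'
#' Extracts, for one analysis time (and optionally one condition), the
#' `(p1i, p1j, p11)` triple of every neuron pair from a `binary_states`
#' table, plus the occupied-cell count used by the bias correction.
#'
#' @param states A `binary_states` tibble from [binarize()].
#' @param time Analysis time to extract (must match one of the binarized
#'   times).
#' @param condition Optional condition filter (`"GO"` or `"NOGO"`); by
#'   default all binarized (correct) trials are used.
#' @return A tibble: neuron_i, neuron_j, p1i, p1j, p11, n_trials,
#'   n_occupied, analysis_time, condition.
#' @export
pairs_from_states <- function(states, time, condition = NULL) {
  d <- filter(states, abs(.data$analysis_time - time) < 1e-9)
  if (!nrow(d)) {
    abort(paste0("no binarized states at time ", time),
          class = "neff_validation_error")
  }
  cond_lab <- "all"
  if (!is.null(condition)) {
    d <- filter(d, .data$condition == !!condition)
    cond_lab <- condition
  }
  d <- arrange(d, .data$neuron_id, .data$trial_index)
  S <- do.call(cbind, split(d$state, d$neuron_id))
  n <- nrow(S)
  ids <- colnames(S)
  if (length(ids) < 2) {
    abort("need at least 2 neurons for pairs",
          class = "neff_validation_error")
  }
  C11 <- crossprod(S)
  m1 <- colSums(S)
  idx <- which(upper.tri(C11), arr.ind = TRUE)
  n11 <- C11[idx]
  n1i <- m1[idx[, 1]]; n1j <- m1[idx[, 2]]
  occ <- (n11 > 0) + (n1i - n11 > 0) + (n1j - n11 > 0) +
    (n - n1i - n1j + n11 > 0)
  tibble(neuron_i = ids[idx[, 1]], neuron_j = ids[idx[, 2]],
         p1i = n1i / n, p1j = n1j / n, p11 = n11 / n,
         n_trials = n, n_occupied = as.integer(occ),
         analysis_time = time, condition = cond_lab)
}

#' Append entropy and correlation to a pair table
#'
#' Adds the closed-form pairwise entropy `H`, its bias-corrected version
#' `H_corrected` and the pairwise correlation `rho` to a table of
#' probability triples. Pairs with a degenerate marginal get `rho = NA`.
#'
#' @param pairs Tibble with columns p1i, p1j, p11, n_trials, n_occupied
#'   (e.g. from [pairs_from_states()]).
#' @return The input with columns H, H_corrected, rho appended.
#' @export
pair_metrics <- function(pairs) {
  H <- pair_entropy(pairs$p1i, pairs$p1j, pairs$p11)
  deg <- pairs$p1i <= 0 | pairs$p1i >= 1 | pairs$p1j <= 0 | pairs$p1j >= 1
  rho <- rep(NA_real_, nrow(pairs))
  if (any(!deg)) {
    rho[!deg] <- pair_correlation(pairs$p1i[!deg], pairs$p1j[!deg],
                                  pairs$p11[!deg])
  }
  mutate(pairs, H = H,
         H_corrected = bias_correct_entropy(H, pairs$n_occupied,
                                            pairs$n_trials),
         rho = rho)
}

#' Entropy and probability-mass changes between two analysis times
#'
#' For every pair present at both times, computes `delta_H = H(t1) - H(t0)`
#' (bias-corrected at both times) and `delta_p1ij = (p1i(t1) - p1i(t0)) +
#' (p1j(t1) - p1j(t0))`, the summed change in marginal active-state
#' probability — the "cost" a pair pays for its entropy change.
#'
#' @param pairs_t1,pairs_t0 Pair tables from [pairs_from_states()] at the
#'   late and baseline times. Pair identities must match exactly.
#' @return A tibble keyed by (neuron_i, neuron_j) with columns delta_H,
#'   delta_p1ij plus the triples at both times.
#' @export
delta_metrics <- function(pairs_t1, pairs_t0) {
  key <- c("neuron_i", "neuron_j")
  if ("session_id" %in% names(pairs_t1) &&
      "session_id" %in% names(pairs_t0)) {
    key <- c("session_id", key)
  }
  m1 <- pair_metrics(pairs_t1)
  m0 <- pair_metrics(pairs_t0)
  miss <- dplyr::anti_join(m1[key], m0[key], by = key)
  miss2 <- dplyr::anti_join(m0[key], m1[key], by = key)
  if (nrow(miss) || nrow(miss2)) {
    bad <- bind_rows(miss, miss2)
    abort(paste0("pair(s) present at only one time: ",
                 paste(paste(bad$neuron_i, bad$neuron_j, sep = "-"),
                       collapse = ", ")),
          class = "neff_validation_error")
  }
  inner_join(m1, m0, by = key, suffix = c("_t1", "_t0")) |>
    mutate(delta_H = .data$H_corrected_t1 - .data$H_corrected_t0,
           delta_p1ij = (.data$p1i_t1 - .data$p1i_t0) +
             (.data$p1j_t1 - .data$p1j_t0))
}

#' Pairwise entropy/cost changes of a binarized session
#'
#' Convenience pipeline: extract the pair triples at a baseline time `t0`
#' and an analysis time `t1` (default -1 s and +0.5 s from tone onset) for
#' one condition's correct trials and return the per-pair `delta_H` and
#' `delta_p1ij` table that the efficiency regression consumes.
#'
#' @param states A `binary_states` tibble from [binarize()] containing both
#'   `t0` and `t1` among its analysis times.
#' @param t0 Baseline time, seconds (default -1).
#' @param t1 Analysis time, seconds (default 0.5).
#' @param condition Condition to analyse (default `"GO"`); `NULL` pools.
#' @return See [delta_metrics()].
#' @export
pair_deltas <- function(states, t0 = -1, t1 = 0.5, condition = "GO") {
  delta_metrics(pairs_from_states(states, t1, condition),
                pairs_from_states(states, t0, condition))
}
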
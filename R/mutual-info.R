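# plug-in mutual information (bits) between columns of a binary state
# matrix and a two-level label vector
mi_plugin_matrix <- function(S, is_go) {
  n <- nrow(S)
  ng <- sum(is_go); nn <- n - ng
  a <- colSums(S[is_go, , drop = FALSE])   # x = 1, s = GO
  b <- colSums(S[!is_go, , drop = FALSE])  # x = 1, s = NOGO
  cells <- rbind(a, ng - a, b, nn - b) / n
  px1 <- (a + b) / n
  marg <- rbind(px1 * ng / n, (1 - px1) * ng / n,
                px1 * nn / n, (1 - px1) * nn / n)
  term <- ifelse(cells > 0, cells * log2(cells / marg), 0)
  # plug-in MI is non-negative; clamp float dust from the summation
  pmax(colSums(term), 0)
}

#' Stimulus mutual information of a binary neuron state
#'
#' Plug-in mutual information `I(X, S)` between a neuron's binary state and
#' the stimulus label set `{GO, NOGO}`, computed from the empirical 2 x 2
#' joint distribution, with a shuffle-based bias estimate: the labels are
#' permuted `n_shuffles` times, the mean shuffled information is taken as
#' the small-sample bias, and the corrected value is the raw value minus
#' that bias. The corrected estimate may be slightly negative — that is
#' informative noise and is not clipped. The raw plug-in value is always
#' non-negative.
#'
#' @param states Binary vector (one entry per trial), or a trials x neurons
#'   matrix for many neurons at once.
#' @param labels Character/factor vector with two levels (`"GO"`/`"NOGO"`),
#'   aligned with the trial axis. Both labels must be present.
#' @param n_shuffles Number of label permutations for the bias estimate
#'   (default 30).
#' @param seed Optional integer seed for the permutation stream.
#' @return A tibble with one row per neuron: `I_raw`, `bias`, `I` (bits,
#'   corrected). For a vector input the tibble has one row.
#' @examples
#' st <- c(1, 1, 1, 0, 0, 0)
#' mutual_information(st, c("GO", "GO", "GO", "NOGO", "NOGO", "NOGO"))
#' @export
mutual_information <- function(states, labels, n_shuffles = 30, seed = NULL) {
  S <- if (is.matrix(states)) states else matrix(as.integer(states), ncol = 1)
  labels <- as.character(labels)
  if (nrow(S) != length(labels)) {
    abort("states and labels differ in length",
          class = "neff_validation_error")
  }
  lv <- unique(labels)
  if (length(lv) != 2) {
    abort(paste0("need exactly two label levels, got: ",
                 paste(lv, collapse = ", ")),
          class = "neff_validation_error")
  }
  is_go <- labels == if ("GO" %in% lv) "GO" else lv[1]
  if (!is.null(seed)) withr_seed(seed)
  raw <- mi_plugin_matrix(S, is_go)
  bias <- rep(0, ncol(S))
  for (s in seq_len(n_shuffles)) {
    bias <- bias + mi_plugin_matrix(S, sample(is_go))
  }
  bias <- bias / n_shuffles
  tibble(neuron = seq_len(ncol(S)), I_raw = raw, bias = bias,
         I = raw - bias)
}

#' Select the analysis window by mutual information
#'
#' Sweeps window lengths and window centres, computing each neuron's
#' bias-corrected stimulus information at every (window, time) point from
#' correct trials, and averages over neurons and times to one `<I>` per
#' window length. The chosen window is the shortest whose `<I>` reaches
#' `fraction` (default 80%) of the best `<I>` over the sweep — short enough
#' for temporal resolution, long enough for a reliable pairwise code.
#' Corrected values are averaged (bias correction applied per neuron
#' before averaging).
#'
#' @param session A [spike_session()].
#' @param windows Window lengths to try, seconds (default 0.10-0.60 s in
#'   20 ms steps).
#' @param times Window centres, seconds (default 0-0.5 s in 50 ms steps).
#' @param fraction Fraction of the maximal `<I>` that qualifies a window.
#' @param n_shuffles Label shuffles per point for the bias estimate.
#' @param seed Integer seed for the shuffle stream.
#' @param pool Threshold pool passed to [binarize()].
#' @return An object of class `mi_curve`: list with `window` (chosen
#'   length, seconds), `summary` (tibble window, I_mean), `curve` (tibble
#'   window, time, I_mean across neurons) and `fraction`.
#' @export
select_window <- function(session,
                          windows = seq(0.10, 0.60, by = 0.02),
                          times = seq(0, 0.5, by = 0.05),
                          fraction = 0.8, n_shuffles = 30, seed = 1L,
                          pool = "all_correct") {
  stopifnot(length(windows) >= 1, length(times) >= 1,
            fraction > 0, fraction <= 1)
  windows <- sort(windows)
  withr_seed(seed)
  curve <- map(windows, function(W) {
    st <- binarize(session, W, times, pool = pool)
    map(times, function(tt) {
      d <- filter(st, .data$analysis_time == tt)
      # rows are trials: d is sorted by neuron then trial within each time
      S <- do.call(cbind, split(d$state, d$neuron_id))
      lab <- d$condition[match(sort(unique(d$trial_index)), d$trial_index)]
      mi <- mutual_information(S, lab, n_shuffles = n_shuffles)
      tibble(window = W, time = tt, I_mean = mean(mi$I),
             I_raw_mean = mean(mi$I_raw))
    }) |> list_rbind()
  }) |> list_rbind()
  summ <- curve |>
    group_by(.data$window) |>
    summarise(I_mean = mean(.data$I_mean), .groups = "drop")
  best <- max(summ$I_mean)
  ok <- summ$window[summ$I_mean >= fraction * best]
  chosen <- if (length(ok)) min(ok) else summ$window[which.max(summ$I_mean)]
  structure(list(window = chosen, summary = summ, curve = curve,
                 fraction = fraction),
            class = "mi_curve")
}

#' @export
print.mi_curve <- function(x, ...) {
  cat("<mi_curve> chosen window:", x$window * 1000, "ms",
      sprintf("(>= %.0f%% of max <I> = %.4f bits)\n",
              100 * x$fraction, max(x$summary$I_mean)))
  invisible(x)
}

#' Spearman correlation between p1 and firing rate
#'
#' Rank correlation between each neuron's active-state probability and its
#' mean firing rate in the matched analysis window — the binary code
#' tracks rate, saturating towards `p1 = 0.5` at high rates.
#'
#' @param p1 Numeric vector of per-neuron `p1` estimates.
#' @param rate Numeric vector of matched mean firing rates (Hz).
#' @return Spearman's rho.
#' @export
p1_rate_correlation <- function(p1, rate) {
  if (length(p1) != length(rate) || length(p1) < 3) {
    abort("need >= 3 matched (p1, rate) observations",
          class = "neff_validation_error")
  }
  if (sd(p1) == 0 || sd(rate) == 0) {
    abort("constant vector: Spearman correlation undefined",
          class = "neff_validation_error")
  }
  cor(p1, rate, method = "spearman")
}
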
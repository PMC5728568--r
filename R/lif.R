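#' Two-neuron leaky integrate-and-fire configuration
#'
#' Parameters of the reciprocally coupled LIF pair. Each model neuron
#' obeys `tau dV/dt = E_rest - V` between inputs; every afferent spike
#' shifts the membrane instantaneously by `w_ex` or `w_inh`, every partner
#' spike by `W_r` (delta-pulse synapses, so no continuous current is
#' integrated). Each neuron receives 500 afferents (400 excitatory, 100
#' inhibitory, independent Poisson at `lambda_ex` / `lambda_inh`); 40 of
#' them (32 excitatory + 8 inhibitory, keeping the 4:1 ratio) form a
#' common pool projecting to both neurons. Integration is forward Euler at
#' `dt = 0.1 ms`; on `V >= V_threshold` a spike is emitted and `V` is set
#' to `V_reset`. There is no refractory period; `V_peak` is cosmetic.
#'
#' @param W_r Reciprocal synaptic weight, mV.
#' @param lambda_ex Excitatory afferent rate, Hz.
#' @param lambda_inh Inhibitory afferent rate, Hz (default 20).
#' @param w_ex,w_inh Afferent jump sizes, mV (defaults +10, -20).
#' @param E_rest,V_reset,V_threshold Membrane potentials, mV (defaults
#'   -70, -80, -55).
#' @param tau Membrane time constant, ms (default 10).
#' @param n_ex,n_inh Afferent population sizes (400, 100).
#' @param n_common Size of the shared pool (default 40, split 4:1).
#' @param dt Euler step, ms (default 0.1).
#' @param trial_length Trial duration, ms (default 300).
#' @param n_trials Trials per simulation (default 200).
#' @param seed Integer seed.
#' @return A list of class `lif_config`.
#' @export
lif_config <- function(W_r = 4, lambda_ex = 5, lambda_inh = 20,
                       w_ex = 10, w_inh = -20,
                       E_rest = -70, V_reset = -80, V_threshold = -55,
                       tau = 10, n_ex = 400, n_inh = 100, n_common = 40,
                       dt = 0.1, trial_length = 300, n_trials = 200,
                       seed = 1L) {
  stopifnot(V_reset < V_threshold, dt > 0, tau > 0,
            lambda_ex >= 0, lambda_inh >= 0, n_trials >= 1)
  n_ex_com <- round(n_common * n_ex / (n_ex + n_inh))
  n_inh_com <- n_common - n_ex_com
  if (n_ex_com > n_ex || n_inh_com > n_inh) {
    abort("n_common larger than the afferent population",
          class = "neff_validation_error")
  }
  structure(
    list(W_r = W_r, lambda_ex = lambda_ex, lambda_inh = lambda_inh,
         w_ex = w_ex, w_inh = w_inh, E_rest = E_rest, V_reset = V_reset,
         V_threshold = V_threshold, tau = tau, n_ex = n_ex, n_inh = n_inh,
         n_ex_com = n_ex_com, n_inh_com = n_inh_com,
         dt = dt, trial_length = trial_length, n_trials = n_trials,
         seed = as.integer(seed)),
    class = "lif_config")
}

#' Simulate the coupled LIF pair
#'
#' Runs `config$n_trials` independent trials and returns the per-trial
#' spike counts of the two neurons. Deterministic given `config$seed`.
#'
#' @param config A [lif_config()].
#' @return Tibble (trial, n1, n2) of spike counts.
#' @examples
#' simulate_pair(lif_config(n_trials = 5, seed = 42))
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "lif_config"))
  withr_seed(config$seed)
  m <- lif_pair_counts(
    config$n_trials, config$trial_length, config$dt, config$tau,
    config$E_rest, config$V_reset, config$V_threshold,
    config$w_ex, config$w_inh, config$W_r,
    config$n_ex - config$n_ex_com, config$n_inh - config$n_inh_com,
    config$n_ex_com, config$n_inh_com,
    config$lambda_ex, config$lambda_inh)
  tibble(trial = seq_len(nrow(m)), n1 = m[, 1], n2 = m[, 2])
}

#' Binarize model spike counts into a pair probability triple
#'
#' Each neuron's state per trial is 1 when its whole-trial spike count
#' strictly exceeds its across-trials mean (identical tie rule to the data
#' pipeline, so all-equal counts give all-zero states).
#'
#' @param counts Tibble from [simulate_pair()] (columns n1, n2).
#' @return One-row tibble from [estimate_pair()]: p1i, p1j, p11, n_trials,
#'   n_occupied.
#' @export
binarize_model_trials <- function(counts) {
  if (nrow(counts) < 2) {
    abort("need at least 2 trials", class = "neff_validation_error")
  }
  estimate_pair(as.integer(counts$n1 > mean(counts$n1)),
                as.integer(counts$n2 > mean(counts$n2)))
}

lif_point_metrics <- function(config) {
  cnt <- simulate_pair(config)
  p <- binarize_model_trials(cnt)
  H <- pair_entropy(p$p1i, p$p1j, p$p11)
  tibble(p1i = p$p1i, p1j = p$p1j, p11 = p$p11,
         H = H,
         H_corrected = bias_correct_entropy(H, p$n_occupied, p$n_trials),
         p1ij = p$p1i + p$p1j,
         rate1 = mean(cnt$n1) / (config$trial_length / 1000),
         rate2 = mean(cnt$n2) / (config$trial_length / 1000))
}

#' Sweep the (W_r, lambda_ex) plane
#'
#' Simulates the pair at every grid point (independent seeds derived from
#' `config$seed`), binarizes, and records the bias-corrected pairwise
#' entropy, the summed marginal probability `p1ij = p1i + p1j` and the
#' firing rates — the surfaces whose level curves expose the
#' entropy-vs-cost trade-off.
#'
#' @param config A [lif_config()] template (its `W_r`/`lambda_ex` are
#'   overridden).
#' @param Wr_grid Reciprocal weights, mV (default 0-8 in 1 mV steps).
#' @param lambdaEx_grid Afferent rates, Hz (default 1-10 in 1 Hz steps).
#' @return A tibble of class `lif_sweep`: W_r, lambda_ex, H, H_corrected,
#'   p1ij, rate1, rate2, seed.
#' @export
lif_sweep <- function(config = lif_config(),
                      Wr_grid = seq(0, 8, by = 1),
                      lambdaEx_grid = seq(1, 10, by = 1)) {
  stopifnot(length(Wr_grid) >= 1, length(lambdaEx_grid) >= 1)
  grid <- crossing(W_r = Wr_grid, lambda_ex = lambdaEx_grid)
  out <- map(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$W_r <- grid$W_r[i]
    cfg$lambda_ex <- grid$lambda_ex[i]
    cfg$seed <- config$seed + i
    mutate(lif_point_metrics(cfg), W_r = cfg$W_r,
           lambda_ex = cfg$lambda_ex, seed = cfg$seed)
  }) |> list_rbind()
  structure(out[, c("W_r", "lambda_ex", "H", "H_corrected", "p1ij",
                    "rate1", "rate2", "seed")],
            Wr_grid = sort(unique(Wr_grid)),
            lambdaEx_grid = sort(unique(lambdaEx_grid)),
            class = c("lif_sweep", class(out)))
}

#' Level curves of a sweep surface
#'
#' Marching-squares contours (via `grDevices::contourLines`) of the
#' entropy or `p1ij` surface in the (W_r, lambda_ex) plane. Levels outside
#' the surface range yield no contour (with a note).
#'
#' @param sweep A [lif_sweep()] result.
#' @param levels Numeric contour levels.
#' @param surface `"entropy"` (bias-corrected) or `"p1ij"`.
#' @return Tibble: surface, level, curve (polyline id), W_r, lambda_ex.
#' @export
level_curves <- function(sweep, levels, surface = c("entropy", "p1ij")) {
  surface <- match.arg(surface)
  xg <- attr(sweep, "Wr_grid"); yg <- attr(sweep, "lambdaEx_grid")
  col <- if (surface == "entropy") "H_corrected" else "p1ij"
  z <- matrix(NA_real_, length(xg), length(yg))
  z[cbind(match(sweep$W_r, xg), match(sweep$lambda_ex, yg))] <- sweep[[col]]
  if (anyNA(z)) abort("sweep does not cover the full grid",
                      class = "neff_validation_error")
  out_of_range <- levels[levels < min(z) | levels > max(z)]
  if (length(out_of_range)) {
    rlang::inform(paste0("level(s) outside surface range: ",
                         paste(signif(out_of_range, 3), collapse = ", ")))
  }
  cl <- grDevices::contourLines(x = xg, y = yg, z = z, levels = levels)
  if (!length(cl)) {
    return(tibble(surface = character(), level = numeric(),
                  curve = integer(), W_r = numeric(),
                  lambda_ex = numeric()))
  }
  imap(cl, function(cc, i) {
    tibble(surface = surface, level = cc$level, curve = as.integer(i),
           W_r = cc$x, lambda_ex = cc$y)
  }) |> list_rbind()
}

exact_sign_test <- function(diffs) {
  nz <- diffs[diffs != 0]
  if (!length(nz)) return(1)
  binom.test(sum(nz > 0), length(nz), p = 0.5,
             alternative = "two.sided")$p.value
}

#' Entropy and efficiency along a parameter trajectory
#'
#' Evaluates an ordered list of (W_r, lambda_ex) points with `n_reps`
#' independent repetitions of `n_trials`-trial simulations per point. Per
#' repetition, the model's efficiency between consecutive points is the
#' ratio `delta_H / delta_p1ij` (repetitions where `delta_p1ij` is exactly
#' 0 are excluded and counted). Consecutive points are compared with exact
#' two-sided sign tests across the paired repetitions, for entropy and for
#' segment efficiency.
#'
#' @param points Data frame with columns `W_r` and `lambda_ex`, in
#'   trajectory order (>= 2 rows).
#' @param config A [lif_config()] template.
#' @param n_reps Independent repetitions (default 30).
#' @return A list of class `lif_trajectory`: `per_rep` (rep, point, H,
#'   p1ij), `points`, `entropy` (per-point medians and consecutive-point
#'   sign-test p), `efficiency` (per-segment median `delta_H/delta_p1ij`,
#'   exclusion count, consecutive-segment sign-test p).
#' @export
evaluate_trajectory <- function(points, config = lif_config(),
                                n_reps = 30) {
  points <- as_tibble(points)
  if (nrow(points) < 2) {
    abort("need at least 2 trajectory points",
          class = "neff_validation_error")
  }
  per_rep <- map(seq_len(n_reps), function(r) {
    map(seq_len(nrow(points)), function(k) {
      cfg <- config
      cfg$W_r <- points$W_r[k]
      cfg$lambda_ex <- points$lambda_ex[k]
      cfg$seed <- config$seed + 10000L * r + k
      m <- lif_point_metrics(cfg)
      tibble(rep = r, point = k, H = m$H_corrected, p1ij = m$p1ij)
    }) |> list_rbind()
  }) |> list_rbind()
  wide_H <- pivot_wider(per_rep, id_cols = "rep", names_from = "point",
                        values_from = "H")
  wide_P <- pivot_wider(per_rep, id_cols = "rep", names_from = "point",
                        values_from = "p1ij")
  n_pts <- nrow(points)
  entropy <- tibble(
    point = seq_len(n_pts),
    H_median = vapply(seq_len(n_pts),
                      function(k) median(wide_H[[as.character(k)]]),
                      numeric(1)))
  entropy$p_vs_prev <- c(NA_real_, vapply(2:n_pts, function(k) {
    exact_sign_test(wide_H[[as.character(k)]] -
                      wide_H[[as.character(k - 1)]])
  }, numeric(1)))
  segs <- map(seq_len(n_pts - 1), function(k) {
    dH <- wide_H[[as.character(k + 1)]] - wide_H[[as.character(k)]]
    dP <- wide_P[[as.character(k + 1)]] - wide_P[[as.character(k)]]
    keep <- dP != 0
    tibble(segment = k, from = k, to = k + 1,
           E_values = list((dH / dP)[keep]),
           E_median = median((dH / dP)[keep]),
           n_excluded = sum(!keep))
  }) |> list_rbind()
  if (any(segs$n_excluded > 0)) {
    rlang::inform(paste0("repetitions with delta_p1ij = 0 excluded from ",
                         "efficiency: ", sum(segs$n_excluded)))
  }
  segs$p_vs_prev <- c(NA_real_,
    if (nrow(segs) > 1) vapply(2:nrow(segs), function(k) {
      a <- segs$E_values[[k]]; b <- segs$E_values[[k - 1]]
      m <- min(length(a), length(b))
      exact_sign_test(a[seq_len(m)] - b[seq_len(m)])
    }, numeric(1)) else NULL)
  structure(list(per_rep = per_rep, points = points, entropy = entropy,
                 efficiency = segs, n_reps = n_reps),
            class = "lif_trajectory")
}

#' @export
print.lif_trajectory <- function(x, ...) {
  cat("<lif_trajectory>", nrow(x$points), "points,", x$n_reps, "reps\n")
  print(select(x$entropy, "point", "H_median", "p_vs_prev"))
  print(select(x$efficiency, "segment", "E_median", "n_excluded",
               "p_vs_prev"))
  invisible(x)
}
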
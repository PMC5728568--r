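#' Marginal-preserving surrogate null for the coincidence structure
#'
#' Tests whether the observed efficiency (and mean entropy/correlation)
#' depends on the specific pairing of coincidence probabilities with
#' marginals, by permuting the coincidence coefficients
#' `f = p11 / (p1i p1j)` among pairs. For each of `n_surrogates`
#' surrogates, `f` values are randomly permuted among the pairs of each
#' session (never across sessions) and stimulus-period coincidences are
#' rewritten as `p11* = f_perm * p1i * p1j`. Nothing else moves: baseline
#' triples and all marginals — hence every `delta_p1ij` — are preserved
#' exactly. `delta_H*` and the efficiency slope `E*` are recomputed per
#' surrogate, and one-sided empirical p-values use the `(r + 1) / (n + 1)`
#' convention for the hypothesis that the observed value is *higher* than
#' chance.
#'
#' A permuted `f` can push `p11*` outside the Frechet bounds implied by the
#' (fixed) marginals; such draws are clipped to the nearest bound and the
#' clip rate is reported. Sessions contributing a single pair can only map
#' to themselves and are noted.
#'
#' @param deltas A [delta_metrics()]/[pair_deltas()] table (suffixes `_t1`
#'   stimulus, `_t0` baseline). An optional `session_id` column scopes the
#'   permutation; without it all pairs are treated as one session.
#' @param n_surrogates Number of surrogates (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param intercept Passed to the efficiency slope (default `TRUE`).
#' @param keep_draws If `TRUE`, store the per-surrogate `p11*` draws (an
#'   `n_surrogates` x `n_pairs` matrix) for auditing the preservation
#'   invariants; off by default to save memory.
#' @return An object of class `surrogate_ensemble`: observed E/H/rho,
#'   vectors `E_star`, `H_star`, `rho_star`, one-sided `p_values`,
#'   `clip_rate`, `n_surrogates`, `seed` (and `p11_star` when
#'   `keep_draws = TRUE`). Supports [tidy()], [glance()], [autoplot()].
#' @export
surrogate_null <- function(deltas, n_surrogates = 1000, seed = 1L,
                           intercept = TRUE, keep_draws = FALSE) {
  d <- as_tibble(deltas)
  if (!"session_id" %in% names(d)) d$session_id <- "s1"
  if (nrow(d) < 2) {
    abort("need at least 2 pairs overall", class = "neff_validation_error")
  }
  singles <- names(which(table(d$session_id) == 1))
  if (length(singles)) {
    rlang::inform(paste0("session(s) with a single pair contribute only ",
                         "identity permutations: ",
                         paste(singles, collapse = ", ")))
  }
  p_ind <- d$p1i_t1 * d$p1j_t1
  f <- ifelse(p_ind > 0, d$p11_t1 / p_ind, 1)
  lo <- pmax(0, d$p1i_t1 + d$p1j_t1 - 1)
  hi <- pmin(d$p1i_t1, d$p1j_t1)
  H0_corr <- d$H_corrected_t0
  obs_fit_E <- if (intercept) slope_ols(d$delta_p1ij, d$delta_H)
               else sum(d$delta_p1ij * d$delta_H) / sum(d$delta_p1ij^2)
  obs_H <- mean(d$H_corrected_t1)
  obs_rho <- mean(d$rho_t1, na.rm = TRUE)
  ses <- split(seq_len(nrow(d)), d$session_id)
  withr_seed(seed)
  E_star <- H_star <- rho_star <- numeric(n_surrogates)
  p11_mat <- if (keep_draws) {
    matrix(NA_real_, n_surrogates, nrow(d))
  }
  n_clip <- 0L
  for (s in seq_len(n_surrogates)) {
    f_perm <- f
    for (ii in ses) {
      if (length(ii) > 1) f_perm[ii] <- f[ii][sample.int(length(ii))]
    }
    p11s <- f_perm * p_ind
    clip <- p11s < lo | p11s > hi
    n_clip <- n_clip + sum(clip)
    p11s <- pmin(pmax(p11s, lo), hi)
    if (keep_draws) p11_mat[s, ] <- p11s
    H1 <- pair_entropy(d$p1i_t1, d$p1j_t1, p11s)
    occ <- (p11s > 0) + (d$p1i_t1 - p11s > 0) + (d$p1j_t1 - p11s > 0) +
      (1 - d$p1i_t1 - d$p1j_t1 + p11s > 0)
    H1c <- bias_correct_entropy(H1, pmax(occ, 1), d$n_trials_t1)
    dH <- H1c - H0_corr
    E_star[s] <- if (intercept) slope_ols(d$delta_p1ij, dH)
                 else sum(d$delta_p1ij * dH) / sum(d$delta_p1ij^2)
    H_star[s] <- mean(H1c)
    deg <- d$p1i_t1 <= 0 | d$p1i_t1 >= 1 | d$p1j_t1 <= 0 | d$p1j_t1 >= 1
    rr <- rep(NA_real_, nrow(d))
    if (any(!deg)) {
      rr[!deg] <- pair_correlation(d$p1i_t1[!deg], d$p1j_t1[!deg],
                                   p11s[!deg])
    }
    rho_star[s] <- mean(rr, na.rm = TRUE)
  }
  p_one <- function(star, obs) (sum(star >= obs) + 1) / (n_surrogates + 1)
  structure(
    list(observed = list(E = obs_fit_E, H = obs_H, rho = obs_rho),
         E_star = E_star, H_star = H_star, rho_star = rho_star,
         p_values = list(E = p_one(E_star, obs_fit_E),
                         H = p_one(H_star, obs_H),
                         rho = p_one(rho_star, obs_rho)),
         clip_rate = n_clip / (n_surrogates * nrow(d)),
         p11_star = p11_mat, pair_table = d,
         n_surrogates = n_surrogates, n_pairs = nrow(d), seed = seed),
    class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d surrogates, %d pairs\n",
              x$n_surrogates, x$n_pairs))
  cat(sprintf("  observed E = %.3f (p = %.4f), mean H = %.3f (p = %.4f)\n",
              x$observed$E, x$p_values$E, x$observed$H, x$p_values$H))
  cat(sprintf("  clip rate = %.3f\n", x$clip_rate))
  invisible(x)
}

#' @rdname surrogate_null
#' @param x,object A `surrogate_ensemble`.
#' @param ... Unused.
#' @export
tidy.surrogate_ensemble <- function(x, ...) {
  tibble(surrogate = seq_len(x$n_surrogates),
         E_star = x$E_star, H_star = x$H_star, rho_star = x$rho_star)
}

#' @rdname surrogate_null
#' @export
glance.surrogate_ensemble <- function(x, ...) {
  tibble(E = x$observed$E, p_E = x$p_values$E,
         H = x$observed$H, p_H = x$p_values$H,
         rho = x$observed$rho, p_rho = x$p_values$rho,
         clip_rate = x$clip_rate,
         n_surrogates = x$n_surrogates, n_pairs = x$n_pairs)
}
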
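test_that("closed-form entropy equals brute-force summation on a dense grid", {
  # independent oracle: enumerate the four joint states explicitly
  brute_H <- function(p1i, p1j, p11) {
    pr <- c(`11` = p11, `10` = p1i - p11, `01` = p1j - p11,
            `00` = 1 - p1i - p1j + p11)
    pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }
  grid <- expand.grid(p1i = seq(0.05, 0.95, by = 0.09),
                      p1j = seq(0.05, 0.95, by = 0.09))
  worst <- 0
  for (r in seq_len(nrow(grid))) {
    lo <- max(0, grid$p1i[r] + grid$p1j[r] - 1)
    hi <- min(grid$p1i[r], grid$p1j[r])
    for (p11 in seq(lo, hi, length.out = 7)) {
      worst <- max(worst, abs(pair_entropy(grid$p1i[r], grid$p1j[r], p11) -
                                brute_H(grid$p1i[r], grid$p1j[r], p11)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("entropy takes its landmark values and symmetries", {
  expect_equal(pair_entropy(0.5, 0.5, 0.25), 2)
  expect_equal(pair_entropy(0.5, 0.5, 0.5), 1)
  expect_equal(pair_entropy(0.3, 0.4, 0.2), 1.76096405, tolerance = 1e-7)
  # swap symmetry and the unique maximum
  set.seed(2)
  for (r in 1:20) {
    a <- runif(1); b <- runif(1)
    p11 <- runif(1, max(0, a + b - 1), min(a, b))
    expect_equal(pair_entropy(a, b, p11), pair_entropy(b, a, p11))
    if (abs(a - 0.5) + abs(b - 0.5) + abs(p11 - 0.25) > 0.05) {
      expect_lt(pair_entropy(a, b, p11), 2)
    }
  }
  expect_error(pair_entropy(0.3, 0.4, 0.45), class = "neff_validation_error")
})

test_that("closed-form correlation equals the trial-sum Pearson formula", {
  set.seed(4)
  worst <- 0
  for (r in 1:1000) {
    n <- sample(20:80, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (var(x) == 0 || var(y) == 0) next
    p <- estimate_pair(x, y)
    worst <- max(worst, abs(pair_correlation(p$p1i, p$p1j, p$p11) -
                              cor(x, y)))
  }
  expect_lt(worst, 1e-12)
})

test_that("correlation landmarks: independence, coupling, known triple", {
  expect_equal(pair_correlation(0.3, 0.4, 0.12), 0)
  expect_equal(pair_correlation(0.5, 0.5, 0.5), 1)
  expect_equal(pair_correlation(0.3, 0.4, 0.2), 0.35634832, tolerance = 1e-7)
  expect_error(pair_correlation(0, 0.4, 0), class = "neff_validation_error")
})

test_that("empirical pair estimation counts the four cells correctly", {
  p <- estimate_pair(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(c(p$p1i, p$p1j, p$p11), c(0.5, 0.5, 0.25))
  expect_equal(p$n_occupied, 4L)
  x <- c(1, 1, 0, 0)
  p2 <- estimate_pair(x, x)
  expect_equal(p2$p11, p2$p1i)
  expect_error(estimate_pair(1:3, 1:2), class = "neff_validation_error")
  set.seed(6)
  d <- generate_binary_pairs(data.frame(p1i = .3, p1j = .4, p11 = .2),
                             1e5, seed = 44)
  p3 <- estimate_pair(d$state_i, d$state_j)
  expect_lt(abs(p3$p1i - 0.3), 0.005)
  expect_lt(abs(p3$p1j - 0.4), 0.005)
  expect_lt(abs(p3$p11 - 0.2), 0.005)
})

test_that("the entropy bias correction matches its analytic form and the
           Monte-Carlo plug-in bias", {
  expect_equal(bias_correct_entropy(1, 1, 50), 1)           # R = 1 -> 0
  expect_equal(bias_correct_entropy(0, 4, 100) , 3 / (200 * log(2)),
               tolerance = 1e-12)                           # ~0.02164
  # oracle: mean plug-in bias over multinomial resamples of a known
  # 4-state distribution is approximately (R - 1) / (2 N ln 2)
  pr <- c(0.3, 0.3, 0.2, 0.2)
  H_true <- -sum(pr * log2(pr))
  N <- 100
  set.seed(10)
  plug <- replicate(1e4, {
    cnt <- as.vector(rmultinom(1, N, pr))
    q <- cnt[cnt > 0] / N
    -sum(q * log2(q))
  })
  mc_bias <- H_true - mean(plug)
  analytic <- (4 - 1) / (2 * N * log(2))
  expect_lt(abs(mc_bias - analytic) / analytic, 0.15)
  expect_error(bias_correct_entropy(1, 5, 10),
               class = "neff_validation_error")
})

test_that("bias corrections on matched synthetic sessions stay small", {
  # with ~10^2 trials the correction is a few percent of raw entropy
  spec <- synthetic_spec(n_neurons = 6, n_trials = 50, seed = 3)
  st <- binarize(generate_spike_session(spec), 0.32, 0.5)
  pm <- pair_metrics(pairs_from_states(st, 0.5))
  rel <- (pm$H_corrected - pm$H) / pm$H
  expect_true(all(rel > 0 & rel < 0.06))
})

test_that("delta metrics subtract matched pairs and error on mismatches", {
  mk <- function(p1i, p1j, p11, n = 100) {
    tibble::tibble(neuron_i = "a", neuron_j = "b", p1i = p1i, p1j = p1j,
                   p11 = p11, n_trials = n, n_occupied = 4L)
  }
  d <- delta_metrics(mk(0.5, 0.5, 0.25), mk(0.5, 0.5, 0.5))
  expect_equal(d$delta_H, 1)       # corrections cancel at matched n, R
  expect_equal(d$delta_p1ij, 0)
  same <- delta_metrics(mk(0.4, 0.3, 0.2), mk(0.4, 0.3, 0.2))
  expect_equal(same$delta_H, 0)
  expect_equal(same$delta_p1ij, 0)
  bad <- mk(0.4, 0.3, 0.2)
  bad$neuron_j <- "c"
  expect_error(delta_metrics(mk(0.4, 0.3, 0.2), bad),
               class = "neff_validation_error")
})

test_that("delta metrics on generated pairs match closed-form differences", {
  t0 <- data.frame(p1i = 0.3, p1j = 0.3, p11 = 0.09)
  t1 <- data.frame(p1i = 0.45, p1j = 0.5, p11 = 0.25)
  n <- 4e4
  d0 <- generate_binary_pairs(t0, n, seed = 5)
  d1 <- generate_binary_pairs(t1, n, seed = 6)
  pr0 <- cbind(tibble::tibble(neuron_i = "a", neuron_j = "b"),
               estimate_pair(d0$state_i, d0$state_j))
  pr1 <- cbind(tibble::tibble(neuron_i = "a", neuron_j = "b"),
               estimate_pair(d1$state_i, d1$state_j))
  dd <- delta_metrics(pr1, pr0)
  dH_true <- pair_entropy(0.45, 0.5, 0.25) - pair_entropy(0.3, 0.3, 0.09)
  dp_true <- (0.45 - 0.3) + (0.5 - 0.3)
  expect_lt(abs(dd$delta_H - dH_true), 0.02)
  expect_lt(abs(dd$delta_p1ij - dp_true), 0.02)
})
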
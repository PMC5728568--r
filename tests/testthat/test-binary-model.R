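test_that("binarization applies the strict above-the-mean tie rule", {
  s <- counted_session(c(2, 4))       # mean 3 -> states 0, 1
  st <- binarize(s, 1, 0)
  expect_equal(st$count, c(2L, 4L))
  expect_equal(st$state, c(0L, 1L))
  s2 <- counted_session(c(3, 3, 3))   # count equals mean -> all zero
  st2 <- binarize(s2, 1, 0)
  expect_equal(st2$state, rep(0L, 3))
})

test_that("binarization refuses windows outside the epoch", {
  expect_error(binarize(tiny_session(), 0.5, c(-1.4, 0)),
               regexp = "-1.4", class = "neff_validation_error")
})

test_that("threshold pooling modes differ only when conditions differ", {
  spec <- synthetic_spec(n_neurons = 3, n_trials = 30, go_gain = 3,
                         responsive_fractions = c(1, 0), seed = 17)
  s <- generate_spike_session(spec)
  a <- binarize(s, 0.32, 0.5, pool = "all_correct")
  b <- binarize(s, 0.32, 0.5, pool = "per_condition")
  expect_identical(a$count, b$count)
  expect_false(identical(a$state, b$state))  # GO-evoked rates move the mean
  base_a <- binarize(s, 0.32, -1, pool = "all_correct")
  base_b <- binarize(s, 0.32, -1, pool = "per_condition")
  # pre-stimulus statistics are condition-independent: states mostly agree
  # (small disagreement where counts fall between the two pool means)
  expect_gt(mean(base_a$state == base_b$state), 0.85)
})

test_that("empirical p1 matches brute-force Poisson exceedance", {
  # independent oracle: direct series summation of the Poisson pmf
  mu <- 5.3
  pmf <- exp(-mu) * mu^(0:200) / factorial(0:200)
  p_exceed <- sum(pmf[(0:200) > floor(mu)])
  expect_equal(expected_poisson_p1(5.3), p_exceed, tolerance = 1e-10)
  set.seed(9)
  counts <- rpois(1e4, mu)
  p1_hat <- estimate_p1(as.integer(counts > mean(counts)))
  expect_lt(abs(p1_hat - p_exceed), 0.015)
})

test_that("expected_poisson_p1 has the documented limits", {
  expect_equal(expected_poisson_p1(0), 0)
  expect_equal(expected_poisson_p1(1), 1 - 2 * exp(-1), tolerance = 1e-12)
  expect_lt(abs(expected_poisson_p1(100) - 0.5), 0.03)
  expect_error(expected_poisson_p1(-1), class = "neff_validation_error")
})

test_that("the Fano factor of the binary state is exactly 1 - p1", {
  st <- c(1, 1, 0, 0)
  expect_equal(estimate_p1(st), 0.5)
  expect_equal(fano_factor(st), 0.5)
  expect_equal(fano_factor(rep(1, 7)), 0)
  expect_error(fano_factor(rep(0, 7)), class = "neff_validation_error")
  set.seed(3)
  x <- rbinom(1e4, 1, 0.3)
  expect_equal(fano_factor(x), 1 - estimate_p1(x))
  expect_lt(abs(fano_factor(x) - 0.7), 0.02)
  # identity with the population-variance ratio
  expect_equal(fano_factor(x), (mean(x^2) - mean(x)^2) / mean(x))
})

test_that("p1 estimation obeys binomial sampling error", {
  set.seed(5)
  x <- rbinom(1e4, 1, 0.3)
  expect_lt(abs(estimate_p1(x) - 0.3), 0.014)
  expect_error(estimate_p1(integer(0)), class = "neff_validation_error")
})

test_that("mutual information: independence, determinism and Eq-form oracle", {
  # deterministic coding: state == GO -> exactly 1 bit raw
  lab <- rep(c("GO", "NOGO"), each = 50)
  mi <- mutual_information(as.integer(lab == "GO"), lab, n_shuffles = 10,
                           seed = 1)
  expect_equal(mi$I_raw, 1, tolerance = 1e-12)
  # conditional Bernoulli construction vs direct summation value
  set.seed(11)
  n <- 1e5
  lab2 <- rep(c("GO", "NOGO"), each = n / 2)
  st <- c(rbinom(n / 2, 1, 0.75), rbinom(n / 2, 1, 0.25))
  mi2 <- mutual_information(st, lab2, n_shuffles = 5, seed = 2)
  hb <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_lt(abs(mi2$I_raw - (1 - hb(0.75))), 0.01)
  # identical distributions -> corrected I within noise of zero
  st3 <- rbinom(2000, 1, 0.4)
  mi3 <- mutual_information(st3, rep(c("GO", "NOGO"), 1000),
                            n_shuffles = 30, seed = 3)
  expect_lt(abs(mi3$I), 0.005)
  expect_error(mutual_information(st3, rep("GO", 2000)),
               class = "neff_validation_error")
})

test_that("raw mutual information is non-negative on random inputs", {
  set.seed(7)
  for (r in 1:50) {
    n <- sample(10:60, 1)
    st <- rbinom(n, 1, runif(1, 0.05, 0.95))
    lab <- sample(rep(c("GO", "NOGO"), length.out = n))
    expect_gte(mutual_information(st, lab, n_shuffles = 2)$I_raw, 0)
  }
})

test_that("window selection returns the shortest qualifying window", {
  # information saturates once the window covers the informative epoch:
  # GO doubles the rate only during 0-0.3 s, so windows beyond ~0.3 s
  # centred at 0.15 s add noise but little signal
  spec <- synthetic_spec(n_neurons = 8, n_trials = 80, baseline_rate = 12,
                         rate_sdlog = 0, go_gain = 4,
                         responsive_fractions = c(1, 0),
                         shared_input_fraction = 0, performance = 1,
                         seed = 23)
  s <- generate_spike_session(spec)
  # restrict the GO modulation to 0-0.3 s by trimming spikes in (0.3, 1) s
  go <- s$trials$trial_index[s$trials$condition == "GO"]
  drop <- s$spikes$trial_index %in% go & s$spikes$time_ms >= 300 &
    s$spikes$time_ms < 1000 & (seq_len(nrow(s$spikes)) %% 4 != 0)
  s$spikes <- s$spikes[!drop, ]
  sel <- select_window(s, windows = seq(0.1, 0.6, by = 0.1),
                       times = 0.15, n_shuffles = 10, seed = 1)
  expect_s3_class(sel, "mi_curve")
  expect_true(sel$window %in% seq(0.1, 0.6, by = 0.1))
  expect_lte(sel$window, 0.4)
  # flat <I> across windows -> the shortest window wins by construction
  flat <- sel
  flat$summary$I_mean <- rep(1, nrow(flat$summary))
  ok <- flat$summary$window[flat$summary$I_mean >= 0.8 * 1]
  expect_equal(min(ok), 0.1)
})

test_that("p1 rises with firing rate across a wide-rate population", {
  spec <- synthetic_spec(n_neurons = 40, n_trials = 150,
                         baseline_rate = seq(1, 20, length.out = 40),
                         go_gain = 1, shared_input_fraction = 0,
                         performance = 1, seed = 13)
  s <- generate_spike_session(spec)
  st <- binarize(s, 0.1, 0.5)
  d <- dplyr::filter(st, analysis_time == 0.5)
  p1 <- tapply(d$state, d$neuron_id, mean)
  rate <- tapply(d$count, d$neuron_id, mean) / 0.1
  expect_gt(p1_rate_correlation(p1, rate), 0.2)
  expect_error(p1_rate_correlation(rep(0.5, 5), 1:5),
               class = "neff_validation_error")
  # noiseless monotone construction
  expect_equal(p1_rate_correlation(c(.1, .2, .3), c(1, 5, 9)), 1)
})
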
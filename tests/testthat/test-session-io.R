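test_that("sessions round-trip bit-exactly through both dialects", {
  for (fmt in c("table", "container")) {
    for (seed in c(7, 21)) {
      s <- random_session(n_neurons = 4, n_trials = 5, seed = seed)
      path <- if (fmt == "table") withr::local_tempdir()
              else withr::local_tempfile(fileext = ".json")
      write_session(s, path, format = fmt)
      s2 <- read_session(path, format = fmt)
      expect_equal(s2$spikes, s$spikes)
      expect_equal(s2$trials, s$trials)
      expect_equal(s2$performance, s$performance)
      expect_equal(s2$session_id, s$session_id)
    }
  }
})

test_that("an empty and a one-spike session survive the round trip", {
  empty <- spike_session("e",
                         trials = data.frame(trial_index = 1L,
                                             condition = "GO",
                                             outcome = "correct"),
                         spikes = data.frame(neuron_id = character(),
                                             trial_index = integer(),
                                             time_ms = integer()),
                         performance = 1)
  one <- spike_session("o",
                       trials = data.frame(trial_index = 1L,
                                           condition = "NOGO",
                                           outcome = "incorrect"),
                       spikes = data.frame(neuron_id = "n1",
                                           trial_index = 1L,
                                           time_ms = 412L),
                       performance = 0)
  for (s in list(empty, one)) {
    p <- withr::local_tempfile(fileext = ".json")
    write_session(s, p, format = "container")
    s2 <- read_session(p, format = "container")
    expect_equal(s2$spikes, s$spikes)
    expect_equal(s2$trials, s$trials)
  }
})

test_that("the reader rejects bad labels and non-monotone timestamps", {
  expect_error(
    spike_session("x",
                  trials = data.frame(trial_index = 1L, condition = "MAYBE",
                                      outcome = "correct"),
                  spikes = data.frame(neuron_id = "a", trial_index = 1L,
                                      time_ms = 1L)),
    class = "neff_format_error")
  expect_error(
    spike_session("x",
                  trials = data.frame(trial_index = 1L, condition = "GO",
                                      outcome = "maybe"),
                  spikes = data.frame(neuron_id = "a", trial_index = 1L,
                                      time_ms = 1L)),
    class = "neff_format_error")
  expect_error(
    spike_session("x",
                  trials = data.frame(trial_index = 1L, condition = "GO",
                                      outcome = "correct"),
                  spikes = data.frame(neuron_id = "a", trial_index = 1L,
                                      time_ms = c(5L, 5L))),
    class = "neff_validation_error")
  expect_error(
    spike_session("x",
                  trials = data.frame(trial_index = 1L, condition = "GO",
                                      outcome = "correct"),
                  spikes = data.frame(neuron_id = "a", trial_index = 2L,
                                      time_ms = 5L)),
    class = "neff_validation_error")
})

test_that("a missing mandatory column is a format error naming the column", {
  s <- tiny_session()
  dir <- withr::local_tempdir()
  write_session(s, dir, format = "table")
  sp <- readr::read_csv(file.path(dir, "spikes.csv"),
                        show_col_types = FALSE)
  readr::write_csv(sp[setdiff(names(sp), "condition")],
                   file.path(dir, "spikes.csv"))
  expect_error(read_session(dir, format = "table"),
               regexp = "condition", class = "neff_format_error")
})

test_that("unknown extra columns are ignored with a warning", {
  s <- tiny_session()
  dir <- withr::local_tempdir()
  write_session(s, dir, format = "table")
  sp <- readr::read_csv(file.path(dir, "spikes.csv"),
                        show_col_types = FALSE)
  sp$waveform_snr <- 5.0
  readr::write_csv(sp, file.path(dir, "spikes.csv"))
  expect_warning(s2 <- read_session(dir, format = "table"),
                 regexp = "waveform_snr")
  expect_equal(s2$spikes, s$spikes)
})

test_that("the deposited-style fixture parses to the documented shape", {
  p <- withr::local_tempfile(fileext = ".json")
  spec <- synthetic_spec(n_neurons = 95, n_trials = 15, seed = 5)
  generate_fixture_file(p, spec)
  fx <- read_deposited_fixture(p)
  expect_equal(length(unique(fx$psth$neuron_id)), 95)
  expect_equal(length(unique(fx$psth$bin_start_s)), 80)  # 2 s / 25 ms
  expect_setequal(unique(fx$psth$condition), c("GO", "NOGO"))
  expect_equal(length(unique(fx$binary$neuron_id)), 95)
  expect_true(all(fx$binary$state %in% 0:1))
})

test_that("fixture generation is deterministic and validates its structure", {
  spec <- synthetic_spec(n_neurons = 6, n_trials = 8, seed = 11)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  expect_message(generate_fixture_file(p1, spec), "6 neurons")
  suppressMessages(generate_fixture_file(p2, spec))
  expect_identical(readLines(p1), readLines(p2))
  # structure removal -> format error
  obj <- jsonlite::read_json(p1, simplifyVector = TRUE)
  p3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj["PSTH"], p3, auto_unbox = TRUE, digits = NA)
  expect_error(read_deposited_fixture(p3), class = "neff_format_error")
  # empty file -> format error
  p4 <- withr::local_tempfile(fileext = ".json")
  file.create(p4)
  expect_error(read_deposited_fixture(p4), class = "neff_format_error")
})
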
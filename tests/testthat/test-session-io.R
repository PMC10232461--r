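test_that("a session round-trips through the tabular store unchanged", {
  s <- tiny_session()
  path <- withr::local_tempdir()
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(s2$trials, s$trials)
  expect_equal(s2$neurons, s$neurons)
  expect_equal(s2$spikes, s$spikes)
  expect_equal(s2$pedals, s$pedals)
  expect_equal(s2$metadata$hemisphere, "left")
})

test_that("an empty session writes valid files and round-trips", {
  s <- new_session(
    trials = tiny_trials()[0, ],
    pedals = data.frame(time_s = numeric(), left_pct = numeric(),
                        right_pct = numeric()),
    neurons = data.frame(neuron_id = character(), region = character(),
                         spike_duration_ms = numeric(),
                         cell_class = character()),
    spikes = data.frame(neuron_id = character(), spike_time_s = numeric()),
    metadata = list(session_id = "empty"))
  path <- withr::local_tempdir()
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(nrow(s2$trials), 0)
  expect_equal(nrow(s2$spikes), 0)
})

test_that("validation rejects an out-of-set reward delay", {
  s <- tiny_session()
  s$trials$reward_onset[1] <- s$trials$release_onset[1] + 0.25
  expect_error(validate_session(s), "reward delay")
})

test_that("validation names the neuron with unsorted spike times", {
  s <- tiny_session()
  i <- which(s$spikes$neuron_id == "n02")[1:2]
  s$spikes$spike_time_s[i] <- rev(s$spikes$spike_time_s[i])
  expect_error(validate_session(s), "n02")
})

test_that("single-field corruptions drawn from the corruption suite are caught", {
  corruptions <- list(
    function(s) { s$trials$hold_duration[1] <- 0.4; s },          # short hold
    function(s) { s$trials$correct[2] <- TRUE; s },               # wrong-side correct
    function(s) { s$trials$reward_onset[2] <- 11.0; s },          # reward on error trial
    function(s) { s$trials$release_onset[4] <- 99; s },           # broken release identity
    function(s) { s$pedals$left_pct[5] <- 120; s },               # position out of range
    function(s) { s$neurons$spike_duration_ms[1] <- -1; s },      # negative duration
    function(s) { s$neurons$region[1] <- "V1"; s })               # unknown region
  for (corrupt in corruptions)
    expect_error(validate_session(corrupt(tiny_session())))
})

test_that("checksum-protected files detect corruption on read", {
  path <- withr::local_tempdir()
  write_session(tiny_session(), path)
  f <- file.path(path, "spikes.tsv")
  txt <- readLines(f)
  txt[2] <- sub("[0-9]", "9", txt[2])
  writeLines(txt, f)
  expect_error(read_session(path), "corrupt")
})

test_that("a missing component file is reported by name", {
  path <- withr::local_tempdir()
  write_session(tiny_session(), path)
  unlink(file.path(path, "trials.tsv"))
  expect_error(read_session(path), "missing component: trials.tsv")
})

test_that("inclusion requires >= 20 completed trials and >= 250 spikes", {
  mk_trials <- function(n) data.frame(
    trial_id = seq_len(n), hold_onset = 10 * seq_len(n) - 8,
    hold_duration = 1.5, release_onset = 10 * seq_len(n) - 6.5,
    released_side = "right", block_side = "right", correct = TRUE,
    immature = FALSE, reward_onset = 10 * seq_len(n) - 6.2,
    stringsAsFactors = FALSE)
  spikes_in <- function(n, trials)
    seq(min(trials$hold_onset), max(trials$reward_onset), length.out = n)
  t19 <- mk_trials(19); t20 <- mk_trials(20); t100 <- mk_trials(100)
  expect_false(validate_inclusion(spikes_in(1000, t19), t19))
  expect_true(validate_inclusion(spikes_in(250, t20), t20))
  expect_false(validate_inclusion(spikes_in(249, t20), t20))
  expect_false(validate_inclusion(numeric(0), t100))
})
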
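test_that("behaviour simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7L, n_trials_target = 40L,
                    neuron_specs = cohort_specs(1L))
  b1 <- simulate_behavior(cfg)
  b2 <- simulate_behavior(cfg)
  expect_identical(b1$trials, b2$trials)
  expect_identical(b1$pedals, b2$pedals)
})

test_that("every reward latency is one of the five admissible delays", {
  tr <- shared_cohort()$session$trials
  delays <- tr$reward_onset[tr$correct] - tr$release_onset[tr$correct]
  expect_true(all(vapply(delays, function(d)
    any(abs(d - c(0.3, 0.4, 0.5, 0.6, 0.7)) < 1e-9), logical(1))))
  # event-count conservation: one reward per correct trial, none elsewhere
  expect_equal(sum(!is.na(tr$reward_onset)), sum(tr$correct))
})

test_that("with the performance rule disabled the block switches at the 100th reward", {
  cfg <- sim_config(seed = 3L, n_trials_target = 205L, error_rate = 0,
                    immature_rate = 0,
                    block_rules = list(min_correct = Inf, recent_n = 10,
                                       recent_frac = 0.8, max_rewards = 100),
                    neuron_specs = cohort_specs(1L))
  tr <- simulate_behavior(cfg)$trials
  expect_equal(tr$block_side[1:100], rep("right", 100))
  expect_equal(tr$block_side[101:200], rep("left", 100))
  expect_equal(tr$block_side[201], "right")
})

test_that("pedals stay in the holding area during holds and cross 30% at release", {
  s <- shared_cohort()$session
  tr <- s$trials[!s$trials$immature, ]
  rate <- s$metadata$pedal_sample_rate
  for (i in seq_len(min(nrow(tr), 25))) {
    sel <- s$pedals$time_s > tr$hold_onset[i] + 0.02 &
      s$pedals$time_s < tr$release_onset[i] - 0.001
    expect_true(all(s$pedals$left_pct[sel] <= 30))
    expect_true(all(s$pedals$right_pct[sel] <= 30))
    pos <- if (tr$released_side[i] == "left") s$pedals$left_pct
           else s$pedals$right_pct
    post <- pos[s$pedals$time_s >= tr$release_onset[i] &
                  s$pedals$time_s <= tr$release_onset[i] + 0.2]
    expect_gt(max(post), 30)
  }
})

test_that("a 'none' neuron is homogeneous Poisson at its baseline rate", {
  trials <- data.frame(
    trial_id = 1L, hold_onset = 995, hold_duration = 1.5,
    release_onset = 996.5, released_side = "right", block_side = "right",
    correct = FALSE, immature = FALSE, reward_onset = NA_real_,
    stringsAsFactors = FALSE)
  ts <- simulate_neuron("none", trials, list(baseline_hz = 3), seed = 5L)
  span <- 996.5 + 2  # simulated horizon
  expected <- 3 * span
  expect_lt(abs(length(ts) - expected), 4 * sqrt(expected))
})

test_that("Hold neurons ramp up before release relative to early baseline", {
  beh <- shared_cohort()$session$trials
  hits <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    ts <- simulate_neuron("Hold", beh, list(preferred_side = "right",
                                            effect = 3), seed = 700L + s)
    rel <- beh$release_onset[!beh$immature]
    late <- ongoing_rate_windows(ts, rel, c(-0.5, 0))
    early <- ongoing_rate_windows(ts, rel, c(-1.0, -0.7))
    if (late > early) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("a Reward neuron adds nothing outside correct-trial reward windows", {
  beh <- shared_cohort()$session$trials
  ts <- simulate_neuron("Reward", beh, list(baseline_hz = 3), seed = 31L)
  err_rel <- beh$release_onset[!beh$immature & !beh$correct]
  # post-release rate on error trials stays at baseline
  r_err <- ongoing_rate_windows(ts, err_rel, c(0, 1))
  n_exp <- 3 * length(err_rel)  # expected count over pooled 1 s windows
  expect_lt(abs(r_err - 3), 4 * sqrt(n_exp) / length(err_rel))
})

test_that("the cohort generator yields a valid, reproducible session", {
  coh <- shared_cohort()
  expect_silent(validate_session(coh$session))
  cfg <- sim_config(seed = 421L, neuron_specs = cohort_specs(2L))
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh2$truth, coh$truth)
  expect_identical(coh2$session$spikes, coh$session$spikes)
  # waveform durations are bimodal by construction
  d <- coh$session$neurons$spike_duration_ms
  expect_gt(sum(d > 0.7), 0)
  expect_gt(sum(d < 0.5), 0)
})

test_that("collision physics: triggered test stimulations never evoke a spike", {
  coh <- shared_cohort()
  proj <- coh$truth[coh$truth$projection_target != "none", ][1, ]
  st <- spike_train(coh$session, proj$neuron_id)
  sim <- simulate_stimulation(st, proj, n_control = 40, n_test = 40, seed = 2L)
  ev <- sim$events
  expect_true(all(!ev$spike_present[ev$kind == "test"]))
  # control spikes recover the planted latency
  lat <- median(ev$trough_time_ms[ev$kind == "control" & ev$spike_present])
  expect_lt(abs(lat - proj$antidromic_latency_ms), 0.1)
  # non-projection neurons evoke nothing at all
  none <- coh$truth[coh$truth$projection_target == "none", ][1, ]
  sim0 <- simulate_stimulation(spike_train(coh$session, none$neuron_id),
                               none, 20, 20, seed = 3L)
  expect_true(all(!sim0$events$spike_present))
})
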
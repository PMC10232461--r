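# Deterministic spike trains with a linear-ramp intensity: spikes are laid
# down where the cumulative intensity crosses integers, giving noise-free
# PETHs for the slope-estimator oracle.
ramp_trials <- function(n = 240) {
  holds <- round(rep(seq(1.05, 2.95, length.out = n / 4), 4), 3)
  onset <- round(cumsum(c(2, rep(6, n - 1))), 3)
  data.frame(trial_id = seq_len(n), hold_onset = onset, hold_duration = holds,
             release_onset = onset + holds, released_side = "right",
             block_side = "right", correct = TRUE, immature = FALSE,
             reward_onset = onset + holds + 0.5, stringsAsFactors = FALSE)
}

deterministic_ramp_spikes <- function(trials, rate_hz_per_s = 40) {
  unlist(lapply(seq_len(nrow(trials)), function(i) {
    H <- trials$hold_duration[i]
    n_max <- rate_hz_per_s * H^2 / 2
    k <- seq_len(floor(n_max))
    trials$hold_onset[i] + sqrt(2 * k / rate_hz_per_s)
  }))
}

test_that("a deterministic linear ramp recovers slope -1", {
  tr <- ramp_trials()
  ts <- sort(deterministic_ramp_spikes(tr))
  fit <- hold_go_slope(ts, tr, "right")
  expect_equal(fit$class, "Hold")
  expect_lt(abs(fit$slope - (-1)), 0.05)
  # brute-force check of one intersection: the range PETH must cross the
  # criterion where the analytic ramp does
  ok <- which(!is.na(fit$intersection_times))
  g <- ok[length(ok)]
  analytic <- fit$criterion_level / 40 - fit$range_mean_hold[g]
  expect_lt(abs(fit$intersection_times[g] - analytic), 0.08)
})

test_that("a release-locked bump gives slope near zero and class Go", {
  tr <- ramp_trials()
  # deterministic bump: 5 spikes in the 100 ms before each release
  ts <- sort(unlist(lapply(tr$release_onset, function(r)
    r - c(0.01, 0.03, 0.05, 0.07, 0.09))))
  fit <- hold_go_slope(ts, tr, "right")
  expect_equal(fit$class, "Go")
  expect_lt(abs(fit$slope), 0.15)
})

test_that("a slope exactly at the boundary is classified Hold", {
  tr <- ramp_trials()
  ts <- sort(deterministic_ramp_spikes(tr))
  fit <- hold_go_slope(ts, tr, "right")
  boundary <- hold_go_slope(ts, tr, "right", slope_threshold = fit$slope)
  expect_equal(boundary$class, "Hold")
})

test_that("too few trials per range yields an indeterminate fit", {
  tr <- ramp_trials(16)
  ts <- sort(deterministic_ramp_spikes(tr))
  expect_equal(hold_go_slope(ts, tr, "right")$class, "indeterminate")
})

test_that("type fractions recover planted archetype proportions", {
  coh <- shared_cohort()
  cls <- classify_cohort(coh$session)
  inc <- cls[cls$included & !is.na(cls$type), ]
  tf <- type_fractions(inc)
  expect_true(all(abs(tapply(tf$proportion, tf$region, sum) - 1) < 1e-12))
  m <- merge(cls[, c("neuron_id", "type")],
             coh$truth[, c("neuron_id", "archetype")])
  expect_gte(mean(m$type == m$archetype, na.rm = TRUE), 0.8)
  # degenerate inputs
  expect_equal(nrow(type_fractions(inc[0, ])), 0)
  one <- type_fractions(data.frame(region = "CA1", type = "Go"))
  expect_equal(one$proportion[one$type == "Go"], 1)
})
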
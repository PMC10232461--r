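test_that("a single spike at the alignment time lands in the zero bin at 50 Hz", {
  p <- compute_peth(c(5.0), align_times = 5.0, window = c(-0.5, 0.5),
                    bin_width = 0.02)
  hit <- which(p$bin_edges[-1] > 0 & p$bin_edges[-length(p$bin_edges)] <= 0)
  expect_equal(p$rates[hit], 1 / (1 * 0.02))
  expect_equal(sum(p$rates > 0), 1)
})

test_that("an empty window yields an all-zero PETH and errors are raised", {
  p <- compute_peth(numeric(0), align_times = c(1, 2), window = c(-0.5, 0.5))
  expect_true(all(p$rates == 0))
  expect_error(compute_peth(1, numeric(0), c(-0.5, 0.5)), "non-empty")
  expect_error(compute_peth(1, 1, c(0.5, -0.5)), "window")
})

test_that("a homogeneous Poisson train gives a flat PETH within Poisson error", {
  set.seed(12)
  ts <- sort(runif(10 * 600, 0, 600))  # 10 Hz over 600 s
  align <- seq(10, 590, by = 2.9)[1:200]
  p <- compute_peth(ts, align, c(-0.5, 0.5), 0.02)
  sd_bin <- sqrt(10 / (200 * 0.02))
  expect_true(all(abs(p$rates - 10) < 5 * sd_bin))
})

test_that("unsmoothed PETHs conserve the pooled spike count", {
  coh <- shared_cohort()
  tr <- coh$session$trials
  rel <- tr$release_onset[!tr$immature]
  for (id in coh$session$neurons$neuron_id[c(1, 5, 9)]) {
    st <- spike_train(coh$session, id)
    p <- compute_peth(st, rel, c(-1, 0.5), 0.02)
    pooled <- sum(vapply(rel, function(a)
      sum(st$spike_times >= a - 1 & st$spike_times <= a + 0.5), numeric(1)))
    expect_equal(sum(p$rates * p$bin_width) * p$n_trials, pooled,
                 tolerance = 1e-9)
  }
})

test_that("smoothing reproduces the kernel for a single spike and keeps mass", {
  sm <- smooth_peth(c(5.0), sigma_ms = 12.5, align_times = 5.0,
                    window = c(-0.5, 0.5))
  expect_equal(sum(sm$rates * sm$bin_width), 1, tolerance = 1e-3)
  expect_lt(abs(1000 * sm$centers[which.max(sm$rates)]), 1.1)
  # profile matches a Gaussian of sd sigma
  th <- dnorm(sm$centers, 0, 0.0125)
  expect_gt(cor(sm$rates, th), 0.999)
})

test_that("smoothing leaves a constant-rate histogram constant away from edges", {
  p <- compute_peth(seq(0.005, 99.995, by = 0.01), align_times = 50,
                    window = c(-2, 2), bin_width = 0.02)
  sm <- smooth_peth(p, sigma_ms = 50)
  interior <- sm$centers > -1.7 & sm$centers < 1.7
  expect_true(all(abs(sm$rates[interior] - 100) < 1e-6))
  # integral preserved to < 0.1% over an 8-sigma-plus window
  expect_lt(abs(sum(sm$rates) / sum(p$rates) - 1), 1e-3)
  expect_error(smooth_peth(p, sigma_ms = 0), "sigma")
})

test_that("ongoing rate is count over duration", {
  expect_equal(ongoing_rate(seq(0.1, 9.9, length.out = 30), c(0, 10)), 3.0)
  expect_equal(ongoing_rate(numeric(0), c(0, 10)), 0)
  expect_error(ongoing_rate(1:3, c(5, 5)), "positive length")
})

test_that("release onset is found at the 5% excursion before the 30% crossing", {
  # noiseless sigmoid: baseline 10%, rises from t = 10.0 s over 100 ms
  t <- seq(8, 12, by = 0.001)
  pos <- 10 + 80 * plogis((t - 10.05) / 0.012)
  trial <- list(hold_onset = 8.5, hold_duration = 1.5)
  det <- detect_release_onset(t, pos, trial)
  t5 <- t[which(pos > 15)[1]]   # first sample above baseline + 5
  expect_lt(abs(det - t5), 0.0011)
  expect_lt(det, t[which(pos > 30)[1]])
})

test_that("a trace that never leaves the holding area reports no release", {
  t <- seq(0, 5, by = 0.01)
  expect_error(
    detect_release_onset(t, rep(10, length(t)), list(hold_onset = 1,
                                                     hold_duration = 2)),
    "no release detected")
})

test_that("detected onsets precede the 30% crossing on simulated trials", {
  s <- shared_cohort()$session
  tr <- s$trials[!s$trials$immature, ]
  for (i in seq_len(nrow(tr))) {
    pos <- if (tr$released_side[i] == "left") s$pedals$left_pct
           else s$pedals$right_pct
    det <- detect_release_onset(s$pedals$time_s, pos, tr[i, ])
    sel <- which(s$pedals$time_s >= tr$hold_onset[i])
    t30 <- s$pedals$time_s[sel][which(pos[sel] > 30)[1]]
    expect_lte(det, t30)
  }
})

test_that("peak latency takes the earliest maximum and flags flat PETHs", {
  p <- compute_peth(numeric(0), 0, c(-0.5, 0.5), 0.02)
  p$rates[p$centers == -0.09] <- 5
  p$rates[p$centers == 0.11] <- 5
  expect_equal(as.numeric(peak_latency(p)), -90)
  flat <- compute_peth(numeric(0), 0, c(-0.5, 0.5), 0.02)
  expect_true(attr(peak_latency(flat), "flat"))
  sm <- smooth_peth(c(10.06), sigma_ms = 12.5, align_times = 10,
                    window = c(-0.5, 0.5))
  expect_lt(abs(as.numeric(peak_latency(sm)) - 60), 1.1)
})
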
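test_that("the ROC threshold separates the two trough populations", {
  set.seed(41)
  present <- rnorm(60, -60, 5); absent <- rnorm(60, -5, 3)
  thr <- roc_threshold(c(present, absent))
  expect_gt(as.numeric(thr), -45)
  expect_lt(as.numeric(thr), -20)
  expect_false(attr(thr, "low_confidence"))
  # with labels, perfectly separable values classify without error
  thr2 <- roc_threshold(c(present, absent),
                        labels = rep(c(TRUE, FALSE), each = 60))
  expect_true(all(present <= as.numeric(thr2)))
  expect_true(all(absent > as.numeric(thr2)))
  # degenerate input flags low confidence
  expect_true(attr(roc_threshold(rep(-5, 20)), "low_confidence"))
})

test_that("spike probabilities and counts are conserved", {
  sp <- spike_probabilities(rep(-60, 20), rep(-5, 20), -30)
  expect_equal(sp$p_control, 1)
  expect_equal(sp$p_test, 0)
  expect_equal(unname(rowSums(sp$counts)), c(20, 20))
  expect_error(spike_probabilities(numeric(0), 1, 0), "non-empty")
})

test_that("the chi-squared collision decision matches hand computation", {
  d <- collision_decision(matrix(c(20, 0, 0, 20), 2, byrow = TRUE))
  expect_equal(d$chi2_stat, 40)
  expect_lt(d$p, 1e-9)
  expect_true(d$passes_chi2)
  d0 <- collision_decision(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(d0$chi2_stat, 0)
  expect_equal(d0$p, 1)
  expect_false(d0$passes_chi2)
  expect_error(collision_decision(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero margin")
})

test_that("chi-squared decisions concord with Fisher's exact test", {
  set.seed(43)
  concord <- 0L
  for (i in 1:100) {
    m <- matrix(rpois(4, 8) + 1, 2)
    chi <- collision_decision(m)$passes_chi2
    fis <- stats::fisher.test(m)$p.value < 0.05
    if (chi == fis) concord <- concord + 1L
  }
  expect_gte(concord, 95)
})

test_that("latency and jitter follow the quartile definitions", {
  lj <- latency_jitter(rep(17.1, 12))
  expect_equal(lj$latency_median_ms, 17.1)
  expect_equal(lj$jitter_ms, 0)
  expect_true(lj$passes_constant_latency)
  expect_equal(latency_jitter(c(16, 17, 18))$latency_median_ms, 17)
  set.seed(47)
  u <- runif(2000, 10, 12)  # uniform over 2 ms: IQR ~ 1 ms
  lju <- latency_jitter(u)
  expect_lt(abs(lju$jitter_ms - 1), 0.1)
  expect_false(lju$passes_constant_latency)
  expect_true(latency_jitter(c(1, 2))$insufficient)
})

test_that("projection neurons pass and non-projection neurons fail end to end", {
  coh <- shared_cohort()
  proj <- coh$truth[coh$truth$projection_target != "none", ][1, ]
  st <- spike_train(coh$session, proj$neuron_id)
  sim <- simulate_stimulation(st, proj, 30, 30, seed = 11)
  ct <- identify_projection(sim$events, sim$ff)
  expect_true(ct$passes)
  expect_lt(abs(ct$latency_median_ms - proj$antidromic_latency_ms), 0.2)
  none <- coh$truth[coh$truth$projection_target == "none", ][1, ]
  sim0 <- simulate_stimulation(spike_train(coh$session, none$neuron_id),
                               none, 30, 30, seed = 12)
  ct0 <- identify_projection(sim0$events, sim0$ff)
  expect_false(ct0$passes)
})

test_that("a control spike probability of exactly 50% fails the gate", {
  set.seed(51)
  ctrl <- c(rnorm(10, -60, 2), rnorm(10, -5, 2))
  test <- rnorm(20, -5, 2)
  ev <- data.frame(kind = rep(c("control", "test"), each = 20),
                   trough_amp = c(ctrl, test),
                   trough_time_ms = c(ifelse(ctrl < -30, 17, runif(20, 0, 25)),
                                      runif(20, 0, 25))[1:40],
                   spike_present = c(ctrl < -30, rep(FALSE, 20)))
  ct <- identify_projection(ev)
  expect_equal(ct$p_control, 0.5)
  expect_false(ct$criteria_breakdown[["control_above_half"]])
  expect_false(ct$passes)
})

test_that("adding test spikes never converts a failing decision to passing", {
  pass_of <- function(test_spikes) {
    counts <- matrix(c(18, 2, test_spikes, 20 - test_spikes), 2, byrow = TRUE,
                     dimnames = list(c("control", "test"),
                                     c("spike", "no_spike")))
    p_control <- 18 / 20; p_test <- test_spikes / 20
    gates <- p_control > 0.5 && p_test < 0.5 * p_control
    gates && collision_decision(counts)$passes_chi2
  }
  passes <- vapply(0:20, pass_of, logical(1))
  expect_false(any(diff(passes) > 0))  # monotone: once failing, stays failing
})
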
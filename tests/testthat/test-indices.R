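test_that("normalized activity follows SR_peak/SR_baseline - 1", {
  expect_equal(normalized_activity(4, 4), 0)
  expect_equal(normalized_activity(8, 4), 1)
  expect_equal(normalized_activity(0, 4), -1)
  na <- normalized_activity(3, 0)
  expect_true(is.na(na) && attr(na, "undefined"))
})

test_that("the laterality index follows the piecewise definition", {
  expect_equal(laterality_index(0.5, -0.3), 1)
  expect_equal(laterality_index(-0.2, 0.4), -1)
  expect_equal(laterality_index(0.3, 0.1), 0.5)
  expect_equal(laterality_index(0.7, 0.7), 0)
  und <- laterality_index(-0.1, -0.2)
  expect_true(is.na(und) && attr(und, "undefined"))
  # zeros take the non-positive branch
  expect_equal(laterality_index(0.4, 0), 1)
  expect_equal(laterality_index(0, 0.4), -1)
})

test_that("laterality is antisymmetric and bounded on random inputs", {
  set.seed(77)
  for (i in 1:200) {
    c_ <- runif(1, 0.01, 5); i_ <- runif(1, 0.01, 5)
    v <- laterality_index(c_, i_)
    expect_equal(v, -laterality_index(i_, c_))
    expect_true(v >= -1 && v <= 1)
  }
  # mixed-sign draws stay bounded too
  for (i in 1:100) {
    v <- laterality_index(runif(1, -2, 2), runif(1, -2, 2))
    expect_true(is.na(v) || (v >= -1 && v <= 1))
  }
})

test_that("the reward modulation index contrasts rewarded vs unrewarded rates", {
  expect_equal(reward_modulation_index(5, 5), 0)
  expect_equal(reward_modulation_index(3, 1), 0.5)
  expect_equal(reward_modulation_index(2, 0), 1)
  und <- reward_modulation_index(0, 0)
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("holding-period side rates separate lateralized from silent neurons", {
  coh <- shared_cohort()
  tr <- coh$session$trials
  expect_equal(hold_side_rates(numeric(0), tr, "left")[c("contra_hz", "ipsi_hz")],
               list(contra_hz = 0, ipsi_hz = 0))
  hold_ids <- coh$truth$neuron_id[coh$truth$archetype == "Hold"]
  for (id in hold_ids) {
    pref <- coh$truth$preferred_side[coh$truth$neuron_id == id]
    hsr <- hold_side_rates(spike_train(coh$session, id), tr, "left")
    pref_rate <- if (pref == "right") hsr$contra_hz else hsr$ipsi_hz
    npref_rate <- if (pref == "right") hsr$ipsi_hz else hsr$contra_hz
    expect_gt(pref_rate, npref_rate)  # non-preferred kernel is halved
  }
})

test_that("planted side preference drives the sign of the laterality index", {
  coh <- shared_cohort()
  tr <- coh$session$trials
  go <- coh$truth[coh$truth$archetype %in% c("Go", "Go&Reward"), ]
  li <- vapply(seq_len(nrow(go)), function(i) {
    ai <- activity_indices(spike_train(coh$session, go$neuron_id[i]),
                           tr, "left", "go")
    ai$laterality_index
  }, numeric(1))
  agree <- sign(li) == go$laterality_sign
  expect_gte(mean(agree, na.rm = TRUE), 0.9)
})

test_that("reward-type neurons show positive reward modulation", {
  coh <- shared_cohort()
  tr <- coh$session$trials
  rw <- coh$truth$neuron_id[coh$truth$archetype == "Reward"]
  rmi <- vapply(rw, function(id) {
    activity_indices(spike_train(coh$session, id), tr, "left",
                     "reward")$reward_modulation_index
  }, numeric(1))
  expect_true(all(rmi > 0))
})
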
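# Shared design built from the small simulated session (built once per run).
glm_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- shared_cohort()
      id <- coh$truth$neuron_id[coh$truth$archetype == "none"][1]
      cache <<- build_design(coh$session, spike_train(coh$session, id))
    }
    cache
  }
})

test_that("the design grid aligns response, predictors and trial time", {
  des <- glm_design()
  expect_equal(length(des$response), nrow(des$predictors))
  expect_equal(length(des$time_s), length(des$response))
  # trial time resets to ~0 at every holding onset
  tr <- shared_cohort()$session$trials
  at_onset <- des$predictors$trial_time[des$time_s %in% tr$hold_onset]
  expect_true(all(at_onset < 0.021))
  expect_true(all(diff(des$time_s) > 0 | diff(des$predictors$trial_time) < 0))
})

test_that("constant pedal predictors are dropped and flagged", {
  s <- tiny_session()
  s$trials <- s$trials[rep(1:2, 12), ]
  s$trials$trial_id <- seq_len(nrow(s$trials))
  s$trials$hold_onset <- seq(2, by = 6, length.out = nrow(s$trials))
  s$trials$release_onset <- s$trials$hold_onset + s$trials$hold_duration
  s$trials$reward_onset <- ifelse(s$trials$correct,
                                  s$trials$release_onset + 0.4, NA)
  s$pedals <- data.frame(time_s = round(seq(0, 160, 0.01), 6),
                         left_pct = 50, right_pct = 50)
  des <- build_design(s, runif(300, 0, 150))
  expect_setequal(des$dropped, c("left_pedal", "right_pedal"))
  expect_equal(names(des$predictors), "trial_time")
})

test_that("planted single-term responses are recovered with the right class", {
  des <- glm_design()
  set.seed(42)
  p <- des$predictors
  sc <- function(x) (x - mean(x)) / sd(x)
  noise <- rnorm(length(des$response))
  fit_p <- stepwise_fit(5 * sc(p$right_pedal) + noise, p)
  expect_equal(classify_glm(fit_p), "Pedal")
  expect_true("right_pedal" %in% fit_p$selected_terms)
  fit_t <- stepwise_fit(5 * sc(p$trial_time) + noise, p)
  expect_equal(classify_glm(fit_t), "Time")
  fit_b <- stepwise_fit(5 * sc(p$trial_time) + 5 * sc(p$left_pedal) + noise, p)
  expect_equal(classify_glm(fit_b), "Time&Pedal")
  # residual degrees of freedom match n - selected - 1
  expect_equal(fit_p$residual_df,
               length(des$response) - length(fit_p$selected_terms) - 1)
})

test_that("selection is deterministic and calibrated on pure noise", {
  des <- glm_design()
  p <- des$predictors
  set.seed(9)
  y <- rnorm(nrow(p))
  f1 <- stepwise_fit(y, p); f2 <- stepwise_fit(y, p)
  expect_identical(f1$selected_terms, f2$selected_terms)
  expect_identical(f1$term_p_values, f2$term_p_values)
  classes <- vapply(1:30, function(s) {
    set.seed(100 + s)
    classify_glm(stepwise_fit(rnorm(nrow(p)), p))
  }, character(1))
  # after Bonferroni the familywise false-selection rate stays near alpha
  expect_lte(mean(classes != "none"), 3 * 0.05)
})

test_that("classification follows the significance table", {
  mk <- function(sel, p) structure(list(selected_terms = sel,
                                        term_p_values = p), class = "glm_cell_result")
  p3 <- c(left_pedal = 0.5, right_pedal = 0.5, trial_time = 0.001)
  expect_equal(classify_glm(mk("trial_time", p3)), "Time")
  p4 <- c(left_pedal = 0.001, right_pedal = 0.5, trial_time = 0.001)
  expect_equal(classify_glm(mk(c("trial_time", "left_pedal"), p4)), "Time&Pedal")
  expect_equal(classify_glm(mk("left_pedal", p4)), "Pedal")
  expect_equal(classify_glm(mk(character(0), p3)), "none")
  # a selected term that fails Bonferroni does not count
  p5 <- c(left_pedal = 0.5, right_pedal = 0.5, trial_time = 0.03)
  expect_equal(classify_glm(mk("trial_time", p5)), "none")
})
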
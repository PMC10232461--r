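#' Simulation configuration
#'
#' Bundles every parameter of the synthetic session generator. The defaults
#' reproduce the study conditions of the task: holding periods of at least
#' 1 s with a truncated-exponential tail (typical holds 1-3 s), reward
#' delivered 300-700 ms after a correct release in random 100 ms steps,
#' blocks that switch once the animal exceeds 30 correct trials with 80%
#' correct performance in the last 10 completed trials (or after 100
#' rewards), pedal traces sampled at 1 kHz with a 0-30% holding area, and an
#' 80 ms sigmoidal release.
#'
#' @param seed master RNG seed; all stage seeds are derived from it.
#' @param n_trials_target number of trials to simulate (default 200, a
#'   typical 2-3 h session).
#' @param min_hold minimum holding duration for a completed trial (s).
#' @param hold_mean_extra mean of the exponential holding time beyond
#'   `min_hold` (s), truncated at `hold_max_extra`.
#' @param hold_max_extra truncation of the extra holding time (s), so that
#'   completed holds span `min_hold` to `min_hold + hold_max_extra`.
#' @param error_rate probability that a completed trial releases the wrong
#'   pedal.
#' @param immature_rate probability that a trial fails to complete the 1 s
#'   holding period.
#' @param reward_delay_set admissible reward delays after release (s).
#' @param block_rules list with `min_correct` (block may switch once strictly
#'   more than this many corrects were collected), `recent_n`, `recent_frac`
#'   (performance gate over the most recent completed trials), and
#'   `max_rewards` (forced switch).
#' @param pedal_sample_rate pedal trace sampling rate (Hz).
#' @param release_rise_time duration of the sigmoidal pedal rise at release (s).
#' @param press_time duration of the pedal press preceding hold onset (s).
#' @param hold_level,rest_level pedal position during holding / between
#'   trials (% of range of motion).
#' @param pedal_noise_sd Gaussian position noise (% units).
#' @param iti_mean mean extra inter-trial interval beyond 1.5 s (s).
#' @param neuron_specs data.frame of neuron specifications, see
#'   [cohort_specs()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_trials_target = 200L,
                       min_hold = 1.0,
                       hold_mean_extra = 0.8,
                       hold_max_extra = 2.0,
                       error_rate = 0.10,
                       immature_rate = 0.10,
                       reward_delay_set = REWARD_DELAYS,
                       block_rules = list(min_correct = 30, recent_n = 10,
                                          recent_frac = 0.8, max_rewards = 100),
                       pedal_sample_rate = 1000,
                       release_rise_time = 0.080,
                       press_time = 0.100,
                       hold_level = 12,
                       rest_level = 75,
                       pedal_noise_sd = 0.3,
                       iti_mean = 1.0,
                       neuron_specs = cohort_specs()) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            immature_rate >= 0, immature_rate <= 1,
            pedal_sample_rate > 0, n_trials_target >= 1)
  if (!isTRUE(all.equal(sort(reward_delay_set), REWARD_DELAYS)))
    stop("reward_delay_set must be {0.3, 0.4, 0.5, 0.6, 0.7} s", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# inverse-CDF sampler for an exponential truncated at `max`
rtexp <- function(n, mean, max) {
  u <- runif(n)
  -mean * log(1 - u * (1 - exp(-max / mean)))
}

# smoothstep used for pedal transitions (C1, monotone on [0, 1])
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate task behaviour: trial table and pedal traces
#'
#' Generates trials sequentially under the block rules, then renders both
#' pedal position traces: both pedals pressed into the holding area (0-30%)
#' during each holding period, the released pedal rising sigmoidally through
#' 30% at release, the other pedal following 300 ms later. Immature trials
#' (holds shorter than 1 s) end with both pedals rising and carry no release
#' or reward fields.
#'
#' @param config a [sim_config()].
#' @return List with `trials` (trial event table) and `pedals` (data.frame
#'   `time_s`, `left_pct`, `right_pct`).
#' @export
simulate_behavior <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_trials_target
    br <- config$block_rules
    block_side <- "right"
    n_correct_block <- 0L
    recent <- logical(0)  # outcomes of completed trials in current block

    rows <- vector("list", n)
    t_cur <- 2.0  # session starts with 2 s of rest
    for (i in seq_len(n)) {
      iti <- 1.5 + min(rexp(1, 1 / config$iti_mean), 3)
      hold_onset <- round(t_cur + iti, 3)
      immature <- runif(1) < config$immature_rate
      if (immature) {
        hold_duration <- round(runif(1, 0.2, 0.95), 3)
        rows[[i]] <- data.frame(
          trial_id = i, hold_onset = hold_onset,
          hold_duration = hold_duration, release_onset = NA_real_,
          released_side = NA_character_, block_side = block_side,
          correct = FALSE, immature = TRUE, reward_onset = NA_real_,
          stringsAsFactors = FALSE)
        t_cur <- hold_onset + hold_duration
        next
      }
      hold_duration <- round(
        config$min_hold + rtexp(1, config$hold_mean_extra, config$hold_max_extra), 3)
      release_onset <- hold_onset + hold_duration
      correct <- runif(1) >= config$error_rate
      released_side <- if (correct) block_side else setdiff(SIDES, block_side)
      reward_onset <- if (correct)
        release_onset + sample(config$reward_delay_set, 1) else NA_real_
      rows[[i]] <- data.frame(
        trial_id = i, hold_onset = hold_onset, hold_duration = hold_duration,
        release_onset = release_onset, released_side = released_side,
        block_side = block_side, correct = correct, immature = FALSE,
        reward_onset = reward_onset, stringsAsFactors = FALSE)
      t_cur <- max(release_onset, reward_onset, na.rm = TRUE) + 1.0

      recent <- c(recent, correct)
      if (correct) n_correct_block <- n_correct_block + 1L
      switch_now <- n_correct_block >= br$max_rewards ||
        (n_correct_block > br$min_correct &&
           length(recent) >= br$recent_n &&
           mean(tail(recent, br$recent_n)) >= br$recent_frac)
      if (switch_now) {
        block_side <- setdiff(SIDES, block_side)
        n_correct_block <- 0L
        recent <- logical(0)
      }
    }
    trials <- do.call(rbind, rows)
    pedals <- render_pedals(trials, config)
    list(trials = trials, pedals = pedals)
  })
}

# Render both pedal traces for a trial table.
render_pedals <- function(trials, config) {
  rate <- config$pedal_sample_rate
  t_end <- max(trials$hold_onset + trials$hold_duration,
               trials$reward_onset, na.rm = TRUE) + 2.0
  nsamp <- floor(t_end * rate) + 1L
  time_s <- (seq_len(nsamp) - 1L) / rate
  pos <- list(left = rep(config$rest_level, nsamp),
              right = rep(config$rest_level, nsamp))
  idx_of <- function(t) pmin(pmax(floor(t * rate) + 1L, 1L), nsamp)
  span <- function(a, b) if (b >= a) seq.int(a, b) else integer(0)
  drop_amt <- config$rest_level - config$hold_level

  for (i in seq_len(nrow(trials))) {
    ho <- trials$hold_onset[i]
    hold_end <- if (trials$immature[i]) ho + trials$hold_duration[i]
                else trials$release_onset[i]
    rise_at <- c(left = hold_end, right = hold_end)
    if (!trials$immature[i]) {
      rel <- trials$released_side[i]
      oth <- setdiff(SIDES, rel)
      rise_at[rel] <- trials$release_onset[i]
      rise_at[oth] <- trials$release_onset[i] + 0.3
    }
    for (side in SIDES) {
      # press: rest -> hold_level, completing exactly at hold onset
      i0 <- idx_of(ho - config$press_time); i1 <- idx_of(ho)
      u <- (time_s[span(i0, i1)] - (ho - config$press_time)) / config$press_time
      pos[[side]][span(i0, i1)] <- config$rest_level - drop_amt * smoothstep(u)
      # hold: flat at hold_level
      j0 <- i1 + 1L; j1 <- idx_of(rise_at[side])
      pos[[side]][span(j0, j1)] <- config$hold_level
      # release: hold_level -> rest over release_rise_time
      k0 <- j1 + 1L
      k1 <- idx_of(rise_at[side] + config$release_rise_time)
      u <- (time_s[span(k0, k1)] - rise_at[side]) / config$release_rise_time
      pos[[side]][span(k0, k1)] <- config$hold_level + drop_amt * smoothstep(u)
    }
  }
  noise <- function(x)
    round(pmin(pmax(x + rnorm(length(x), 0, config$pedal_noise_sd), 0), 100), 4)
  data.frame(time_s = round(time_s, 6),
             left_pct = noise(pos$left),
             right_pct = noise(pos$right))
}
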
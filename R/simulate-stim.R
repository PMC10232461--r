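#' Simulate antidromic stimulation with collision physics
#'
#' For a projection neuron, each untriggered (control) stimulation evokes an
#' antidromic spike at the true latency with sub-0.1 ms jitter, unless a
#' spontaneous spike occurred within one conduction round-trip (twice the
#' antidromic latency) before the stimulus, in which case the two spikes
#' collide and the antidromic spike disappears. Triggered (test)
#' stimulations are delivered a quarter round-trip after a spontaneous
#' spike, so collision is guaranteed. Non-projection neurons never produce
#' antidromic spikes. For each stimulation the most negative point (trough)
#' of the filtered trace inside the counting window is reported: troughs
#' with a spike draw from N(-60, 5), troughs without from N(-5, 3)
#' (arbitrary filtered-voltage units), giving the two separated
#' distributions the ROC threshold stage expects. A paired-pulse
#' frequency-following block (100 and 200 Hz) is simulated alongside.
#'
#' @param spikes a `spike_train` or numeric vector of spontaneous spike
#'   times (s).
#' @param truth list or one-row data.frame with `projection_target`
#'   (`"mPFC"`, `"CA1"` or `"none"`) and `antidromic_latency_ms`.
#' @param n_control number of control (untriggered) stimulations.
#' @param n_test number of test (spike-triggered) stimulations.
#' @param seed RNG seed.
#' @param jitter_sd_ms sd of the antidromic latency jitter (ms).
#' @return List with `stims` (stimulation epoch table), `events` (one row
#'   per stimulation: `kind`, `stim_time_s`, `trough_amp`, `trough_time_ms`,
#'   `spike_present`) and `ff` (frequency-following counts).
#' @export
simulate_stimulation <- function(spikes, truth, n_control = 30L, n_test = 30L,
                                 seed = 1L, jitter_sd_ms = 0.02) {
  if (n_control < 1 || n_test < 1)
    stop("n_control and n_test must be >= 1", call. = FALSE)
  ts <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  target <- as.character(truth$projection_target)
  is_proj <- !is.na(target) && target != "none"
  lat_ms <- if (is_proj) as.numeric(truth$antidromic_latency_ms) else NA_real_
  win_ms <- if (is_proj) lat_ms + 5 else 25
  site <- if (is_proj && target == "CA1") "CA1" else "mPFC"

  with_seed(seed, {
    t0 <- if (length(ts)) min(ts) else 0
    t1 <- if (length(ts)) max(ts) else 100
    rt_s <- if (is_proj) 2 * lat_ms / 1000 else 0

    ctrl_times <- sort(runif(n_control, t0 + 1, t1 - 1))
    if (is_proj) {
      # collision with a spontaneous spike inside the round-trip window
      prev_idx <- findInterval(ctrl_times, ts)
      prev_gap <- ctrl_times - ifelse(prev_idx >= 1, ts[pmax(prev_idx, 1)], -Inf)
      ctrl_present <- prev_gap > rt_s
    } else {
      ctrl_present <- rep(FALSE, n_control)
    }

    if (length(ts) < n_test)
      stop("not enough spontaneous spikes to trigger ", n_test,
           " test stimulations", call. = FALSE)
    trig <- sort(sample(ts[ts > t0 + 1 & ts < t1 - 1], n_test))
    test_times <- trig + if (is_proj) 0.25 * rt_s else 0.002
    test_present <- rep(FALSE, n_test)  # collision (or no projection)

    mk_event <- function(kind, stim_time, present) {
      n <- length(stim_time)
      amp <- ifelse(present, rnorm(n, -60, 5), rnorm(n, -5, 3))
      tt <- ifelse(present, lat_ms + rnorm(n, 0, jitter_sd_ms),
                   runif(n, 0, win_ms))
      data.frame(kind = kind, stim_time_s = round(stim_time, 6),
                 trough_amp = amp, trough_time_ms = tt,
                 spike_present = present, stringsAsFactors = FALSE)
    }
    events <- rbind(mk_event("control", ctrl_times, ctrl_present),
                    mk_event("test", test_times, test_present))

    stims <- data.frame(
      stim_time_s = round(c(ctrl_times, test_times), 6),
      site = site, pulse_ms = 1.0,
      triggered = c(rep(FALSE, n_control), rep(TRUE, n_test)),
      trigger_spike_time_s = c(rep(NA_real_, n_control), round(trig, 6)),
      stringsAsFactors = FALSE)
    stims <- stims[order(stims$stim_time_s), ]

    ff <- data.frame(
      freq_hz = c(100, 200), n = c(20L, 20L),
      responses = if (is_proj) c(rbinom(1, 20, 0.95), rbinom(1, 20, 0.75))
                  else c(0L, 0L))
    list(stims = stims, events = events, ff = ff,
         window_ms = win_ms)
  })
}
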
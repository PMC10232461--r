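# Shared fixtures: tiny deterministic sessions built in code.

# A minimal hand-written trial table (times in s, rounded to 1 ms).
tiny_trials <- function() {
  data.frame(
    trial_id = 1:4,
    hold_onset = c(2.0, 8.0, 14.0, 20.0),
    hold_duration = c(1.5, 2.0, 0.6, 1.2),
    release_onset = c(3.5, 10.0, NA, 21.2),
    released_side = c("right", "left", NA, "right"),
    block_side = c("right", "right", "right", "left"),
    correct = c(TRUE, FALSE, FALSE, FALSE),
    immature = c(FALSE, FALSE, TRUE, FALSE),
    reward_onset = c(3.9, NA, NA, NA),
    stringsAsFactors = FALSE)
}

tiny_session <- function(n_neurons = 2, spikes_per_neuron = 30) {
  tr <- tiny_trials()
  set.seed(99)
  ids <- sprintf("n%02d", seq_len(n_neurons))
  spikes <- do.call(rbind, lapply(ids, function(id) data.frame(
    neuron_id = id,
    spike_time_s = round(sort(runif(spikes_per_neuron, 0, 25)), 6),
    stringsAsFactors = FALSE)))
  neurons <- data.frame(
    neuron_id = ids,
    region = rep(c("CA1", "LECs", "LECd"), length.out = n_neurons),
    spike_duration_ms = rep(c(1.0, 0.3), length.out = n_neurons),
    cell_class = "unset", stringsAsFactors = FALSE)
  pedals <- data.frame(
    time_s = round(seq(0, 25, by = 0.01), 6),
    left_pct = 50, right_pct = 50)
  new_session(tr, pedals, neurons, spikes,
              metadata = list(session_id = "tiny", group = "post-training",
                              hemisphere = "left", pedal_sample_rate = 100))
}

# Pooled mean rate (Hz) in a window relative to each alignment time.
ongoing_rate_windows <- function(ts, align, win) {
  n <- sum(vapply(align, function(a)
    sum(ts >= a + win[1] & ts <= a + win[2]), numeric(1)))
  n / (length(align) * diff(win))
}

# Small simulated session shared across expensive tests (built once).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 421L, neuron_specs = cohort_specs(2L))
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
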
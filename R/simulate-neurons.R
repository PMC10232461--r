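#' Neuron archetypes
#'
#' Task-related activity is simulated as an inhomogeneous Poisson process
#' whose intensity is a constant baseline plus archetype kernels tied to the
#' behavioural events:
#'
#' * `Hold`: a constant-slope ramp starting at hold onset and ending at
#'   release, so that longer holds reach higher peaks (the ramp rate is
#'   scaled so the mean-duration hold peaks at `effect` times baseline).
#' * `Go`: a Gaussian bump (sd `go_sigma`, default 50 ms) centred
#'   `go_offset` s from release onset; a configurable fraction of Go
#'   neurons peaks before release (preparation) vs after (feedback).
#' * `Reward`: a causal Gaussian bump after reward delivery on correct
#'   trials only (centre `reward_offset` after reward onset).
#' * `Go&Reward`, `Hold&Reward`: sums of the component kernels.
#' * `none`: constant baseline.
#'
#' Kernels are scaled by `nonpref_frac` on trials of the non-preferred side,
#' and the composed intensity is clipped at zero.
#'
#' @name archetypes
NULL

ARCHETYPES <- c("Hold", "Hold&Reward", "Go", "Go&Reward", "Reward", "none")

default_neuron_spec <- function() {
  list(baseline_hz = 3, effect = 4, preferred_side = "right",
       nonpref_frac = 0.5, go_offset = -0.225, go_sigma = 0.05,
       reward_offset = 0.2, reward_sigma = 0.06)
}

# Composed Poisson intensity (Hz) at times `t` for one archetype.
archetype_intensity <- function(t, archetype, trials, spec) {
  lam <- rep(spec$baseline_hz, length(t))
  comp <- which(!trials$immature)
  amp <- spec$effect * spec$baseline_hz
  w_for <- function(i) if (is.na(trials$released_side[i]) ||
                           trials$released_side[i] == spec$preferred_side)
    1 else spec$nonpref_frac

  if (archetype %in% c("Hold", "Hold&Reward")) {
    ramp_rate <- amp / mean(trials$hold_duration[comp])
    for (i in seq_len(nrow(trials))) {
      ho <- trials$hold_onset[i]
      he <- ho + trials$hold_duration[i]
      sel <- which(t >= ho & t <= he)
      if (length(sel))
        lam[sel] <- lam[sel] + w_for(i) * ramp_rate * (t[sel] - ho)
    }
  }
  if (archetype %in% c("Go", "Go&Reward")) {
    for (i in comp) {
      ctr <- trials$release_onset[i] + spec$go_offset
      sel <- which(t >= ctr - 4 * spec$go_sigma & t <= ctr + 4 * spec$go_sigma)
      if (length(sel))
        lam[sel] <- lam[sel] +
          w_for(i) * amp * exp(-(t[sel] - ctr)^2 / (2 * spec$go_sigma^2))
    }
  }
  if (archetype %in% c("Reward", "Go&Reward", "Hold&Reward")) {
    for (i in which(trials$correct)) {
      ctr <- trials$reward_onset[i] + spec$reward_offset
      sel <- which(t >= ctr - 4 * spec$reward_sigma &
                     t <= ctr + 4 * spec$reward_sigma)
      if (length(sel))
        lam[sel] <- lam[sel] +
          amp * exp(-(t[sel] - ctr)^2 / (2 * spec$reward_sigma^2))
    }
  }
  pmax(lam, 0)
}

#' Simulate one neuron's spike train
#'
#' Draws spikes from the inhomogeneous Poisson process of the given
#' archetype by thinning a homogeneous process at the intensity upper
#' bound. Spike times are rounded to 1 microsecond and deduplicated so a
#' simulated session round-trips exactly through the tabular store.
#'
#' @param archetype one of `"Hold"`, `"Hold&Reward"`, `"Go"`, `"Go&Reward"`,
#'   `"Reward"`, `"none"`.
#' @param trials the session trial table.
#' @param spec list of rate parameters; see [archetypes]. Missing entries
#'   take the defaults.
#' @param seed RNG seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
simulate_neuron <- function(archetype, trials, spec = list(), seed = 1L) {
  if (!archetype %in% ARCHETYPES)
    stop("unknown archetype: ", archetype, call. = FALSE)
  if (nrow(trials) == 0) stop("trials must be non-empty", call. = FALSE)
  spec <- utils::modifyList(default_neuron_spec(), spec)
  with_seed(seed, {
    t_end <- max(trials$hold_onset + trials$hold_duration,
                 trials$reward_onset, na.rm = TRUE) + 2.0
    comp <- !trials$immature
    amp <- spec$effect * spec$baseline_hz
    lam_max <- spec$baseline_hz
    if (archetype %in% c("Hold", "Hold&Reward"))
      lam_max <- lam_max + amp * max(trials$hold_duration) /
        mean(trials$hold_duration[comp])
    if (archetype %in% c("Go", "Go&Reward")) lam_max <- lam_max + amp
    if (archetype %in% c("Reward", "Go&Reward", "Hold&Reward"))
      lam_max <- lam_max + amp
    n_cand <- rpois(1, lam_max * t_end)
    cand <- sort(runif(n_cand, 0, t_end))
    lam <- archetype_intensity(cand, archetype, trials, spec)
    keep <- runif(n_cand) < lam / lam_max
    sort(unique(round(cand[keep], 6)))
  })
}

#' Default cohort specification table
#'
#' Builds the neuron specification table for a simulated cohort:
#' `n_per_archetype` neurons of each of the six archetypes, spread over
#' CA1, LECs and LECd, alternating preferred sides. Go-like neurons are
#' split half/half between pre-release (centre -225 ms) and post-release
#' (centre +62 ms) kernels, mirroring the two phasic subpopulations seen
#' around movement onset. Within the `none` archetype half the neurons are
#' fast-spiking (short waveforms, higher baseline); everything else is
#' regular-spiking. A subset of LEC neurons carries a projection target
#' (LECs to CA1, LECd to mPFC) with a fixed antidromic latency for the
#' collision-test stage.
#'
#' @param n_per_archetype neurons per archetype (default 20).
#' @param baseline_hz regular-spiking baseline rate (Hz).
#' @param fs_baseline_hz fast-spiking baseline rate (Hz).
#' @param effect kernel peak in multiples of baseline.
#' @param regions regions to cycle through.
#' @return data.frame, one row per neuron, used by [simulate_cohort()].
#' @export
cohort_specs <- function(n_per_archetype = 20L, baseline_hz = 3,
                         fs_baseline_hz = 12, effect = 4,
                         regions = c("CA1", "LECs", "LECd")) {
  rows <- list()
  for (arch in ARCHETYPES) {
    for (j in seq_len(n_per_archetype)) {
      region <- regions[(j - 1L) %% length(regions) + 1L]
      fs <- arch == "none" && j > n_per_archetype / 2
      go_offset <- if (arch %in% c("Go", "Go&Reward")) {
        if (j %% 2L == 1L) -0.225 else 0.062
      } else NA_real_
      proj <- "none"; lat <- NA_real_
      if (region %in% c("LECs", "LECd") && j %% 4L == 2L) {
        proj <- if (region == "LECs") "CA1" else "mPFC"
        lat <- 5 + 2 * ((j %/% 4L) %% 10L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = sprintf("%s_%s_%02d", region, gsub("&", "", arch), j),
        archetype = arch, region = region,
        baseline_hz = if (fs) fs_baseline_hz else baseline_hz,
        effect = effect,
        preferred_side = SIDES[j %% 2L + 1L],
        nonpref_frac = 0.5,
        go_offset = go_offset,
        cell_class_true = if (fs) "FS" else "RS",
        projection_target = proj,
        antidromic_latency_ms = lat,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete session with ground truth
#'
#' Runs [simulate_behavior()] and realises every neuron in
#' `config$neuron_specs` with [simulate_neuron()], drawing waveform
#' durations from the RS (1.0 +/- 0.1 ms) or FS (0.3 +/- 0.05 ms) component.
#'
#' @param config a [sim_config()].
#' @return List with `session` (a validated `taskspike_session`) and
#'   `truth` (data.frame of per-neuron generative labels: archetype,
#'   preferred side, cell class, projection target and antidromic latency).
#' @export
simulate_cohort <- function(config) {
  beh <- simulate_behavior(config)
  specs <- config$neuron_specs
  spikes <- vector("list", nrow(specs))
  durations <- numeric(nrow(specs))
  with_seed(derive_seed(config$seed, 2L), {
    durations <- ifelse(specs$cell_class_true == "FS",
                        rnorm(nrow(specs), 0.30, 0.05),
                        rnorm(nrow(specs), 1.00, 0.10))
    durations <- round(pmax(durations, 0.05), 4)
  })
  for (i in seq_len(nrow(specs))) {
    sp <- list(baseline_hz = specs$baseline_hz[i], effect = specs$effect[i],
               preferred_side = specs$preferred_side[i],
               nonpref_frac = specs$nonpref_frac[i])
    if (!is.na(specs$go_offset[i])) sp$go_offset <- specs$go_offset[i]
    spikes[[i]] <- data.frame(
      neuron_id = specs$neuron_id[i],
      spike_time_s = simulate_neuron(specs$archetype[i], beh$trials, sp,
                                     seed = derive_seed(config$seed, 100L + i)),
      stringsAsFactors = FALSE)
  }
  session <- new_session(
    trials = beh$trials, pedals = beh$pedals,
    neurons = data.frame(neuron_id = specs$neuron_id, region = specs$region,
                         spike_duration_ms = durations,
                         cell_class = "unset", stringsAsFactors = FALSE),
    spikes = do.call(rbind, spikes),
    metadata = list(session_id = sprintf("sim-%d", config$seed),
                    group = "post-training", hemisphere = "left",
                    pedal_sample_rate = config$pedal_sample_rate))
  validate_session(session)
  truth <- data.frame(
    neuron_id = specs$neuron_id, archetype = specs$archetype,
    region = specs$region, preferred_side = specs$preferred_side,
    laterality_sign = ifelse(
      specs$preferred_side == contra_side(session$metadata$hemisphere), 1L, -1L),
    cell_class_true = specs$cell_class_true,
    baseline_hz = specs$baseline_hz,
    go_offset = specs$go_offset,
    projection_target = specs$projection_target,
    antidromic_latency_ms = specs$antidromic_latency_ms,
    stringsAsFactors = FALSE)
  list(session = session, truth = truth)
}
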
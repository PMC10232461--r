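#' Session data model
#'
#' A session bundles everything recorded (or simulated) in one behavioural
#' recording: the trial event table, the two pedal position traces, the
#' per-neuron spike trains, optional antidromic stimulation events, and
#' session metadata (group, recorded hemisphere). All times are in seconds
#' relative to session start and are stored at microsecond precision.
#'
#' @param trials data.frame with columns `trial_id`, `hold_onset`,
#'   `hold_duration`, `release_onset`, `released_side`, `block_side`,
#'   `correct`, `immature`, `reward_onset`. Release/reward fields are `NA`
#'   where absent (immature / unrewarded trials).
#' @param pedals data.frame with columns `time_s`, `left_pct`, `right_pct`;
#'   uniformly sampled pedal positions in percent of the range of motion.
#' @param neurons data.frame with columns `neuron_id`, `region`,
#'   `spike_duration_ms`, `cell_class` (one of `"RS"`, `"FS"`, `"unset"`).
#' @param spikes data.frame with columns `neuron_id`, `spike_time_s`,
#'   one row per spike, sorted in time within each neuron.
#' @param stims optional data.frame with columns `stim_time_s`, `site`,
#'   `pulse_ms`, `triggered`, `trigger_spike_time_s`.
#' @param metadata list; recognised fields are `session_id`, `group`
#'   (`"pre-training"` or `"post-training"`), `hemisphere` (`"left"` or
#'   `"right"`, the recorded hemisphere used to derive contra/ipsi), and
#'   `pedal_sample_rate` (Hz).
#' @return An object of class `taskspike_session`.
#' @export
new_session <- function(trials, pedals, neurons, spikes, stims = NULL,
                        metadata = list()) {
  s <- structure(
    list(trials = trials, pedals = pedals, neurons = neurons,
         spikes = spikes, stims = stims, metadata = metadata),
    class = "taskspike_session")
  s
}

#' @export
print.taskspike_session <- function(x, ...) {
  cat(sprintf("<taskspike_session> %s (%s)\n",
              x$metadata$session_id %||% "unnamed",
              x$metadata$group %||% "ungrouped"))
  cat(sprintf("  %d trials (%d correct, %d immature), %d neurons, %d spikes\n",
              nrow(x$trials), sum(x$trials$correct %in% TRUE),
              sum(x$trials$immature %in% TRUE),
              nrow(x$neurons), nrow(x$spikes)))
  if (!is.null(x$stims) && nrow(x$stims) > 0)
    cat(sprintf("  %d stimulation events\n", nrow(x$stims)))
  invisible(x)
}

REGIONS <- c("CA1", "LECs", "LECd", "M1")
SIDES <- c("left", "right")
REWARD_DELAYS <- c(0.3, 0.4, 0.5, 0.6, 0.7)
TIME_TOL <- 2e-6  # times are stored at 1 microsecond precision

#' Validate a session against the task invariants
#'
#' Checks the trial-table invariants (completed trials have
#' `release_onset = hold_onset + hold_duration`, holding lasted at least 1 s,
#' reward follows release by 0.3-0.7 s in 0.1 s steps, `correct` matches
#' `released_side == block_side`, immature trials carry no release or reward),
#' the pedal-trace invariants (positions within 0-100, uniform strictly
#' increasing sample times), strictly increasing spike times per neuron, and
#' cross-reference integrity between the spike and neuron tables.
#'
#' @param session a `taskspike_session`.
#' @return `session`, invisibly, if valid; otherwise an error listing the
#'   offending rows.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "taskspike_session"))
  tr <- session$trials
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)

  if (nrow(tr) > 0) {
    comp <- !tr$immature
    bad <- which(comp & abs(tr$release_onset - (tr$hold_onset + tr$hold_duration)) > TIME_TOL)
    if (length(bad)) add(sprintf(
      "trials: release_onset != hold_onset + hold_duration in rows %s",
      paste(bad, collapse = ", ")))
    bad <- which(comp & tr$hold_duration < 1.0 - TIME_TOL)
    if (length(bad)) add(sprintf(
      "trials: completed trial with hold_duration < 1 s in rows %s",
      paste(bad, collapse = ", ")))
    bad <- which(tr$immature & tr$hold_duration >= 1.0)
    if (length(bad)) add(sprintf(
      "trials: immature trial with hold_duration >= 1 s in rows %s",
      paste(bad, collapse = ", ")))
    delay <- tr$reward_onset - tr$release_onset
    bad <- which(tr$correct &
                   !vapply(delay, function(d)
                     !is.na(d) && any(abs(d - REWARD_DELAYS) <= TIME_TOL), logical(1)))
    if (length(bad)) add(sprintf(
      "trials: reward delay not in {0.3..0.7 by 0.1} s in rows %s",
      paste(bad, collapse = ", ")))
    bad <- which(comp & (tr$correct != (tr$released_side == tr$block_side)))
    if (length(bad)) add(sprintf(
      "trials: correct flag inconsistent with released vs block side in rows %s",
      paste(bad, collapse = ", ")))
    bad <- which(tr$immature & (tr$correct | !is.na(tr$reward_onset) |
                                  !is.na(tr$release_onset)))
    if (length(bad)) add(sprintf(
      "trials: immature trial marked correct or carrying release/reward in rows %s",
      paste(bad, collapse = ", ")))
    bad <- which(!tr$correct & !is.na(tr$reward_onset))
    if (length(bad)) add(sprintf(
      "trials: reward_onset present on non-correct trial in rows %s",
      paste(bad, collapse = ", ")))
    bad <- which(!tr$released_side %in% c(SIDES, NA) |
                   !tr$block_side %in% SIDES)
    if (length(bad)) add(sprintf("trials: unknown side label in rows %s",
                                 paste(bad, collapse = ", ")))
  }

  pd <- session$pedals
  if (nrow(pd) > 1) {
    if (any(pd$left_pct < -TIME_TOL | pd$left_pct > 100 + TIME_TOL, na.rm = TRUE) ||
        any(pd$right_pct < -TIME_TOL | pd$right_pct > 100 + TIME_TOL, na.rm = TRUE))
      add("pedals: position outside [0, 100]")
    dt <- diff(pd$time_s)
    if (any(dt <= 0)) add("pedals: sample times not strictly increasing")
    else if (diff(range(dt)) > 10 * TIME_TOL) add("pedals: sample times not uniform")
  }

  sp <- session$spikes
  if (nrow(sp) > 0) {
    if (!all(sp$neuron_id %in% session$neurons$neuron_id))
      add("spikes: neuron_id not present in neuron table")
    for (id in unique(sp$neuron_id)) {
      ts <- sp$spike_time_s[sp$neuron_id == id]
      if (any(diff(ts) <= 0))
        add(sprintf("spikes: times not strictly increasing for neuron %s", id))
    }
  }
  nr <- session$neurons
  if (nrow(nr) > 0) {
    if (any(nr$spike_duration_ms <= 0))
      add("neurons: spike_duration_ms must be > 0")
    if (!all(nr$region %in% REGIONS))
      add("neurons: unknown region label")
    if (anyDuplicated(nr$neuron_id))
      add("neurons: duplicated neuron_id")
  }

  st <- session$stims
  if (!is.null(st) && nrow(st) > 1) {
    if (is.unsorted(st$stim_time_s)) add("stims: stim times not sorted")
    bad <- which(st$triggered & is.na(st$trigger_spike_time_s))
    if (length(bad)) add(sprintf(
      "stims: triggered stimulation without trigger spike time in rows %s",
      paste(bad, collapse = ", ")))
  }

  if (length(problems))
    stop("session validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(session)
}

#' Extract one neuron's spike train from a session
#'
#' @param session a `taskspike_session`.
#' @param neuron_id neuron identifier present in `session$neurons`.
#' @return A `spike_train` object: list with `neuron_id`, `region`,
#'   `spike_times` (seconds, sorted), `spike_duration_ms`, `cell_class`.
#' @export
spike_train <- function(session, neuron_id) {
  row <- session$neurons[session$neurons$neuron_id == neuron_id, ]
  if (nrow(row) != 1)
    stop("unknown neuron_id: ", neuron_id, call. = FALSE)
  structure(
    list(neuron_id = neuron_id,
         region = row$region,
         spike_times = session$spikes$spike_time_s[
           session$spikes$neuron_id == neuron_id],
         spike_duration_ms = row$spike_duration_ms,
         cell_class = row$cell_class),
    class = "spike_train")
}

#' Inclusion gate for single-neuron analysis
#'
#' A neuron enters the analysis only if the session provides at least 20
#' completed trials and the neuron fired at least 250 spikes during task
#' performance (between the first holding onset and the end of the last
#' trial, plus 1 s).
#'
#' @param spikes a `spike_train` or a numeric vector of spike times (s).
#' @param trials the session trial table.
#' @return `TRUE` if the neuron satisfies both gates.
#' @export
validate_inclusion <- function(spikes, trials) {
  ts <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  completed <- sum(!trials$immature)
  if (completed < 20) return(FALSE)
  t0 <- min(trials$hold_onset)
  t1 <- max(trials$hold_onset + trials$hold_duration,
            trials$reward_onset, na.rm = TRUE) + 1
  sum(ts >= t0 & ts <= t1) >= 250
}

# Map physical sides to contra/ipsi given the recorded hemisphere.
# Contralateral to a left-hemisphere recording is the right forelimb.
contra_side <- function(hemisphere) {
  if (!hemisphere %in% SIDES)
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  if (hemisphere == "left") "right" else "left"
}
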
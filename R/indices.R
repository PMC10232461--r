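#' Normalized peak activity
#'
#' `SR_peak / SR_baseline - 1`: 0 for no modulation, -1 for complete
#' suppression, positive values for peak rates above baseline. The peak
#' period is the centre of the peak PETH bin +/- 150 ms; the baseline
#' period is -1000 to -700 ms before release.
#'
#' @param sr_peak mean spike rate in the peak period (Hz).
#' @param sr_baseline mean spike rate in the baseline period (Hz).
#' @return Dimensionless normalized activity; `NA` with attribute
#'   `undefined = TRUE` when the baseline rate is zero (such neurons are
#'   excluded from laterality summaries).
#' @export
normalized_activity <- function(sr_peak, sr_baseline) {
  if (is.na(sr_baseline) || sr_baseline == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  sr_peak / sr_baseline - 1
}

#' Laterality index
#'
#' Bounded index of contra- vs ipsilateral movement preference built from
#' the normalized peak activities `c` (contralateral) and `i`
#' (ipsilateral):
#' `(c - i) / (c + i)` when both are positive, `+1` when only the
#' contralateral activity is positive, `-1` when only the ipsilateral
#' activity is positive. +1 therefore indicates contralateral-preferring
#' and -1 ipsilateral-preferring activity. When neither normalized
#' activity is positive the index is undefined and flagged (zeros count as
#' non-positive).
#'
#' @param c_act normalized contralateral activity.
#' @param i_act normalized ipsilateral activity.
#' @return Value in `[-1, 1]`, or `NA` with attribute `undefined = TRUE`.
#' @export
laterality_index <- function(c_act, i_act) {
  if (is.na(c_act) || is.na(i_act)) {
    out <- NA_real_; attr(out, "undefined") <- TRUE; return(out)
  }
  if (c_act > 0 && i_act > 0) return((c_act - i_act) / (c_act + i_act))
  if (c_act > 0 && i_act <= 0) return(1)
  if (c_act <= 0 && i_act > 0) return(-1)
  out <- NA_real_
  attr(out, "undefined") <- TRUE
  out
}

#' Reward modulation index
#'
#' `(SR_r - SR_nr) / (SR_r + SR_nr)` where `SR_r` and `SR_nr` are the mean
#' peak-period spike rates on rewarded (correct) and non-rewarded (error)
#' trials. Positive values indicate activity facilitated by reward. Peak
#' periods: go-related activity uses peak +/- 250 ms; reward-related
#' activity uses reward onset to 500 ms.
#'
#' @param sr_r mean rewarded-trial rate (Hz), >= 0.
#' @param sr_nr mean non-rewarded-trial rate (Hz), >= 0.
#' @return Value in `[-1, 1]`, or `NA` with attribute `undefined = TRUE`
#'   when both rates are zero.
#' @export
reward_modulation_index <- function(sr_r, sr_nr) {
  stopifnot(sr_r >= 0, sr_nr >= 0)
  if (sr_r + sr_nr == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE; return(out)
  }
  (sr_r - sr_nr) / (sr_r + sr_nr)
}

#' Mean holding-period rates by release side
#'
#' Mean spike rate in the holding period (-1000 to 0 ms before release)
#' separately for contralateral and ipsilateral release trials; used to
#' compare the limb preference of Hold-type neurons.
#'
#' @param spikes a `spike_train` or numeric vector of spike times (s).
#' @param trials the session trial table.
#' @param hemisphere recorded hemisphere (`"left"`/`"right"`).
#' @return List with `contra_hz`, `ipsi_hz` and per-side trial counts;
#'   a side without trials yields `NA` with a flag.
#' @export
hold_side_rates <- function(spikes, trials, hemisphere) {
  ts <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  cs <- contra_side(hemisphere)
  comp <- trials[!trials$immature, ]
  rate_for <- function(side) {
    at <- comp$release_onset[comp$released_side == side]
    if (!length(at)) return(NA_real_)
    mean(vapply(at, function(a) sum(ts >= a - 1 & ts <= a), numeric(1)))
  }
  list(contra_hz = rate_for(cs), ipsi_hz = rate_for(setdiff(SIDES, cs)),
       n_contra = sum(comp$released_side == cs),
       n_ipsi = sum(comp$released_side != cs))
}

#' Full activity-index computation for one neuron
#'
#' Locates the peak bin on the preferred-side unsmoothed 20 ms PETH
#' (release +/- 500 ms), reuses the same absolute peak period on the
#' non-preferred side, computes `SR_peak`, `SR_baseline`, the normalized
#' activities `c` and `i`, the laterality index, and the reward modulation
#' index (correct vs error trials) with the peak period appropriate to the
#' activity type.
#'
#' @param spikes a `spike_train` or numeric vector of spike times (s).
#' @param trials the session trial table.
#' @param hemisphere recorded hemisphere.
#' @param activity `"go"` (peak +/- 250 ms around the release-aligned peak)
#'   or `"reward"` (reward onset to 500 ms) for the reward-modulation peak
#'   period.
#' @return An `activity_indices` list with the fields above plus
#'   per-quantity undefined flags.
#' @export
activity_indices <- function(spikes, trials, hemisphere,
                             activity = c("go", "reward")) {
  activity <- match.arg(activity)
  ts <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  cs <- contra_side(hemisphere)
  comp <- trials[!trials$immature, ]
  al <- list(contra = comp$release_onset[comp$released_side == cs],
             ipsi = comp$release_onset[comp$released_side != cs])

  p_by_side <- lapply(al, function(at) if (length(at))
    compute_peth(ts, at, c(-0.5, 0.5), 0.02) else NULL)
  pref <- names(which.max(vapply(p_by_side, function(p)
    if (is.null(p)) -Inf else max(p$rates), numeric(1))))
  peak_center <- p_by_side[[pref]]$centers[which.max(p_by_side[[pref]]$rates)]

  mean_rate <- function(at, win) {
    if (!length(at)) return(NA_real_)
    mean(vapply(at, function(a)
      sum(ts >= a + win[1] & ts <= a + win[2]), numeric(1))) / diff(win)
  }
  peak_win <- peak_center + c(-0.15, 0.15)
  base_win <- c(-1.0, -0.7)
  sr <- lapply(al, function(at) list(
    peak = mean_rate(at, peak_win), base = mean_rate(at, base_win)))
  c_act <- normalized_activity(sr$contra$peak, sr$contra$base)
  i_act <- normalized_activity(sr$ipsi$peak, sr$ipsi$base)
  lat <- laterality_index(as.numeric(c_act), as.numeric(i_act))

  if (activity == "go") {
    rwd_win <- peak_center + c(-0.25, 0.25)
    sr_r <- mean_rate(comp$release_onset[comp$correct], rwd_win)
    sr_nr <- mean_rate(comp$release_onset[!comp$correct], rwd_win)
  } else {
    sr_r <- mean_rate(trials$reward_onset[trials$correct], c(0, 0.5))
    # error trials have no reward onset; use release + median delay instead
    delay <- median(trials$reward_onset - trials$release_onset, na.rm = TRUE)
    err_rel <- comp$release_onset[!comp$correct]
    sr_nr <- mean_rate(err_rel + delay, c(0, 0.5))
  }
  rmi <- if (!is.na(sr_r) && !is.na(sr_nr) && sr_r >= 0 && sr_nr >= 0)
    reward_modulation_index(sr_r, sr_nr) else
      structure(NA_real_, undefined = TRUE)

  structure(list(
    preferred_side = pref, peak_center_s = peak_center,
    sr_peak_contra = sr$contra$peak, sr_peak_ipsi = sr$ipsi$peak,
    sr_baseline_contra = sr$contra$base, sr_baseline_ipsi = sr$ipsi$base,
    c_act = as.numeric(c_act), i_act = as.numeric(i_act),
    laterality_index = as.numeric(lat),
    laterality_undefined = isTRUE(attr(lat, "undefined")),
    sr_r = sr_r, sr_nr = sr_nr,
    reward_modulation_index = as.numeric(rmi),
    reward_modulation_undefined = isTRUE(attr(rmi, "undefined"))),
    class = "activity_indices")
}
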
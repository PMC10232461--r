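#' Task-relevance index (KS test against uniform spike positions)
#'
#' Pools spike times relative to the alignment events across trials within
#' the window and compares their distribution against uniformity on the
#' window with a Kolmogorov-Smirnov test. A task-modulated neuron
#' concentrates spikes around the event, producing a small p value; the
#' index is that p value. The default is a one-sample KS test against the
#' uniform CDF, which is deterministic; `two_sample = TRUE` instead draws
#' one matched set of uniform positions and runs a two-sample test.
#'
#' @param spikes a `spike_train` or numeric vector of spike times (s).
#' @param align_times alignment event times (s).
#' @param window c(start, end) seconds relative to alignment.
#' @param two_sample compare against one random uniform draw instead of the
#'   uniform CDF.
#' @return p value in `[0, 1]`; `1` with attribute `no_spikes = TRUE` when
#'   no spikes fall in any window.
#' @export
relevance_index <- function(spikes, align_times, window, two_sample = FALSE) {
  ts <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  rel <- rel_times(ts, align_times, window)
  if (length(rel) == 0) {
    p <- 1
    attr(p, "no_spikes") <- TRUE
    return(p)
  }
  if (two_sample) {
    ref <- runif(length(rel), window[1], window[2])
    p <- suppressWarnings(ks.test(rel, ref)$p.value)
  } else {
    exact <- length(rel) <= 500
    p <- suppressWarnings(
      ks.test(rel, "punif", min = window[1], max = window[2],
              exact = exact)$p.value)
  }
  p
}

#' Release- and reward-aligned task relevance of one neuron
#'
#' Computes the task-relevance index in the release-aligned window
#' (onset +/- 500 ms) separately for contralateral and ipsilateral release
#' trials, and in the reward-aligned window (onset to 1000 ms) over correct
#' trials. A neuron is task-related when any of the three p values falls
#' below the criterion (default 1e-6). The preferred side is the release
#' side with the smaller p value; exact ties break toward contra.
#'
#' @param spikes a `spike_train` or numeric vector of spike times (s).
#' @param trials the session trial table.
#' @param hemisphere recorded hemisphere (`"left"` or `"right"`), used to
#'   map physical sides onto contra/ipsi.
#' @param criterion significance criterion on the index.
#' @param release_window,reward_window analysis windows (s).
#' @return A `task_relevance` list: `p_release_contra`, `p_release_ipsi`,
#'   `p_reward`, `preferred_side` (`"contra"`/`"ipsi"`),
#'   `preferred_side_physical`, `release_significant`, `reward_significant`,
#'   `included`, `criterion`, and `reward_computable`.
#' @export
classify_relevance <- function(spikes, trials, hemisphere,
                               criterion = 1e-6,
                               release_window = c(-0.5, 0.5),
                               reward_window = c(0, 1)) {
  cs <- contra_side(hemisphere)
  is_ <- setdiff(SIDES, cs)
  comp <- trials[!trials$immature, ]
  p_side <- function(side) {
    at <- comp$release_onset[comp$released_side == side]
    if (!length(at)) return(structure(1, no_trials = TRUE))
    relevance_index(spikes, at, release_window)
  }
  p_contra <- p_side(cs)
  p_ipsi <- p_side(is_)
  rw_times <- trials$reward_onset[trials$correct]
  reward_computable <- length(rw_times) > 0
  p_reward <- if (reward_computable)
    relevance_index(spikes, rw_times, reward_window) else NA_real_

  preferred <- if (as.numeric(p_ipsi) < as.numeric(p_contra)) "ipsi" else "contra"
  structure(list(
    p_release_contra = as.numeric(p_contra),
    p_release_ipsi = as.numeric(p_ipsi),
    p_reward = as.numeric(p_reward),
    preferred_side = preferred,
    preferred_side_physical = if (preferred == "contra") cs else is_,
    release_significant = min(as.numeric(p_contra), as.numeric(p_ipsi)) < criterion,
    reward_significant = reward_computable && !is.na(p_reward) &&
      as.numeric(p_reward) < criterion,
    reward_computable = reward_computable,
    included = validate_inclusion(spikes, trials),
    criterion = criterion), class = "task_relevance")
}
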
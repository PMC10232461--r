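#' ROC cut-off for antidromic spike presence
#'
#' Antidromic spikes leave a large negative trough in the filtered trace
#' inside the post-stimulus counting window; stimulations without a spike
#' leave only noise. The threshold separating the two trough populations
#' is taken from the ROC curve of the trough value as a classifier: with
#' known labels (simulation) the Youden-optimal point is used directly;
#' without labels, a two-component split of the trough values provides
#' pseudo-labels first, and a weakly separated split is flagged as
#' low-confidence.
#'
#' @param trough_values most negative trace values per stimulation
#'   (arbitrary filtered units; spikes are more negative).
#' @param labels optional logical vector, `TRUE` where a spike is present.
#' @return Threshold (a trough at or below it counts as a spike), with
#'   attribute `low_confidence` when pseudo-labelling was weakly bimodal.
#' @export
roc_threshold <- function(trough_values, labels = NULL) {
  if (length(trough_values) < 10)
    stop("need at least 10 trough values", call. = FALSE)
  low_conf <- FALSE
  if (is.null(labels)) {
    if (diff(range(trough_values)) == 0) {
      out <- min(trough_values) - 1
      attr(out, "low_confidence") <- TRUE
      return(out)
    }
    ctrs <- quantile(trough_values, c(0.1, 0.9), names = FALSE)
    if (ctrs[1] == ctrs[2]) ctrs <- range(trough_values)
    km <- suppressWarnings(kmeans(trough_values, centers = matrix(ctrs, 2)))
    lower <- which.min(km$centers)
    labels <- km$cluster == lower  # spike-present = more negative cluster
    m <- sort(km$centers)
    s <- sqrt(mean(c(var(trough_values[labels]),
                     var(trough_values[!labels])), na.rm = TRUE))
    if (!is.finite(s) || s == 0 || (m[2] - m[1]) / s < 2) low_conf <- TRUE
  }
  if (all(labels) || !any(labels)) {
    out <- if (all(labels)) max(trough_values) else min(trough_values) - 1
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  r <- pROC::roc(response = labels, predictor = trough_values,
                 levels = c(FALSE, TRUE), direction = ">", quiet = TRUE)
  thr <- pROC::coords(r, "best", best.method = "youden",
                      ret = "threshold", transpose = FALSE)$threshold[1]
  attr(thr, "low_confidence") <- low_conf
  thr
}

#' Spike probabilities in control and test events
#'
#' Applies the trough threshold to both event classes and tabulates spike
#' and no-spike counts.
#'
#' @param control_troughs,test_troughs trough values per stimulation.
#' @param threshold from [roc_threshold()]; troughs <= threshold count as
#'   spikes.
#' @return List with `p_control`, `p_test` and `counts` (2x2 matrix, rows
#'   control/test, columns spike/no_spike).
#' @export
spike_probabilities <- function(control_troughs, test_troughs, threshold) {
  if (!length(control_troughs) || !length(test_troughs))
    stop("control and test events must be non-empty", call. = FALSE)
  cs <- sum(control_troughs <= threshold)
  ts_ <- sum(test_troughs <= threshold)
  counts <- matrix(c(cs, length(control_troughs) - cs,
                     ts_, length(test_troughs) - ts_),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("control", "test"),
                                   c("spike", "no_spike")))
  list(p_control = cs / length(control_troughs),
       p_test = ts_ / length(test_troughs),
       counts = counts)
}

#' Chi-squared collision decision
#'
#' Pearson 2x2 chi-squared test (without continuity correction by
#' default) of spike/no-spike counts in control vs test events; the
#' collision test is passed when the counts differ at p < 0.05.
#'
#' @param counts 2x2 matrix of nonnegative integers (rows control/test,
#'   columns spike/no_spike); both margins must be positive.
#' @param correct apply the Yates continuity correction.
#' @param alpha significance level.
#' @return List with `chi2_stat`, `p`, `passes_chi2`.
#' @export
collision_decision <- function(counts, correct = FALSE, alpha = 0.05) {
  stopifnot(is.matrix(counts), all(dim(counts) == 2), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-squared test undefined: zero margin", call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  list(chi2_stat = unname(ct$statistic), p = ct$p.value,
       passes_chi2 = ct$p.value < alpha)
}

#' Antidromic latency and jitter
#'
#' Latency is the median of the post-stimulus peak (trough) positions in
#' the counting window; jitter is their interquartile range (75th minus
#' 25th percentile). The constant-latency criterion requires jitter below
#' 0.5 ms.
#'
#' @param peak_positions_ms spike peak times after stimulation onset (ms).
#' @param max_jitter_ms constant-latency bound (ms).
#' @return List with `latency_median_ms`, `jitter_ms`,
#'   `passes_constant_latency`, and `insufficient` flag when fewer than 3
#'   positions are available.
#' @export
latency_jitter <- function(peak_positions_ms, max_jitter_ms = 0.5) {
  if (length(peak_positions_ms) < 3)
    return(list(latency_median_ms = if (length(peak_positions_ms))
      median(peak_positions_ms) else NA_real_,
      jitter_ms = NA_real_, passes_constant_latency = FALSE,
      insufficient = TRUE))
  q <- quantile(peak_positions_ms, c(0.25, 0.5, 0.75), names = FALSE)
  jit <- q[3] - q[1]
  list(latency_median_ms = q[2], jitter_ms = jit,
       passes_constant_latency = jit < max_jitter_ms,
       insufficient = FALSE)
}

#' Identify a projection neuron from stimulation events
#'
#' Composes the full identification: ROC trough threshold (pseudo-labelled
#' unless labels are supplied), a pre-screen requiring antidromic-like
#' responses in many control traces (at least `min_control_spikes`
#' control events classified as spikes), the inclusion gates
#' (control spike probability strictly above 50% and test probability
#' below half of control), the 2x2 chi-squared collision decision,
#' the constant-latency test (jitter < 0.5 ms on control spike troughs),
#' and, when a frequency-following block is provided, paired-pulse
#' reliability of at least 0.8 at 100 Hz and 0.5 at 200 Hz.
#'
#' @param events data.frame from [simulate_stimulation()] (columns `kind`,
#'   `trough_amp`, `trough_time_ms`, optionally `spike_present`).
#' @param ff optional frequency-following data.frame (`freq_hz`, `n`,
#'   `responses`).
#' @param use_labels use the simulation's `spike_present` labels for the
#'   ROC threshold instead of pseudo-labelling (default FALSE).
#' @param min_control_spikes pre-screen count.
#' @param alpha chi-squared significance level.
#' @return A `collision_test` list: threshold, counts, probabilities,
#'   chi-squared statistics, latency median and jitter, per-criterion
#'   breakdown and the overall `passes` flag.
#' @export
identify_projection <- function(events, ff = NULL, use_labels = FALSE,
                                min_control_spikes = 10L, alpha = 0.05) {
  ctrl <- events[events$kind == "control", ]
  test <- events[events$kind == "test", ]
  if (nrow(test) == 0 || nrow(ctrl) == 0)
    return(structure(list(passes = FALSE, attempted = FALSE,
                          reason = "missing control or test events"),
                     class = "collision_test"))
  labels <- if (use_labels && "spike_present" %in% names(events))
    ctrl$spike_present else NULL
  thr <- if (use_labels) roc_threshold(ctrl$trough_amp, labels)
         else roc_threshold(c(ctrl$trough_amp, test$trough_amp))
  sp <- spike_probabilities(ctrl$trough_amp, test$trough_amp, as.numeric(thr))

  prescreen_ok <- sp$counts["control", "spike"] >= min_control_spikes
  gate_control <- sp$p_control > 0.5
  gate_test <- sp$p_test < 0.5 * sp$p_control
  chi <- if (prescreen_ok && !any(rowSums(sp$counts) == 0) &&
             !any(colSums(sp$counts) == 0))
    collision_decision(sp$counts, alpha = alpha)
  else list(chi2_stat = NA_real_, p = NA_real_, passes_chi2 = FALSE)

  ctrl_spk <- ctrl$trough_time_ms[ctrl$trough_amp <= as.numeric(thr)]
  lat <- latency_jitter(ctrl_spk)
  ff_ok <- TRUE
  if (!is.null(ff)) {
    rel <- ff$responses / ff$n
    ff_ok <- rel[ff$freq_hz == 100] >= 0.8 && rel[ff$freq_hz == 200] >= 0.5
  }
  breakdown <- c(prescreen = prescreen_ok,
                 control_above_half = gate_control,
                 test_below_half_control = gate_test,
                 chi2 = isTRUE(chi$passes_chi2),
                 constant_latency = isTRUE(lat$passes_constant_latency),
                 frequency_following = ff_ok)
  structure(list(
    attempted = TRUE,
    trough_threshold = as.numeric(thr),
    low_confidence = isTRUE(attr(thr, "low_confidence")),
    counts = sp$counts, p_control = sp$p_control, p_test = sp$p_test,
    chi2_stat = chi$chi2_stat, chi2_p = chi$p,
    latency_median_ms = lat$latency_median_ms, jitter_ms = lat$jitter_ms,
    criteria_breakdown = breakdown,
    passes = all(breakdown)), class = "collision_test")
}
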
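#' Classify regular-spiking vs fast-spiking neurons
#'
#' Splits the bimodal distribution of spike waveform durations
#' (onset-to-peak, ms) into RS and FS classes by minimum cross-entropy
#' thresholding of the duration histogram (the Li & Lee formulation): the
#' threshold minimizes
#' `-A1(t) * log(mu1(t)) - A2(t) * log(mu2(t))`,
#' where `mu1`, `mu2` are the mean durations below and at/above the
#' candidate threshold and `A1`, `A2` the corresponding first moments.
#' Durations greater than or equal to the threshold are labelled RS, the
#' rest FS (so a duration exactly at the threshold is RS).
#'
#' @param durations numeric vector of waveform durations (ms), at least two
#'   distinct values for a meaningful split.
#' @param bin_ms histogram bin width (ms).
#' @return A `waveform_classification` list: `threshold` (ms), `labels`
#'   (per input, `"RS"`/`"FS"`), `cross_entropy_curve` (data.frame of
#'   candidate thresholds and objective values), and `degenerate` flag
#'   (set, with a warning, for unimodal or constant input).
#' @export
classify_rs_fs <- function(durations, bin_ms = 0.02) {
  stopifnot(length(durations) >= 1, all(durations > 0))
  if (length(unique(durations)) < 2) {
    warning("degenerate duration distribution; threshold set below all values")
    thr <- min(durations)
    return(structure(list(
      threshold = thr,
      labels = rep("RS", length(durations)),
      cross_entropy_curve = data.frame(threshold = thr, objective = NA_real_),
      degenerate = TRUE), class = "waveform_classification"))
  }
  edges <- seq(floor(min(durations) / bin_ms) * bin_ms,
               ceiling(max(durations) / bin_ms) * bin_ms + bin_ms, by = bin_ms)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- tabulate(findInterval(durations, edges, rightmost.closed = TRUE),
                nbins = length(mids))

  gh <- mids * h
  cum_h <- cumsum(h); cum_gh <- cumsum(gh)
  tot_h <- sum(h); tot_gh <- sum(gh)
  # candidate threshold = lower edge of bin i (split: bins < i vs >= i)
  obj <- rep(NA_real_, length(mids))
  for (i in 2:length(mids)) {
    a1 <- cum_gh[i - 1]; n1 <- cum_h[i - 1]
    a2 <- tot_gh - a1;   n2 <- tot_h - n1
    if (n1 == 0 || n2 == 0) next
    mu1 <- a1 / n1; mu2 <- a2 / n2
    obj[i] <- -(a1 * log(mu1) + a2 * log(mu2))
  }
  # the objective is flat across the empty gap between modes (identical
  # partitions); place the threshold at the centre of the minimal plateau
  finite <- which(is.finite(obj))
  minval <- min(obj[finite])
  plateau <- finite[abs(obj[finite] - minval) < 1e-12]
  runs <- split(plateau, cumsum(c(1, diff(plateau) != 1)))
  run <- runs[[which.max(vapply(runs, length, integer(1)))]]
  thr <- edges[run[ceiling(length(run) / 2)]]
  labels <- ifelse(durations >= thr, "RS", "FS")

  # flag weakly bimodal input: both classes should be well populated and
  # separated by more than the pooled within-class spread
  n_fs <- sum(labels == "FS"); n_rs <- sum(labels == "RS")
  degen <- n_fs == 0 || n_rs == 0
  if (!degen) {
    m1 <- mean(durations[labels == "FS"]); m2 <- mean(durations[labels == "RS"])
    s <- sqrt(mean(c(var(durations[labels == "FS"]),
                     var(durations[labels == "RS"])), na.rm = TRUE))
    if (is.finite(s) && s > 0 && (m2 - m1) / s < 1) degen <- TRUE
  }
  if (degen) warning("duration distribution appears unimodal; ",
                     "threshold returned with degenerate flag")
  structure(list(
    threshold = thr, labels = labels,
    cross_entropy_curve = data.frame(threshold = edges[seq_along(mids)],
                                     objective = obj),
    degenerate = degen), class = "waveform_classification")
}
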
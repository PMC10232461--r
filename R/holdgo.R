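#' Hold-vs-Go classification by the intersection-slope procedure
#'
#' Distinguishes holding-time-dependent ramps (Hold) from release-locked
#' phasic bursts (Go). Completed trials on the preferred side are split
#' into four holding-time ranges (quartiles); a criterion level is set at
#' 75% of the peak of the all-trials release-aligned PETH (20 ms bins);
#' for each range the intersection time is the interpolated time at which
#' the range PETH last rises through the criterion before its peak; and
#' the slope of intersection time against mean holding time is obtained by
#' linear regression. A ramp that starts at hold onset shifts its crossing
#' one second earlier per extra second of holding (slope near -1), whereas
#' a release-locked burst crosses at a fixed latency (slope near 0). The
#' class boundary is at slope -0.5, with the boundary value assigned to
#' Hold.
#'
#' Range PETHs are lightly smoothed (Gaussian, `smooth_sigma_ms`) before
#' the crossing search; smoothing a linear ramp or shifting a bump leaves
#' crossing-time differences unbiased while suppressing single-bin noise.
#'
#' @param spikes a `spike_train` or numeric vector of spike times (s).
#' @param trials the session trial table.
#' @param preferred_side physical preferred side (`"left"`/`"right"`).
#' @param bin_width PETH bin width (s).
#' @param criterion_frac criterion as a fraction of the all-PETH peak.
#' @param slope_threshold class boundary: slope <= threshold is Hold.
#' @param smooth_sigma_ms Gaussian sd for the pre-search smoothing (ms).
#' @param min_per_range minimum trials per holding-time range.
#' @return A `hold_go_fit` list: `range_bounds`, `range_mean_hold`,
#'   `criterion_level` (Hz), `intersection_times` (s, NA for omitted
#'   ranges), `slope`, `class` (`"Hold"`, `"Go"` or `"indeterminate"`).
#' @export
hold_go_slope <- function(spikes, trials, preferred_side,
                          bin_width = 0.02, criterion_frac = 0.75,
                          slope_threshold = -0.5, smooth_sigma_ms = 100,
                          min_per_range = 5) {
  tr <- trials[!trials$immature & trials$released_side == preferred_side, ]
  out <- structure(list(range_bounds = NULL, range_mean_hold = NULL,
                        criterion_level = NA_real_,
                        intersection_times = NULL, slope = NA_real_,
                        class = "indeterminate"), class = "hold_go_fit")
  if (nrow(tr) < 4 * min_per_range) return(out)

  holds <- tr$hold_duration
  qs <- quantile(holds, probs = seq(0, 1, 0.25), names = FALSE)
  grp <- findInterval(holds, qs, rightmost.closed = TRUE)
  grp[grp < 1] <- 1L; grp[grp > 4] <- 4L
  if (any(tabulate(grp, 4) < min_per_range)) return(out)

  cap <- min(3, max(holds))
  window <- c(-cap, 0.5)
  smoothed <- function(at) {
    p <- compute_peth(spikes, at, window, bin_width)
    smooth_peth(p, sigma_ms = smooth_sigma_ms)
  }
  all_p <- smoothed(tr$release_onset)
  pre <- which(all_p$centers <= 0)
  crit <- criterion_frac * max(all_p$rates[pre])

  mean_hold <- tapply(holds, grp, mean)
  inter <- rep(NA_real_, 4)
  for (g in 1:4) {
    at <- tr$release_onset[grp == g]
    rp <- smoothed(at)
    pre_g <- which(rp$centers <= 0)
    pk <- pre_g[which.max(rp$rates[pre_g])]
    if (rp$rates[pk] < crit) next  # range never reaches criterion: omitted
    below <- which(rp$rates[seq_len(pk)] < crit)
    if (!length(below)) { inter[g] <- window[1]; next }
    j <- max(below)
    r0 <- rp$rates[j]; r1 <- rp$rates[j + 1]
    inter[g] <- rp$centers[j] +
      (crit - r0) / (r1 - r0) * (rp$centers[j + 1] - rp$centers[j])
  }
  valid <- which(!is.na(inter))
  out$range_bounds <- qs
  out$range_mean_hold <- as.numeric(mean_hold)
  out$criterion_level <- crit
  out$intersection_times <- inter
  if (length(valid) < 2) return(out)
  fit <- lm(inter[valid] ~ as.numeric(mean_hold)[valid])
  out$slope <- unname(coef(fit)[2])
  out$class <- if (out$slope <= slope_threshold) "Hold" else "Go"
  out
}

TASK_TYPES <- c("Hold", "Hold&Reward", "Go", "Go&Reward", "Reward", "none")

#' Assign the five-type task taxonomy label
#'
#' Release-significant neurons whose release-aligned activity peaks before
#' the release are split into Hold or Go by the intersection slope;
#' release-significant neurons peaking after the release are the
#' post-movement phasic subpopulation and are labelled Go. Reward-aligned
#' significance appends `&Reward` to an action label, or yields the pure
#' Reward type when the neuron has no release-aligned significance.
#'
#' @param relevance a `task_relevance` from [classify_relevance()].
#' @param holdgo a `hold_go_fit` from [hold_go_slope()], or NULL.
#' @param peak_before_release logical: does the preferred-side smoothed
#'   release-aligned PETH peak at or before release onset?
#' @return One of `"Hold"`, `"Hold&Reward"`, `"Go"`, `"Go&Reward"`,
#'   `"Reward"`, `"none"`.
#' @export
assign_task_type <- function(relevance, holdgo, peak_before_release) {
  if (!relevance$release_significant) {
    return(if (isTRUE(relevance$reward_significant)) "Reward" else "none")
  }
  action <- if (isTRUE(peak_before_release) && !is.null(holdgo) &&
                holdgo$class %in% c("Hold", "Go")) holdgo$class else "Go"
  if (isTRUE(relevance$reward_significant)) paste0(action, "&Reward") else action
}

#' Task-type counts and proportions per region
#'
#' @param classifications data.frame with columns `region` and `type`.
#' @return data.frame with `region`, `type`, `n`, `proportion` (summing to
#'   1 within each region).
#' @export
type_fractions <- function(classifications) {
  if (nrow(classifications) == 0)
    return(data.frame(region = character(), type = character(),
                      n = integer(), proportion = numeric()))
  tab <- as.data.frame(table(region = classifications$region,
                             type = factor(classifications$type,
                                           levels = TASK_TYPES)),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[order(tab$region, match(tab$type, TASK_TYPES)), ]
  totals <- tapply(tab$n, tab$region, sum)
  tab$proportion <- tab$n / as.numeric(totals[tab$region])
  tab <- tab[as.numeric(totals[tab$region]) > 0, ]
  rownames(tab) <- NULL
  tab
}
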
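#' Build the regression design for time-vs-pedal coding
#'
#' The response is the neuron's Gaussian-smoothed spike rate
#' (sigma = 150 ms) sampled on a uniform grid restricted to within-trial
#' spans (from each holding onset to the next); the predictors, sampled on
#' the same grid, are the left and right pedal positions and the trial
#' time, i.e. seconds elapsed since the most recent holding onset (reset
#' to zero at every holding onset). The default 20 ms grid is an
#' insensitive down-sampling given the 150 ms response smoothing; finer
#' grids are available via `resolution_ms`.
#'
#' @param session a `taskspike_session`.
#' @param spikes a `spike_train` or numeric vector of spike times (s).
#' @param resolution_ms sampling grid step (ms).
#' @param sigma_ms response smoothing sd (ms).
#' @return List with `time_s`, `response` (Hz), and `predictors`
#'   (data.frame `left_pedal`, `right_pedal`, `trial_time`); constant
#'   predictors are reported in `dropped` and removed.
#' @export
build_design <- function(session, spikes, resolution_ms = 20,
                         sigma_ms = 150) {
  ts <- if (inherits(spikes, "spike_train")) spikes$spike_times else spikes
  tr <- session$trials
  if (nrow(tr) == 0) stop("session has no trials", call. = FALSE)
  res <- resolution_ms / 1000

  onsets <- tr$hold_onset
  span_end <- c(onsets[-1], max(onsets[length(onsets)] +
                                  tr$hold_duration[nrow(tr)] + 1,
                                max(tr$reward_onset, na.rm = TRUE) + 1))
  grid <- unlist(lapply(seq_along(onsets), function(i)
    seq(onsets[i], span_end[i] - res / 2, by = res)), use.names = FALSE)

  # smoothed rate on the session-wide grid: fine binning + Gaussian kernel
  t_max <- max(span_end)
  nb <- floor(t_max / res) + 1L
  counts <- tabulate(pmin(floor(ts / res) + 1L, nb), nbins = nb)
  sig_bins <- (sigma_ms / 1000) / res
  hw <- ceiling(4 * sig_bins)
  k <- dnorm(seq(-hw, hw), sd = sig_bins); k <- k / sum(k)
  sm <- convolve(counts, rev(k), type = "open")[(hw + 1):(hw + nb)]
  rate <- sm / res
  g_idx <- pmin(floor(grid / res) + 1L, nb)
  response <- rate[g_idx]

  pd <- session$pedals
  p_rate <- session$metadata$pedal_sample_rate %||%
    (1 / median(diff(pd$time_s)))
  p_idx <- pmin(pmax(round(grid * p_rate) + 1L, 1L), nrow(pd))
  trial_idx <- findInterval(grid, onsets)
  predictors <- data.frame(
    left_pedal = pd$left_pct[p_idx],
    right_pedal = pd$right_pct[p_idx],
    trial_time = grid - onsets[pmax(trial_idx, 1L)])

  dropped <- names(predictors)[vapply(predictors, function(x)
    var(x) == 0, logical(1))]
  if (length(dropped)) predictors <- predictors[setdiff(names(predictors), dropped)]
  list(time_s = grid, response = response, predictors = predictors,
       dropped = dropped)
}

#' Stepwise selection of pedal and time predictors
#'
#' Forward-backward stepwise regression of the smoothed rate on the
#' candidate predictors, starting from the intercept-only model. A term
#' is added when the F test on the deviance reduction has p below
#' `alpha_add` (the best candidate first) and removed when its deletion
#' p value exceeds `alpha_remove`; the procedure iterates to a fixed
#' point. The model family is Gaussian with identity link (the response
#' is a continuous smoothed rate), matching the F-test branch of the
#' selection rule. Per-term p values are reported for every candidate in
#' the context of the final model (deletion tests for selected terms,
#' addition tests for excluded ones).
#'
#' Note that smoothed-rate samples are serially correlated; p values are
#' reported as classically computed, without correction for
#' autocorrelation.
#'
#' @param response numeric response vector (Hz).
#' @param predictors data.frame of candidate predictors.
#' @param alpha_add,alpha_remove entry and removal p thresholds.
#' @param max_iter iteration cap; exceeding it flags non-convergence.
#' @return A `glm_cell_result` list: `selected_terms`, `coefficients`,
#'   `term_p_values` (all candidates), `alpha_add`, `alpha_remove`,
#'   `converged`, `dropped`.
#' @export
stepwise_fit <- function(response, predictors, alpha_add = 0.05,
                         alpha_remove = 0.10, max_iter = 50L) {
  cand <- names(predictors)
  if (length(cand) == 0) stop("no usable predictors", call. = FALSE)
  dat <- cbind(data.frame(.y = response), predictors)
  fit_of <- function(terms) {
    f <- if (length(terms)) paste(".y ~", paste(terms, collapse = " + "))
         else ".y ~ 1"
    lm(stats::as.formula(f), data = dat)
  }
  f_test_p <- function(small, big) {
    a <- anova(small, big)
    a$`Pr(>F)`[2]
  }
  selected <- character(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    cur <- fit_of(selected)
    # forward step: best addition below alpha_add
    pool <- setdiff(cand, selected)
    if (length(pool)) {
      p_add <- vapply(pool, function(tm)
        f_test_p(cur, fit_of(c(selected, tm))), numeric(1))
      if (min(p_add) < alpha_add) {
        selected <- c(selected, pool[which.min(p_add)])
        cur <- fit_of(selected)
        changed <- TRUE
      }
    }
    # backward step: worst deletion above alpha_remove
    if (length(selected)) {
      p_drop <- vapply(selected, function(tm)
        f_test_p(fit_of(setdiff(selected, tm)), cur), numeric(1))
      if (max(p_drop) > alpha_remove) {
        selected <- setdiff(selected, selected[which.max(p_drop)])
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  final <- fit_of(selected)
  term_p <- vapply(cand, function(tm) {
    if (tm %in% selected)
      f_test_p(fit_of(setdiff(selected, tm)), final)
    else
      f_test_p(final, fit_of(c(selected, tm)))
  }, numeric(1))
  structure(list(
    candidate_terms = cand, selected_terms = selected,
    coefficients = coef(final), term_p_values = term_p,
    alpha_add = alpha_add, alpha_remove = alpha_remove,
    converged = converged,
    residual_df = final$df.residual), class = "glm_cell_result")
}

#' Classify a cell as Time-, Time&Pedal- or Pedal-correlated
#'
#' A candidate term counts as significant when it was selected and its
#' p value survives Bonferroni correction over the three candidate
#' predictors. Cells with only the trial-time term are Time cells, cells
#' with only pedal terms are Pedal cells, cells with both are Time&Pedal,
#' and cells with neither are unclassified.
#'
#' @param result a `glm_cell_result` from [stepwise_fit()].
#' @param alpha base significance level before correction.
#' @param n_candidates Bonferroni factor (number of candidate predictors).
#' @return One of `"Time"`, `"Time&Pedal"`, `"Pedal"`, `"none"`.
#' @export
classify_glm <- function(result, alpha = 0.05, n_candidates = 3L) {
  a <- alpha / n_candidates
  sig <- names(result$term_p_values)[
    names(result$term_p_values) %in% result$selected_terms &
      result$term_p_values < a]
  time_sig <- "trial_time" %in% sig
  pedal_sig <- any(c("left_pedal", "right_pedal") %in% sig)
  if (time_sig && pedal_sig) "Time&Pedal"
  else if (time_sig) "Time"
  else if (pedal_sig) "Pedal"
  else "none"
}
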
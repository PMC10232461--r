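#' Pipeline configuration
#'
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it deterministically.
#' @param sim a [sim_config()] for the simulation stage (its seed is
#'   overridden by `seed`).
#' @param out_dir directory for stage outputs and report tables; `NULL`
#'   keeps everything in memory.
#' @param stages named logical vector toggling the stages `simulate`,
#'   `classify`, `indices`, `glm`, `cluster`, `flow`, `collision`.
#' @param criterion task-relevance criterion.
#' @param glm_types task types entered into the time-vs-pedal GLM stage.
#' @param gmm_repeats EM repeats per component count in the latency
#'   clustering stage.
#' @param flow_B bootstrap repeats for the pseudo-signal-flow stage.
#' @param collision_n_control,collision_n_test stimulation counts per
#'   neuron in the collision stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            out_dir = NULL,
                            stages = c(simulate = TRUE, classify = TRUE,
                                       indices = TRUE, glm = TRUE,
                                       cluster = TRUE, flow = TRUE,
                                       collision = TRUE),
                            criterion = 1e-6,
                            glm_types = c("Hold", "Hold&Reward"),
                            gmm_repeats = 200L,
                            flow_B = 1000L,
                            collision_n_control = 30L,
                            collision_n_test = 30L) {
  sim$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Classify every included neuron of a session
#'
#' Runs the inclusion gate, RS/FS waveform thresholding, the release- and
#' reward-aligned task-relevance tests, the Hold/Go intersection-slope fit
#' and the taxonomy assignment for each neuron.
#'
#' @param session a `taskspike_session`.
#' @param criterion task-relevance criterion.
#' @return data.frame with one row per neuron: p values, preferred side,
#'   slope, peak side flag, cell class and task type (`NA` type for
#'   excluded neurons).
#' @export
classify_cohort <- function(session, criterion = 1e-6) {
  hemi <- session$metadata$hemisphere %||% "left"
  wc <- classify_rs_fs(session$neurons$spike_duration_ms)
  rows <- lapply(seq_len(nrow(session$neurons)), function(i) {
    id <- session$neurons$neuron_id[i]
    st <- spike_train(session, id)
    base <- data.frame(
      neuron_id = id, region = st$region, cell_class = wc$labels[i],
      included = FALSE, p_contra = NA_real_, p_ipsi = NA_real_,
      p_reward = NA_real_, preferred_side = NA_character_,
      preferred_side_physical = NA_character_, slope = NA_real_,
      peak_before_release = NA, type = NA_character_,
      stringsAsFactors = FALSE)
    ok <- tryCatch({
      if (!validate_inclusion(st, session$trials)) return(base)
      rel <- classify_relevance(st, session$trials, hemi, criterion)
      base$included <- TRUE
      base$p_contra <- rel$p_release_contra
      base$p_ipsi <- rel$p_release_ipsi
      base$p_reward <- rel$p_reward
      base$preferred_side <- rel$preferred_side
      base$preferred_side_physical <- rel$preferred_side_physical
      hg <- NULL; pk_before <- NA
      if (rel$release_significant) {
        pref_rel <- session$trials$release_onset[
          !session$trials$immature &
            session$trials$released_side == rel$preferred_side_physical]
        sm <- smooth_peth(st, sigma_ms = 12.5, align_times = pref_rel,
                          window = c(-0.5, 0.5))
        pk_before <- peak_latency(sm) <= 0
        hg <- hold_go_slope(st, session$trials, rel$preferred_side_physical)
        base$slope <- hg$slope
      }
      base$peak_before_release <- pk_before
      base$type <- assign_task_type(rel, hg, pk_before)
      TRUE
    }, error = function(e) {
      warning("neuron ", id, " skipped: ", conditionMessage(e))
      FALSE
    })
    base
  })
  do.call(rbind, rows)
}

run_indices_stage <- function(session, cls) {
  hemi <- session$metadata$hemisphere %||% "left"
  task <- cls[!is.na(cls$type) & cls$type != "none", ]
  rows <- lapply(seq_len(nrow(task)), function(i) {
    id <- task$neuron_id[i]
    kind <- if (task$type[i] %in% c("Reward")) "reward" else "go"
    ai <- tryCatch(
      activity_indices(spike_train(session, id), session$trials, hemi, kind),
      error = function(e) NULL)
    if (is.null(ai)) return(NULL)
    data.frame(neuron_id = id, type = task$type[i], region = task$region[i],
               c_act = ai$c_act, i_act = ai$i_act,
               laterality_index = ai$laterality_index,
               laterality_undefined = ai$laterality_undefined,
               sr_r = ai$sr_r, sr_nr = ai$sr_nr,
               reward_modulation_index = ai$reward_modulation_index,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

run_glm_stage <- function(session, cls, glm_types) {
  sel <- cls[!is.na(cls$type) & cls$type %in% glm_types, ]
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    id <- sel$neuron_id[i]
    res <- tryCatch({
      des <- build_design(session, spike_train(session, id))
      fit <- stepwise_fit(des$response, des$predictors)
      data.frame(neuron_id = id, region = sel$region[i], type = sel$type[i],
                 selected_terms = paste(fit$selected_terms, collapse = "+"),
                 p_left = unname(fit$term_p_values["left_pedal"]),
                 p_right = unname(fit$term_p_values["right_pedal"]),
                 p_time = unname(fit$term_p_values["trial_time"]),
                 glm_class = classify_glm(fit), stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    res
  })
  do.call(rbind, rows)
}

run_latency_stage <- function(session, cls, gmm_repeats, seed) {
  task <- cls[!is.na(cls$type), ]
  lat_rows <- list()
  for (i in seq_len(nrow(task))) {
    ty <- task$type[i]
    id <- task$neuron_id[i]
    st <- spike_train(session, id)
    if (ty %in% c("Go", "Go&Reward")) {
      at <- session$trials$release_onset[
        !session$trials$immature &
          session$trials$released_side == task$preferred_side_physical[i]]
      sm <- smooth_peth(st, 12.5, align_times = at, window = c(-0.5, 0.5))
      lat_rows[[length(lat_rows) + 1L]] <- data.frame(
        neuron_id = id, region = task$region[i], alignment = "release",
        latency_ms = as.numeric(peak_latency(sm)), stringsAsFactors = FALSE)
    }
    if (ty %in% c("Reward", "Go&Reward")) {
      at <- session$trials$reward_onset[session$trials$correct]
      sm <- smooth_peth(st, 12.5, align_times = at, window = c(0, 1))
      lat_rows[[length(lat_rows) + 1L]] <- data.frame(
        neuron_id = id, region = task$region[i], alignment = "reward",
        latency_ms = as.numeric(peak_latency(sm)), stringsAsFactors = FALSE)
    }
  }
  latencies <- do.call(rbind, lat_rows)
  sel_rows <- list()
  if (!is.null(latencies)) {
    for (alg in unique(latencies$alignment)) {
      for (rg in unique(latencies$region)) {
        v <- latencies$latency_ms[latencies$alignment == alg &
                                    latencies$region == rg]
        if (length(v) >= 10) {
          gs <- gmm_select(v, repeats = gmm_repeats,
                           seed = derive_seed(seed, 300L + match(rg, REGIONS)))
          xk <- xmeans_check(v, seed = derive_seed(seed, 400L + match(rg, REGIONS)))
          sel_rows[[length(sel_rows) + 1L]] <- data.frame(
            alignment = alg, region = rg, n = length(v),
            chosen_k = gs$chosen_k, xmeans_k = xk,
            mean_bic = paste(sprintf("%.3f", gs$mean_bic), collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(latencies = latencies, selection = do.call(rbind, sel_rows))
}

run_collision_stage <- function(session, truth, n_control, n_test, seed) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    st <- spike_train(session, truth$neuron_id[i])
    if (length(st$spike_times) < n_test + 10) return(NULL)
    sim <- simulate_stimulation(st, truth[i, ], n_control, n_test,
                                seed = derive_seed(seed, 500L + i))
    ct <- identify_projection(sim$events, sim$ff)
    data.frame(neuron_id = truth$neuron_id[i],
               region = truth$region[i],
               true_target = truth$projection_target[i],
               true_latency_ms = truth$antidromic_latency_ms[i],
               p_control = ct$p_control %||% NA_real_,
               p_test = ct$p_test %||% NA_real_,
               chi2_stat = ct$chi2_stat %||% NA_real_,
               chi2_p = ct$chi2_p %||% NA_real_,
               latency_median_ms = ct$latency_median_ms %||% NA_real_,
               jitter_ms = ct$jitter_ms %||% NA_real_,
               passes = isTRUE(ct$passes), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates a session (with ground truth), classifies every neuron,
#' computes the activity indices, fits the time-vs-pedal GLM on
#' hold-related cells, clusters event-peak latencies per region, runs the
#' bootstrap pseudo-signal-flow analysis, simulates and evaluates the
#' collision test per neuron, and assembles the report. Failure of one
#' neuron's analysis is logged (as a warning) and skipped. With an
#' `out_dir`, the session and every report table are written as TSV
#' files; runs with identical configuration and seed produce
#' byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return A `taskspike_report` list; see [make_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  if (!isTRUE(st[["simulate"]]))
    stop("run_pipeline currently requires the simulate stage", call. = FALSE)
  cohort <- simulate_cohort(config$sim)
  session <- cohort$session
  truth <- cohort$truth

  cls <- if (isTRUE(st[["classify"]]))
    classify_cohort(session, config$criterion) else NULL
  need <- function(stage, dep) {
    if (isTRUE(st[[stage]]) && is.null(dep))
      stop("stage '", stage, "' requires the classify stage", call. = FALSE)
    isTRUE(st[[stage]])
  }
  idx <- if (need("indices", cls)) run_indices_stage(session, cls) else NULL
  glm_tab <- if (need("glm", cls))
    run_glm_stage(session, cls, config$glm_types) else NULL
  lat <- if (need("cluster", cls))
    run_latency_stage(session, cls, config$gmm_repeats, config$seed) else NULL
  flow <- NULL
  if (isTRUE(st[["flow"]]) && !is.null(lat$latencies)) {
    rel <- lat$latencies[lat$latencies$alignment == "release", ]
    by_rg <- split(rel$latency_ms, rel$region)
    if (all(c("CA1", "LECs", "LECd") %in% names(by_rg)) &&
        all(vapply(by_rg[c("CA1", "LECs", "LECd")], length, integer(1)) > 0))
      flow <- bootstrap_flow(by_rg, B = config$flow_B,
                             seed = derive_seed(config$seed, 600L),
                             gmm_repeats = config$gmm_repeats)
  }
  col_tab <- if (isTRUE(st[["collision"]]))
    run_collision_stage(session, truth, config$collision_n_control,
                        config$collision_n_test, config$seed) else NULL

  report <- make_report(
    list(classifications = cls, indices = idx, glm = glm_tab,
         latencies = lat$latencies, gmm_selection = lat$selection,
         flow = flow, collision = col_tab, config = config),
    ground_truth = truth)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session(session, file.path(config$out_dir, "session"))
    write_tsv(truth, file.path(config$out_dir, "ground_truth.tsv"))
    write_report(report, config$out_dir)
  }
  report
}

#' Assemble the cohort report
#'
#' Builds the per-region task-type fraction table, laterality and
#' reward-modulation summaries (with one-sample signed-rank tests), the
#' GLM class table, the latency-cluster selections, the flow order-label
#' frequencies, the collision identification table, and, when ground
#' truth is available, the type confusion matrix and recovery rate.
#'
#' @param stages named list of stage outputs (see [run_pipeline()]).
#' @param ground_truth optional truth table from [simulate_cohort()].
#' @return A `taskspike_report` list of data.frames.
#' @export
make_report <- function(stages, ground_truth = NULL) {
  rep_ <- list()
  cls <- stages$classifications
  if (!is.null(cls)) {
    inc <- cls[cls$included & !is.na(cls$type), ]
    rep_$type_fractions <- type_fractions(inc)
    rep_$classifications <- cls
  }
  if (!is.null(stages$indices)) {
    idx <- stages$indices
    summ <- lapply(split(idx, idx$region), function(g) {
      li <- g$laterality_index[!g$laterality_undefined & !is.na(g$laterality_index)]
      rmi <- g$reward_modulation_index[!is.na(g$reward_modulation_index)]
      data.frame(
        region = g$region[1], n = nrow(g),
        median_laterality = if (length(li)) median(li) else NA_real_,
        median_reward_mod = if (length(rmi)) median(rmi) else NA_real_,
        p_signed_rank_rmi = if (length(rmi) >= 3 && any(rmi != 0))
          suppressWarnings(wilcox.test(rmi)$p.value) else NA_real_,
        stringsAsFactors = FALSE)
    })
    rep_$index_summary <- do.call(rbind, summ)
    rep_$indices <- idx
  }
  if (!is.null(stages$glm)) {
    rep_$glm <- stages$glm
    tab <- as.data.frame(table(region = stages$glm$region,
                               glm_class = stages$glm$glm_class),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    rep_$glm_fractions <- tab
  }
  if (!is.null(stages$latencies)) rep_$latencies <- stages$latencies
  if (!is.null(stages$gmm_selection)) rep_$gmm_selection <- stages$gmm_selection
  if (!is.null(stages$flow)) {
    rep_$flow_samples <- stages$flow$samples
    of <- as.data.frame(stages$flow$order_freq, stringsAsFactors = FALSE)
    names(of) <- c("order", "n")
    of$fraction <- of$n / sum(of$n)
    rep_$flow_orders <- of
  }
  if (!is.null(stages$collision)) rep_$collision <- stages$collision

  if (!is.null(ground_truth) && !is.null(cls)) {
    m <- merge(cls[, c("neuron_id", "type")],
               ground_truth[, c("neuron_id", "archetype")], by = "neuron_id")
    m <- m[!is.na(m$type), ]
    if (nrow(m)) {
      cm <- as.data.frame(table(truth = factor(m$archetype, TASK_TYPES),
                                recovered = factor(m$type, TASK_TYPES)),
                          stringsAsFactors = FALSE)
      names(cm)[3] <- "n"
      rep_$confusion <- cm
      rep_$recovery <- data.frame(
        n = nrow(m), exact_agreement = mean(m$type == m$archetype))
    }
  }
  structure(rep_, class = "taskspike_report")
}

# Write every report table as a TSV with fixed formatting (byte-stable).
write_report <- function(report, out_dir) {
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.data.frame(x)) {
      num <- vapply(x, is.numeric, logical(1))
      x[num] <- lapply(x[num], function(v)
        ifelse(is.na(v), "", sprintf("%.10g", v)))
      write_tsv(x, file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  invisible(out_dir)
}

#' @export
print.taskspike_report <- function(x, ...) {
  cat("<taskspike_report>\n  tables:", paste(names(x), collapse = ", "), "\n")
  if (!is.null(x$recovery))
    cat(sprintf("  type recovery: %.1f%% of %d neurons\n",
                100 * x$recovery$exact_agreement, x$recovery$n))
  invisible(x)
}
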
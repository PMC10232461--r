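#' Session I/O
#'
#' A session is stored as a directory of plain tab-separated files so that
#' fixtures stay inspectable and diff-able:
#'
#' * `trials.tsv`: `trial_id, hold_onset_s, hold_duration_s, release_onset_s,
#'   released_side, block_side, correct, immature, reward_onset_s`
#' * `neurons.tsv`: `neuron_id, region, spike_duration_ms, cell_class`
#' * `spikes.tsv`: `neuron_id, spike_time_s` (one row per spike)
#' * `pedals.tsv`: `time_s, left_pct, right_pct`
#' * `stims.tsv` (optional): `stim_time_s, site, pulse_ms, triggered,
#'   trigger_spike_time_s`
#' * `metadata.tsv`: key/value pairs
#' * `manifest.tsv`: per-file MD5 checksums, verified on read
#'
#' Times are written with microsecond precision; positions with 10^-4 %
#' precision. A session whose values are representable at those precisions
#' round-trips bit-identically.
#'
#' @name session-io
NULL

fmt_num <- function(x, digits) {
  out <- ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8", eol = "\n")
}

read_tsv <- function(path, colClasses = NA) {
  read.delim(path, sep = "\t", na.strings = "", stringsAsFactors = FALSE,
             colClasses = colClasses)
}

SESSION_FILES <- c("trials.tsv", "neurons.tsv", "spikes.tsv", "pedals.tsv",
                   "metadata.tsv")

#' Write a session to a directory of tabular files
#'
#' @param session a validated `taskspike_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly. `read_session(path)` reproduces the session
#'   at the declared storage precision.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)

  tr <- session$trials
  write_tsv(data.frame(
    trial_id = tr$trial_id,
    hold_onset_s = fmt_num(tr$hold_onset, 6),
    hold_duration_s = fmt_num(tr$hold_duration, 6),
    release_onset_s = fmt_num(tr$release_onset, 6),
    released_side = ifelse(is.na(tr$released_side), "", tr$released_side),
    block_side = tr$block_side,
    correct = tr$correct,
    immature = tr$immature,
    reward_onset_s = fmt_num(tr$reward_onset, 6),
    stringsAsFactors = FALSE), file.path(path, "trials.tsv"))

  write_tsv(data.frame(
    neuron_id = session$neurons$neuron_id,
    region = session$neurons$region,
    spike_duration_ms = fmt_num(session$neurons$spike_duration_ms, 4),
    cell_class = session$neurons$cell_class,
    stringsAsFactors = FALSE), file.path(path, "neurons.tsv"))

  write_tsv(data.frame(
    neuron_id = session$spikes$neuron_id,
    spike_time_s = fmt_num(session$spikes$spike_time_s, 6),
    stringsAsFactors = FALSE), file.path(path, "spikes.tsv"))

  write_tsv(data.frame(
    time_s = fmt_num(session$pedals$time_s, 6),
    left_pct = fmt_num(session$pedals$left_pct, 4),
    right_pct = fmt_num(session$pedals$right_pct, 4),
    stringsAsFactors = FALSE), file.path(path, "pedals.tsv"))

  md <- session$metadata
  keys <- names(md)
  write_tsv(data.frame(
    key = keys %||% character(),
    value = vapply(md, function(v) as.character(v)[1], character(1)),
    stringsAsFactors = FALSE), file.path(path, "metadata.tsv"))

  files <- SESSION_FILES
  if (!is.null(session$stims)) {
    st <- session$stims
    write_tsv(data.frame(
      stim_time_s = fmt_num(st$stim_time_s, 6),
      site = st$site,
      pulse_ms = fmt_num(st$pulse_ms, 4),
      triggered = st$triggered,
      trigger_spike_time_s = fmt_num(st$trigger_spike_time_s, 6),
      stringsAsFactors = FALSE), file.path(path, "stims.tsv"))
    files <- c(files, "stims.tsv")
  }

  sums <- tools::md5sum(file.path(path, files))
  write_tsv(data.frame(file = files, md5 = unname(sums),
                       stringsAsFactors = FALSE),
            file.path(path, "manifest.tsv"))
  invisible(path)
}

#' Read and validate a session directory
#'
#' Verifies the manifest checksums, reads the component tables, rebuilds the
#' session object and runs [validate_session()].
#'
#' @param path directory written by [write_session()].
#' @return A validated `taskspike_session`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("missing component: session directory ", path)
  for (f in SESSION_FILES)
    if (!file.exists(file.path(path, f)))
      stop("missing component: ", f, call. = FALSE)

  mf <- file.path(path, "manifest.tsv")
  if (file.exists(mf)) {
    man <- read_tsv(mf, colClasses = c("character", "character"))
    sums <- tools::md5sum(file.path(path, man$file))
    bad <- man$file[is.na(sums) | unname(sums) != man$md5]
    if (length(bad))
      stop("session container corrupt (checksum mismatch): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  trf <- read_tsv(file.path(path, "trials.tsv"), colClasses = c(
    trial_id = "integer", hold_onset_s = "numeric",
    hold_duration_s = "numeric", release_onset_s = "numeric",
    released_side = "character", block_side = "character",
    correct = "logical", immature = "logical", reward_onset_s = "numeric"))
  trials <- data.frame(
    trial_id = trf$trial_id, hold_onset = trf$hold_onset_s,
    hold_duration = trf$hold_duration_s, release_onset = trf$release_onset_s,
    released_side = trf$released_side, block_side = trf$block_side,
    correct = trf$correct, immature = trf$immature,
    reward_onset = trf$reward_onset_s, stringsAsFactors = FALSE)

  neurons <- read_tsv(file.path(path, "neurons.tsv"), colClasses = c(
    neuron_id = "character", region = "character",
    spike_duration_ms = "numeric", cell_class = "character"))
  spikes <- read_tsv(file.path(path, "spikes.tsv"), colClasses = c(
    neuron_id = "character", spike_time_s = "numeric"))
  pedals <- read_tsv(file.path(path, "pedals.tsv"), colClasses = c(
    time_s = "numeric", left_pct = "numeric", right_pct = "numeric"))

  mdf <- read_tsv(file.path(path, "metadata.tsv"),
                  colClasses = c("character", "character"))
  metadata <- as.list(setNames(mdf$value, mdf$key))
  if (!is.null(metadata$pedal_sample_rate))
    metadata$pedal_sample_rate <- as.numeric(metadata$pedal_sample_rate)

  stims <- NULL
  if (file.exists(file.path(path, "stims.tsv")))
    stims <- {
      stf <- read_tsv(file.path(path, "stims.tsv"), colClasses = c(
        stim_time_s = "numeric", site = "character", pulse_ms = "numeric",
        triggered = "logical", trigger_spike_time_s = "numeric"))
      names(stf) <- c("stim_time_s", "site", "pulse_ms", "triggered",
                      "trigger_spike_time_s")
      stf
    }

  s <- new_session(trials, pedals, neurons, spikes, stims, metadata)
  validate_session(s)
  s
}
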
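#' Multichannel intracranial recording container
#'
#' Bundles a channels-by-time sample matrix (microvolts) with its sampling
#' rate and per-channel metadata. This is the raw-data carrier every
#' preprocessing step consumes and returns.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Optional data frame with columns `name`, `label`
#'   (anatomical label) and `good` (logical artifact flag). Defaults are
#'   generated when omitted.
#'
#' @return An object of class `si_recording` with elements `samples`,
#'   `sampling_rate` and `channels`.
#' @export
recording <- function(samples, sampling_rate, channels = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    .stopf("`samples` must be a numeric channels x time matrix")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    .stopf("`sampling_rate` must be a positive number of Hz")
  nch <- nrow(samples)
  if (is.null(channels)) {
    channels <- data.frame(
      name = sprintf("ch%02d", seq_len(nch)),
      label = rep("unknown", nch),
      good = rep(TRUE, nch),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(channels) == nch, all(c("name", "label", "good") %in% names(channels)))
  if (!any(channels$good)) .stopf("a recording needs at least one good channel")
  structure(
    list(samples = samples, sampling_rate = sampling_rate, channels = channels),
    class = "si_recording"
  )
}

#' @export
print.si_recording <- function(x, ...) {
  cat(sprintf(
    "<si_recording> %d channels x %d samples @ %g Hz (%.1f s), %d good\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate,
    ncol(x$samples) / x$sampling_rate, sum(x$channels$good)
  ))
  invisible(x)
}

#' Per-trial behavioural events
#'
#' Validates and types a table of per-trial event times (seconds from
#' recording start). Required columns: `trial_id`, `task`, `stimulus_onset_s`,
#' `stimulus_offset_s`, `go_cue_s`, `voice_onset_s`, `voice_offset_s`. Within
#' each trial the recorded times must be non-decreasing. A missing
#' `stimulus_onset_s` column is tolerated (stimulus-aligned analyses are then
#' unavailable), mirroring recordings where the stimulus trigger was lost.
#'
#' @param df Data frame of events, one row per trial.
#' @return A data frame of class `si_events`. The attribute `silence_anchor_s`
#'   holds the task-dependent start of the silence window after voice offset
#'   (0.5 s for auditory tasks, 1.5 s otherwise).
#' @export
trial_events <- function(df) {
  req <- c("trial_id", "task", "stimulus_offset_s", "go_cue_s",
           "voice_onset_s", "voice_offset_s")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("events table is missing column(s): %s", paste(miss, collapse = ", "))
  has_stim_on <- "stimulus_onset_s" %in% names(df)
  ord_cols <- c(if (has_stim_on) "stimulus_onset_s", "stimulus_offset_s",
                "go_cue_s", "voice_onset_s", "voice_offset_s")
  for (i in seq_len(nrow(df))) {
    tt <- as.numeric(df[i, ord_cols])
    if (anyNA(tt)) next  # flagged, not fatal: trials with missing voice onset are dropped later
    if (any(tt < 0)) .stopf("negative event time in trial %s", df$trial_id[i])
    if (is.unsorted(tt)) .stopf("event times out of order in trial %s (%s)",
                                df$trial_id[i], paste(ord_cols, collapse = " <= "))
  }
  task <- as.character(df$task[1])
  auditory <- grepl("^auditory", task)
  structure(
    df,
    class = c("si_events", "data.frame"),
    has_stimulus_onset = has_stim_on,
    silence_anchor_s = if (auditory) 0.5 else 1.5
  )
}

#' Write / read the flat binary signal container
#'
#' Signals are stored as channel-major little-endian `float64` with a JSON
#' sidecar (`<path>.json`) carrying channel names, anatomical labels, good
#' flags, roles (synthetic data only), sampling rate and units. The
#' round-trip is lossless.
#'
#' @param rec An `si_recording`.
#' @param path Path of the binary file to write (sidecar gets `.json` added).
#' @param roles Optional per-channel role labels to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_signals <- function(rec, path, roles = NULL) {
  stopifnot(inherits(rec, "si_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$samples)), con, size = 8, endian = "little")
  sidecar <- list(
    channel_names = rec$channels$name,
    anatomical_labels = rec$channels$label,
    good = rec$channels$good,
    sampling_rate_hz = rec$sampling_rate,
    n_samples = ncol(rec$samples),
    units = "uV"
  )
  if (!is.null(roles)) sidecar$roles <- roles
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signals
#' @param path Path of the binary file written by [write_signals()].
#' @return For `read_signals`, the reconstructed `si_recording` (roles, if
#'   present in the sidecar, attached as attribute `roles`).
#' @export
read_signals <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path)) .stopf("sidecar not found: %s", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$sampling_rate_hz)) .stopf("sidecar %s lacks sampling_rate_hz", sc_path)
  nch <- length(sc$channel_names)
  nsam <- sc$n_samples
  expect_bytes <- as.numeric(nch) * nsam * 8
  if (file.size(path) != expect_bytes)
    .stopf("binary %s has %d bytes, sidecar implies %d (channels x samples x 8)",
           path, file.size(path), expect_bytes)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = nch * nsam, size = 8, endian = "little")
  rec <- recording(
    matrix(x, nrow = nch, byrow = TRUE), sc$sampling_rate_hz,
    data.frame(name = sc$channel_names, label = sc$anatomical_labels,
               good = sc$good, stringsAsFactors = FALSE)
  )
  if (!is.null(sc$roles)) attr(rec, "roles") <- sc$roles
  rec
}

#' Write / read the per-trial events table
#'
#' Tab-separated, one row per trial, times in seconds from recording start
#' written with 6-decimal fixed point.
#'
#' @param events An `si_events` table (or plain data frame with the required
#'   columns).
#' @param path File path.
#' @return `path` (write) or an `si_events` table (read).
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "trial_id"
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  trial_events(df)
}

#' Threshold-based artifact exclusion
#'
#' A deliberately simple automated stand-in for manual artifact review:
#' channels whose peak absolute amplitude or sample variance exceeds
#' `amp_thresh` resp. `var_thresh` times the across-channel median are
#' flagged bad; epochs (if given) whose peak amplitude exceeds the channel
#' threshold are masked out.
#'
#' @param rec An `si_recording`.
#' @param amp_thresh,var_thresh Multiples of the across-channel median peak
#'   amplitude / variance above which a channel is excluded. `Inf` disables
#'   a criterion.
#' @return The recording with updated `good` flags; attribute `report` lists
#'   per-channel statistics and decisions.
#' @export
exclude_artifacts <- function(rec, amp_thresh = 10, var_thresh = 10) {
  stopifnot(inherits(rec, "si_recording"))
  if (!(amp_thresh > 0) || !(var_thresh > 0)) .stopf("thresholds must be positive")
  peak <- apply(abs(rec$samples), 1, max)
  v <- apply(rec$samples, 1, stats::var)
  bad <- (peak > amp_thresh * stats::median(peak)) | (v > var_thresh * stats::median(v))
  if (all(bad | !rec$channels$good)) .stopf("artifact thresholds would exclude every channel")
  rec$channels$good <- rec$channels$good & !bad
  attr(rec, "report") <- data.frame(
    name = rec$channels$name, peak_uV = peak, variance = v,
    excluded = bad, stringsAsFactors = FALSE
  )
  rec
}
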
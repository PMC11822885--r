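#' Mean band power in consecutive 100 ms windows
#'
#' Computes `n_windows` non-overlapping 100 ms mean-power values per channel,
#' the last window ending at `end_time`. Windows are half-open
#' `[start, end)`. If any sample inside the span is invalid (filter-edge
#' mask) or out of bounds, `NA` is returned for every channel so the caller
#' can exclude the trial.
#'
#' @param env An `si_envelope`.
#' @param end_time End of the last window, seconds from record start.
#' @param n_windows 1 or 4.
#' @param width Window width in seconds (0.100).
#' @return A channels x n_windows matrix of means, or all-`NA` when the span
#'   touches invalid samples.
#' @export
window_mean_power <- function(env, end_time, n_windows = 4, width = 0.100) {
  stopifnot(inherits(env, "si_envelope"))
  if (!n_windows %in% c(1L, 2L, 3L, 4L)) .stopf("n_windows must be in 1..4")
  fs <- env$sampling_rate
  nch <- nrow(env$power)
  out <- matrix(NA_real_, nch, n_windows)
  i_end <- .t2i(end_time, fs) - 1L               # last sample strictly before end_time
  i_start <- .t2i(end_time - width * n_windows, fs)
  if (i_start < 1 || i_end > ncol(env$power)) return(out)
  if (!all(env$valid[i_start:i_end])) return(out)
  wlen <- as.integer(round(width * fs))
  for (j in seq_len(n_windows)) {
    a <- i_start + (j - 1L) * wlen
    idx <- a:(a + wlen - 1L)
    out[, j] <- rowMeans(env$power[, idx, drop = FALSE])
  }
  out
}

# End time of the contrast-class window span for each trial. Silence windows
# start at voice_offset + silence anchor (1.5 s visual / 0.5 s auditory) and
# run forward; the instructed-delay window ends 1 s after the stimulus left
# the screen (the 0.9-1 s mid-delay probe). Neither is ever offset.
.contrast_end_times <- function(events, contrast, n_windows, width = 0.1) {
  if (contrast == "silence") {
    anchor <- attr(events, "silence_anchor_s")
    if (is.null(anchor)) anchor <- 1.5
    events$voice_offset_s + anchor + n_windows * width
  } else if (contrast == "delay") {
    if (!isTRUE(attr(events, "has_stimulus_onset")) &&
        !"stimulus_offset_s" %in% names(events))
      .stopf("delay contrast needs stimulus timing")
    delay_dur <- events$go_cue_s - events$stimulus_offset_s
    if (any(is.na(delay_dur)) || min(delay_dur) < 1.0)
      .stopf("delay contrast needs an instructed delay of at least 1 s (task has %.2f s)",
             suppressWarnings(min(delay_dur, na.rm = TRUE)))
    events$stimulus_offset_s + 1.0
  } else .stopf("unknown contrast class '%s'", contrast)
}

#' Build a class-labelled, balanced feature set at one offset
#'
#' Speech-intent features are `n_windows` consecutive 100 ms mean-power
#' windows per good channel ending at `voice_onset + offset`; contrast
#' features (silence or instructed-delay) are anchored to fixed,
#' never-offset times. Trials whose span touches invalid samples are
#' dropped; classes are then balanced by seeded subsampling of the majority
#' class without replacement. Features are concatenated across good channels
#' in recorded channel order.
#'
#' @param env An `si_envelope` (delay-corrected band power).
#' @param events An `si_events` table.
#' @param contrast `"silence"` or `"delay"`.
#' @param offset Seconds added to the end of the speech-intent span relative
#'   to voice onset (negative = strictly causal features).
#' @param n_windows 1 or 4 windows of 100 ms.
#' @param band Label stored with the set (`"high_gamma"`, `"alpha"`, `"beta"`).
#' @param task_filter Optional task label; other trials are dropped.
#' @param seed Integer seed for the balancing subsample.
#' @return An `si_features` object: `x` (rows = trials, columns =
#'   electrode x window means), `y` (factor `speech_intent` vs the contrast),
#'   `trial_id` per row, plus the build parameters.
#' @export
build_feature_set <- function(env, events, contrast = "silence", offset = 0,
                              n_windows = 4, band = "high_gamma",
                              task_filter = NULL, seed = 1) {
  stopifnot(inherits(env, "si_envelope"))
  contrast <- match.arg(contrast, c("silence", "delay"))
  if (!is.null(task_filter)) {
    keep <- events$task == task_filter
    if (!any(keep)) .stopf("no trials with task '%s'", task_filter)
    events <- trial_events(as.data.frame(events)[keep, , drop = FALSE])
  }
  good <- env$channels$good
  ch_names <- env$channels$name[good]
  speech_end <- events$voice_onset_s + offset
  contrast_end <- .contrast_end_times(events, contrast, n_windows)

  grab <- function(ends) {
    rows <- lapply(ends, function(e) {
      m <- window_mean_power(env, e, n_windows)
      as.vector(t(m[good, , drop = FALSE]))  # electrode-major: ch1 w1..wn, ch2 w1..wn
    })
    ok <- !vapply(rows, anyNA, logical(1)) & !is.na(ends)
    list(x = do.call(rbind, rows[ok]), ok = ok)
  }
  sp <- grab(speech_end)
  co <- grab(contrast_end)
  if (is.null(sp$x) || nrow(sp$x) == 0) .stopf("speech_intent class is empty after exclusions")
  if (is.null(co$x) || nrow(co$x) == 0) .stopf("%s class is empty after exclusions", contrast)

  sp_id <- events$trial_id[sp$ok]
  co_id <- events$trial_id[co$ok]
  n <- min(nrow(sp$x), nrow(co$x))
  set.seed(.sub_seed(seed, 3))
  take_sp <- sort(sample(nrow(sp$x), n))
  take_co <- sort(sample(nrow(co$x), n))
  x <- rbind(sp$x[take_sp, , drop = FALSE], co$x[take_co, , drop = FALSE])
  colnames(x) <- as.vector(t(outer(ch_names, seq_len(n_windows), paste, sep = "_w")))
  structure(list(
    x = x,
    y = factor(rep(c("speech_intent", contrast), each = n),
               levels = c("speech_intent", contrast)),
    trial_id = c(sp_id[take_sp], co_id[take_co]),
    offset = offset, n_windows = n_windows, band = band, contrast = contrast,
    channel_names = ch_names, seed = seed
  ), class = "si_features")
}

#' Export a feature set for audit
#'
#' @param fs An `si_features` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(fs, path) {
  df <- data.frame(trial_id = fs$trial_id, label = as.character(fs$y),
                   offset_s = fs$offset, band = fs$band,
                   fs$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
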
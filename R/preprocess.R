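#' Zero-phase notch filtering of line-noise harmonics
#'
#' Applies a 2nd-order IIR notch (quality factor `Q`) forward and backward
#' (`signal::filtfilt`) at each harmonic, so no phase delay is introduced.
#'
#' @param rec An `si_recording`.
#' @param harmonics Hz vector of notch frequencies; each must be below Nyquist.
#' @param Q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return The notch-filtered recording, same length.
#' @export
notch_line_noise <- function(rec, harmonics = c(60, 120, 180), Q = 30) {
  stopifnot(inherits(rec, "si_recording"))
  fs <- rec$sampling_rate
  bad <- harmonics[harmonics >= fs / 2]
  if (length(bad)) .stopf("notch harmonic %g Hz is at or above Nyquist (%g Hz)", bad[1], fs / 2)
  for (f0 in harmonics) {
    # RBJ-cookbook biquad notch
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * Q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    b <- b / a[1]; a <- a / a[1]
    for (i in seq_len(nrow(rec$samples)))
      rec$samples[i, ] <- signal::filtfilt(b, a, rec$samples[i, ])
  }
  rec
}

#' Common average referencing
#'
#' Subtracts, per sample, the mean across *good* channels from every channel
#' (bad channels are excluded from the mean but still referenced).
#'
#' @param rec An `si_recording` with at least two good channels.
#' @return The referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "si_recording"))
  good <- rec$channels$good
  if (sum(good) < 2) .stopf("common average reference needs at least 2 good channels")
  car <- colMeans(rec$samples[good, , drop = FALSE])
  rec$samples <- sweep(rec$samples, 2, car)
  rec
}

#' Design the causal linear-phase band-pass filter
#'
#' Tap count follows \eqn{N \approx 4 f_s / \Delta f} (rounded to the nearest
#' integer), giving a constant group delay \eqn{\tau = (N-1)/(2 f_s)}:
#' 199, 199.5 and 199.75 ms at 500, 1000 and 2000 Hz with the default 10 Hz
#' transition bandwidth. Coefficients are a Hamming-windowed sinc band-pass
#' (`signal::fir1`).
#'
#' @param f_s Sampling rate, Hz.
#' @param band Hz pair (low, high); the upper edge must be below Nyquist.
#' @param delta_f Transition bandwidth, Hz (default 10).
#' @return An `si_filterspec` list: `band`, `transition_bandwidth`, `n_taps`,
#'   `group_delay` (seconds), `sampling_rate`, `coef`.
#' @export
design_band_filter <- function(f_s, band = c(70, 200), delta_f = 10) {
  if (!(band[1] > 0 && band[2] > band[1])) .stopf("band must be an increasing positive Hz pair")
  if (band[2] >= f_s / 2) .stopf("band edge %g Hz is at or above Nyquist (%g Hz)", band[2], f_s / 2)
  n_taps <- round(4 * f_s / delta_f)
  tau <- (n_taps - 1) / (2 * f_s)
  coef <- as.numeric(signal::fir1(n_taps - 1, band / (f_s / 2), type = "pass"))
  structure(list(band = band, transition_bandwidth = delta_f, n_taps = n_taps,
                 group_delay = tau, sampling_rate = f_s, coef = coef),
            class = "si_filterspec")
}

#' Delay-corrected band-power envelope
#'
#' Causal (one-way) FIR band-pass filtering, analytic amplitude via the
#' Hilbert transform over the full record, squared to instantaneous power,
#' then shifted backward in time by the filter's group delay \eqn{\tau} so
#' envelope features align with their physiological time. Samples inside the
#' startup transient and the trailing \eqn{\tau} are marked invalid; the
#' invalid mask propagates to epoching and feature extraction.
#'
#' @param rec An `si_recording`.
#' @param spec An `si_filterspec` designed at the recording's sampling rate.
#' @param correct_delay Set `FALSE` to keep the raw (lagged) envelope; the
#'   result is then flagged `delay_corrected = FALSE`.
#' @return An `si_envelope`: `power` (channels x time, squared amplitude),
#'   `band`, `sampling_rate`, `delay_corrected`, `group_delay`, and a logical
#'   `valid` time mask.
#' @export
band_power <- function(rec, spec, correct_delay = TRUE) {
  stopifnot(inherits(rec, "si_recording"), inherits(spec, "si_filterspec"))
  if (spec$sampling_rate != rec$sampling_rate)
    .stopf("filter designed at %g Hz but recording is %g Hz",
           spec$sampling_rate, rec$sampling_rate)
  n <- ncol(rec$samples)
  if (n < 3 * spec$n_taps)
    .stopf("record too short (%d samples) for a %d-tap filter transient", n, spec$n_taps)
  fs <- rec$sampling_rate
  shift <- if (correct_delay) as.integer(round(spec$group_delay * fs)) else 0L
  pw <- matrix(0, nrow(rec$samples), n)
  for (i in seq_len(nrow(rec$samples))) {
    y <- as.numeric(signal::filter(spec$coef, 1, rec$samples[i, ]))
    p <- Mod(.analytic(y))^2
    if (shift > 0) p <- c(p[(shift + 1):n], rep(NA_real_, shift))
    pw[i, ] <- p
  }
  valid <- rep(TRUE, n)
  lead <- max(spec$n_taps - 1 - shift, 0)      # startup transient after shifting
  if (lead > 0) valid[seq_len(lead)] <- FALSE
  if (shift > 0) valid[(n - shift + 1):n] <- FALSE
  pw[, !valid] <- NA_real_
  structure(list(power = pw, band = spec$band, sampling_rate = fs,
                 delay_corrected = correct_delay, group_delay = spec$group_delay,
                 valid = valid, channels = rec$channels),
            class = "si_envelope")
}

#' Short-time Fourier log power
#'
#' Per-channel spectrogram with a Hamming window (default 512 ms) evaluated
#' on a regular step grid (default 50 ms), returned as log10 power.
#'
#' @param rec An `si_recording`.
#' @param window Window length in seconds.
#' @param step Hop size in seconds; must not exceed `window`.
#' @return A list: `power` (channels x frequencies x times, log10 units),
#'   `freq` (Hz), `time` (seconds, window centres).
#' @export
stft_power <- function(rec, window = 0.512, step = 0.050) {
  stopifnot(inherits(rec, "si_recording"))
  fs <- rec$sampling_rate
  if (step > window) .stopf("step (%g s) must not exceed window (%g s)", step, window)
  nwin <- round(window * fs)
  if (nwin >= ncol(rec$samples)) .stopf("window longer than the recording")
  hop <- max(1L, as.integer(round(step * fs)))
  ov <- nwin - hop
  first <- NULL
  out <- NULL
  for (i in seq_len(nrow(rec$samples))) {
    sg <- signal::specgram(rec$samples[i, ], n = nwin, Fs = fs, overlap = ov)
    lp <- log10(Mod(sg$S)^2 + .Machine$double.xmin)
    if (is.null(out)) {
      first <- sg
      out <- array(0, c(nrow(rec$samples), nrow(lp), ncol(lp)))
    }
    out[i, , ] <- lp
  }
  list(power = out, freq = as.numeric(first$f),
       time = as.numeric(first$t) + window / 2)
}

#' Epoch an envelope (or recording) around behavioural events
#'
#' Cuts trials x channels x time windows around the chosen alignment event.
#' Trials whose window leaves the record or touches invalid (masked) samples
#' are dropped and reported via the `dropped` attribute. With `z_score = TRUE`
#' each channel is normalised by its mean/SD pooled over the epoch window
#' across all retained trials (an SD of zero yields zeros with a warning).
#'
#' @param env An `si_envelope` or `si_recording`.
#' @param events An `si_events` table.
#' @param align `"voice_onset"`, `"go_cue"`, `"stimulus_onset"` or
#'   `"stimulus_offset"`.
#' @param window Seconds pair relative to the event; both ends inclusive, so
#'   the epoch holds `round(diff(window) * fs) + 1` samples.
#' @param z_score Logical.
#' @return An `si_epochs` object: `data` (trials x channels x time), `time`
#'   (seconds relative to the event), `alignment_event`, `window`,
#'   `sampling_rate`, `z_scored`, `trial_id`.
#' @export
epoch <- function(env, events, align = "voice_onset", window = c(-1, 0.5),
                  z_score = FALSE) {
  align <- match.arg(align, c("voice_onset", "voice_offset", "go_cue",
                              "stimulus_onset", "stimulus_offset"))
  if (inherits(env, "si_recording")) {
    pw <- env$samples; valid <- rep(TRUE, ncol(pw)); fs <- env$sampling_rate
  } else {
    pw <- env$power; valid <- env$valid; fs <- env$sampling_rate
  }
  col <- paste0(align, "_s")
  if (!col %in% names(events)) .stopf("events table has no column %s", col)
  t0 <- events[[col]]
  ns <- as.integer(round(diff(window) * fs)) + 1L
  rel <- as.integer(round(window[1] * fs)) + 0:(ns - 1L)
  keep <- logical(length(t0))
  idx_list <- vector("list", length(t0))
  for (k in seq_along(t0)) {
    if (is.na(t0[k])) next
    idx <- .t2i(t0[k], fs) + rel
    if (idx[1] < 1 || idx[ns] > ncol(pw)) next
    if (!all(valid[idx])) next
    keep[k] <- TRUE
    idx_list[[k]] <- idx
  }
  if (!any(keep)) .stopf("no trial survives bounds/validity filtering for %s epochs", align)
  nt <- sum(keep)
  dat <- array(0, c(nt, nrow(pw), ns))
  j <- 0
  for (k in which(keep)) {
    j <- j + 1
    dat[j, , ] <- pw[, idx_list[[k]], drop = FALSE]
  }
  if (z_score) {
    for (c_i in seq_len(nrow(pw))) {
      v <- dat[, c_i, ]
      s <- stats::sd(v)
      if (s == 0 || is.na(s)) {
        warning("channel ", c_i, " has zero variance in the epoch window; z-scores set to 0")
        dat[, c_i, ] <- 0
      } else {
        dat[, c_i, ] <- (v - mean(v)) / s
      }
    }
  }
  structure(list(
    data = dat, time = window[1] + (0:(ns - 1)) / fs, alignment_event = align,
    window = window, sampling_rate = fs, z_scored = z_score,
    trial_id = events$trial_id[keep],
    channels = if (inherits(env, "si_recording")) env$channels else env$channels
  ), class = "si_epochs", dropped = events$trial_id[!keep])
}
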
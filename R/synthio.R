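#' Configuration for the synthetic intracranial recording generator
#'
#' Describes a simulated delayed-speech session: trial timing, channel roles,
#' noise structure and the planted high-gamma (HG) intent modulation. The
#' generator plants, per trial, a smooth HG amplitude modulation that begins
#' `production_lead` seconds *before* voice onset on production channels and
#' `perception_lag` seconds *after* it on perception channels, on top of 1/f
#' background noise, 60/120/180 Hz line noise and a shared common-mode
#' component. Silent channels carry everything except the modulation.
#'
#' @param n_channels Number of channels.
#' @param sampling_rate Hz; one of 500, 1000, 2000.
#' @param n_trials Number of trials.
#' @param task One of `"visual_delay"`, `"visual_nodelay"`,
#'   `"auditory_repetition"`, `"picture_naming"`, `"auditory_naming"`.
#' @param channel_roles Character vector of per-channel roles
#'   (`production`, `perception`, `silent`, `common_mode_only`); recycled
#'   default cycles production/perception/silent.
#' @param production_lead Seconds before voice onset at which HG modulation
#'   begins on production channels (default 0.3).
#' @param perception_lag Seconds after voice onset at which it begins on
#'   perception channels (default 0.1).
#' @param hg_band Hz pair of the modulated band (default 70-200).
#' @param modulation_snr Ratio of planted HG plateau amplitude to the
#'   background's HG-band RMS amplitude. 0 plants nothing.
#' @param line_noise_amp Line-noise sinusoid amplitude relative to the unit-RMS
#'   background (per harmonic).
#' @param common_mode_amp Amplitude of the shared common-mode noise trace.
#' @param timing Named list of interval durations in seconds:
#'   `stimulus`, `delay`, `reaction` (length-2 uniform range go-cue to voice),
#'   `word`, `iti`, `lead_in`. Defaults: 1.5, 1.5, c(0.3, 0.8), 0.6,
#'   2.5 (visual) / 1.2 (auditory), 2.
#' @param ramp Rise/fall time (s) of the raised-cosine modulation envelope.
#' @param seed Integer seed; one seed fans out deterministically into
#'   per-channel and per-trial substreams.
#'
#' @return A validated list of class `si_simconfig`.
#' @export
sim_config <- function(n_channels = 8, sampling_rate = 500, n_trials = 40,
                       task = "visual_delay", channel_roles = NULL,
                       production_lead = 0.300, perception_lag = 0.100,
                       hg_band = c(70, 200), modulation_snr = 1,
                       line_noise_amp = 0.5, common_mode_amp = 1,
                       timing = list(), ramp = 0.1, seed = 1) {
  task <- match.arg(task, c("visual_delay", "visual_nodelay", "auditory_repetition",
                            "picture_naming", "auditory_naming"))
  auditory <- grepl("^auditory", task)
  def <- list(stimulus = 1.5, delay = if (task == "visual_nodelay") 0 else 1.5,
              reaction = c(0.3, 0.8), word = 0.6,
              iti = if (auditory) 1.2 else 2.5, lead_in = 2)
  timing <- utils::modifyList(def, timing)
  if (!sampling_rate %in% c(500, 1000, 2000))
    .stopf("sampling_rate must be one of 500, 1000, 2000 Hz")
  if (!(production_lead > 0)) .stopf("production_lead must be > 0")
  if (!.is_count(n_channels) || !.is_count(n_trials)) .stopf("counts must be positive integers")
  durs <- c(stimulus = timing$stimulus, word = timing$word,
            iti = timing$iti, lead_in = timing$lead_in)
  if (any(durs <= 0)) .stopf("interval duration must be > 0: %s",
                             paste(names(durs)[durs <= 0], collapse = ", "))
  if (timing$delay < 0) .stopf("delay duration must be >= 0")
  if (length(timing$reaction) != 2 || any(timing$reaction <= 0) || diff(timing$reaction) < 0)
    .stopf("timing$reaction must be an increasing pair of positive seconds")
  # Silence feature windows start `anchor` after voice offset and may extend
  # 0.4 s; they must end before the next trial's stimulus onset.
  anchor <- if (auditory) 0.5 else 1.5
  if (anchor + 0.4 > timing$iti)
    .stopf(paste0("inter-trial interval (%.2f s) too short: silence windows need ",
                  "silence_anchor (%.1f) + 0.4 s of features before the next stimulus"),
           timing$iti, anchor)
  if (is.null(channel_roles))
    channel_roles <- rep_len(c("production", "perception", "silent"), n_channels)
  if (length(channel_roles) != n_channels) .stopf("channel_roles must have length n_channels")
  bad <- setdiff(channel_roles, c("production", "perception", "silent", "common_mode_only"))
  if (length(bad)) .stopf("unknown channel role(s): %s", paste(bad, collapse = ", "))
  if (hg_band[2] >= sampling_rate / 2) .stopf("hg_band upper edge must be below Nyquist")
  structure(list(
    n_channels = n_channels, sampling_rate = sampling_rate, n_trials = n_trials,
    task = task, channel_roles = channel_roles, production_lead = production_lead,
    perception_lag = perception_lag, hg_band = hg_band, modulation_snr = modulation_snr,
    line_noise_amp = line_noise_amp, common_mode_amp = common_mode_amp,
    timing = timing, ramp = ramp, seed = as.integer(seed)
  ), class = "si_simconfig")
}

# Raised-cosine ramp 0 -> 1 over `ramp` seconds starting at t0, plateau until
# t1, then back down; evaluated on sample grid indices i1:i2 (vectorised).
.mod_envelope <- function(n, fs, starts, stops, ramp) {
  env <- numeric(n)
  for (k in seq_along(starts)) {
    t0 <- starts[k]; t1 <- stops[k]
    i <- .t2i(t0, fs):min(.t2i(t1 + ramp, fs), n)
    t <- (i - 1) / fs
    up <- pmin(pmax((t - t0) / ramp, 0), 1)
    dn <- pmin(pmax((t1 + ramp - t) / ramp, 0), 1)
    seg <- (1 - cos(pi * up)) / 2 * (1 - cos(pi * dn)) / 2
    env[i] <- pmax(env[i], seg)
  }
  env
}

#' Generate a synthetic recording, events table and ground truth
#'
#' Deterministic given `config$seed`. Each channel is the sum of unit-RMS 1/f
#' (pink) background noise, line-noise sinusoids at 60/120/180 Hz, a shared
#' common-mode pink-noise trace, and (for production/perception roles) a
#' band-limited HG carrier multiplied by a raised-cosine envelope that rises
#' at `voice_onset - production_lead` (production) or
#' `voice_onset + perception_lag` (perception) and is sustained through the
#' word. The planted plateau amplitude is `modulation_snr` times the
#' background's RMS amplitude inside `hg_band`.
#'
#' @param config An [sim_config()] object.
#' @return A list with elements `recording` (an `si_recording`), `events`
#'   (an `si_events` table) and `truth` (channel roles, per-trial voice
#'   onsets, and the per-channel-per-trial modulation start times).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "si_simconfig"))
  fs <- config$sampling_rate
  tm <- config$timing

  set.seed(.sub_seed(config$seed, 1))
  rt <- stats::runif(config$n_trials, tm$reaction[1], tm$reaction[2])
  stim_on <- numeric(config$n_trials)
  t <- tm$lead_in
  trial_len <- tm$stimulus + tm$delay + tm$word + tm$iti
  for (k in seq_len(config$n_trials)) {
    stim_on[k] <- t
    t <- t + trial_len + rt[k]
  }
  stim_off <- stim_on + tm$stimulus
  go <- stim_off + tm$delay
  vo <- go + rt
  voff <- vo + tm$word
  events <- trial_events(data.frame(
    trial_id = seq_len(config$n_trials), task = config$task,
    stimulus_onset_s = stim_on, stimulus_offset_s = stim_off,
    go_cue_s = go, voice_onset_s = vo, voice_offset_s = voff,
    stringsAsFactors = FALSE
  ))

  # Round the record length up to a 2-3-5-smooth sample count (a slightly
  # longer final inter-trial interval) so frequency-domain synthesis and the
  # downstream Hilbert transform use fast FFT lengths.
  n <- stats::nextn(ceiling((voff[config$n_trials] + tm$iti) * fs), c(2, 3, 5))
  pink <- function(f) 1 / sqrt(f)
  bandshape <- function(f) as.numeric(f >= config$hg_band[1] & f <= config$hg_band[2])
  # Fraction of unit-RMS pink-noise power inside hg_band, from the synthesis grid.
  f_grid <- (1:(n %/% 2)) * fs / n
  p_all <- sum(pink(f_grid)^2)
  p_band <- sum(pink(f_grid)[f_grid >= config$hg_band[1] & f_grid <= config$hg_band[2]]^2)
  bg_band_rms <- sqrt(p_band / p_all)
  mod_amp <- config$modulation_snr * bg_band_rms

  set.seed(.sub_seed(config$seed, 2))
  cm <- .spectral_noise(n, fs, pink) * config$common_mode_amp

  tvec <- (seq_len(n) - 1) / fs
  samples <- matrix(0, config$n_channels, n)
  mstart <- matrix(NA_real_, config$n_channels, config$n_trials)
  for (c_i in seq_len(config$n_channels)) {
    role <- config$channel_roles[c_i]
    set.seed(.sub_seed(config$seed, 100 + c_i))
    x <- cm
    if (role != "common_mode_only") x <- x + .spectral_noise(n, fs, pink)
    if (config$line_noise_amp > 0) {
      for (h in c(60, 120, 180)) {
        if (h < fs / 2) x <- x + config$line_noise_amp *
            sin(2 * pi * h * tvec + stats::runif(1, 0, 2 * pi))
      }
    }
    if (role %in% c("production", "perception") && config$modulation_snr > 0) {
      starts <- if (role == "production") vo - config$production_lead
                else vo + config$perception_lag
      mstart[c_i, ] <- starts
      carrier <- .spectral_noise(n, fs, bandshape)
      x <- x + mod_amp * carrier * .mod_envelope(n, fs, starts, voff, config$ramp)
    } else if (role %in% c("production", "perception")) {
      # modulation_snr == 0: role recorded but nothing planted
      mstart[c_i, ] <- if (role == "production") vo - config$production_lead
                       else vo + config$perception_lag
    }
    samples[c_i, ] <- x
  }

  rec <- recording(samples, fs, data.frame(
    name = sprintf("ch%02d", seq_len(config$n_channels)),
    label = paste0("synthetic-", config$channel_roles),
    good = rep(TRUE, config$n_channels), stringsAsFactors = FALSE
  ))
  truth <- list(
    channel_roles = config$channel_roles,
    voice_onset_s = vo,
    modulation_start_s = mstart
  )
  list(recording = rec, events = events, truth = truth)
}

#' Write a small canonical fixture suite
#'
#' Emits three deterministic fixtures used throughout the test suite — a
#' high-SNR signal recording, a zero-SNR null recording, and an
#' auditory-task recording with the short 0.5 s silence anchor — each as a
#' binary+JSON signal container plus an events TSV, together with a manifest
#' of the seeds and channel roles needed to regenerate them bit-identically.
#'
#' @param out_dir Writable directory.
#' @param n_trials Trials per fixture (kept small by default).
#' @return The manifest (a list), invisibly written to `manifest.json`.
#' @export
write_fixture_suite <- function(out_dir, n_trials = 20) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  specs <- list(
    signal = list(task = "visual_delay", snr = 4, seed = 101L),
    null = list(task = "visual_delay", snr = 0, seed = 102L),
    auditory = list(task = "auditory_repetition", snr = 4, seed = 103L)
  )
  roles <- c("production", "production", "production", "perception",
             "perception", "silent", "silent", "silent")
  manifest <- list(fixtures = list())
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    cfg <- sim_config(n_channels = 8, sampling_rate = 500, n_trials = n_trials,
                      task = sp$task, channel_roles = roles,
                      modulation_snr = sp$snr, seed = sp$seed)
    sim <- generate_recording(cfg)
    sig <- file.path(out_dir, paste0(nm, ".f64"))
    ev <- file.path(out_dir, paste0(nm, "_events.tsv"))
    write_signals(sim$recording, sig, roles = roles)
    write_events(sim$events, ev)
    manifest$fixtures[[nm]] <- list(
      signals = basename(sig), events = basename(ev), seed = sp$seed,
      task = sp$task, modulation_snr = sp$snr, n_trials = n_trials,
      sampling_rate_hz = 500, channel_roles = roles
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
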
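# Shared fixtures, built lazily once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

# Canonical high-SNR delayed-reading fixture: 8 channels (2 production,
# 2 perception, 4 silent), 40 trials at 500 Hz, with the full preprocessing
# chain (notch -> CAR -> delay-corrected 70-200 Hz envelope) applied.
fx_signal <- function() {
  if (is.null(.fx_cache$signal)) {
    cfg <- sim_config(
      n_channels = 8, sampling_rate = 500, n_trials = 40,
      channel_roles = rep(c("production", "perception", "silent", "silent"), 2),
      modulation_snr = 4, seed = 11
    )
    sim <- generate_recording(cfg)
    rec <- common_average_reference(notch_line_noise(sim$recording))
    env <- band_power(rec, design_band_filter(500, c(70, 200), 10))
    .fx_cache$signal <- list(cfg = cfg, sim = sim, env = env,
                             events = sim$events, truth = sim$truth)
  }
  .fx_cache$signal
}

# Variant without common-mode noise, preprocessed without CAR: referencing
# an 8-channel montage would feed 1/8 of the planted production modulation
# back into every other channel, which is exactly the crosstalk the
# role-recovery tests must not inherit from the fixture.
fx_clean <- function() {
  if (is.null(.fx_cache$clean)) {
    cfg <- sim_config(
      n_channels = 8, sampling_rate = 500, n_trials = 40,
      channel_roles = rep(c("production", "perception", "silent", "silent"), 2),
      modulation_snr = 4, common_mode_amp = 0, seed = 11
    )
    sim <- generate_recording(cfg)
    env <- band_power(notch_line_noise(sim$recording),
                      design_band_filter(500, c(70, 200), 10))
    .fx_cache$clean <- list(cfg = cfg, sim = sim, env = env,
                            events = sim$events, truth = sim$truth)
  }
  .fx_cache$clean
}

# 100 Hz carrier with slow sinusoidal amplitude modulation: the analytic
# ground-truth envelope is known in closed form, so delay correction can be
# checked to the sample.
fx_am_recording <- function(f_mod = 2, dur = 20, fs = 500) {
  t <- (0:(dur * fs - 1)) / fs
  am <- 1 + 0.8 * sin(2 * pi * f_mod * t)
  x <- am * sin(2 * pi * 100 * t)
  list(rec = recording(matrix(x, 1), fs), t = t, am = am)
}

# Two well-separated Gaussian blobs for decoder unit tests.
fx_blobs <- function(n_per_class = 20, d = 4, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * d), ncol = d),
             matrix(stats::rnorm(n_per_class * d, mean = sep), ncol = d))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per_class)))
}

# A hand-made constant-valid envelope for feature-window arithmetic tests.
fx_flat_envelope <- function(values, fs = 500, n = 10000, nch = length(values)) {
  pw <- matrix(rep(values, n), nrow = nch)
  structure(list(
    power = pw, band = c(70, 200), sampling_rate = fs, delay_corrected = TRUE,
    group_delay = 0.199, valid = rep(TRUE, n),
    channels = data.frame(name = sprintf("ch%02d", seq_len(nch)),
                          label = "synthetic", good = TRUE, stringsAsFactors = FALSE)
  ), class = "si_envelope")
}

# Minimal valid events table (visual delayed-reading timing).
fx_events <- function(n_trials = 6, t0 = 2, task = "visual_delay",
                      rt = 0.5, iti = 2.5) {
  stim_on <- t0 + (0:(n_trials - 1)) * (1.5 + 1.5 + rt + 0.6 + iti)
  trial_events(data.frame(
    trial_id = seq_len(n_trials), task = task,
    stimulus_onset_s = stim_on, stimulus_offset_s = stim_on + 1.5,
    go_cue_s = stim_on + 3.0, voice_onset_s = stim_on + 3.0 + rt,
    voice_offset_s = stim_on + 3.6 + rt, stringsAsFactors = FALSE
  ))
}
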
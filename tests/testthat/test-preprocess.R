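test_that("FIR tap count and group delay follow the design rule", {
  # doubling the transition bandwidth halves the taps and (nearly) the delay
  a <- design_band_filter(500, c(70, 200), 10)
  b <- design_band_filter(500, c(70, 200), 20)
  expect_equal(b$n_taps, a$n_taps / 2)
  expect_equal(b$group_delay, (a$n_taps / 2 - 1) / 1000)
  expect_length(a$coef, a$n_taps)
  expect_error(design_band_filter(500, c(70, 260)), "Nyquist")
})

test_that("zero-phase notch removes the line while sparing neighbours and DC", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  mid <- 500:4500  # steady-state region, away from filter edges

  s60 <- recording(matrix(sin(2 * pi * 60 * t), 1), fs)
  out <- notch_line_noise(s60)$samples[1, ]
  atten_db <- 20 * log10(sqrt(mean(out[mid]^2)) / sqrt(mean(s60$samples[1, mid]^2)))
  expect_lt(atten_db, -30)

  dc <- recording(matrix(rep(2, 10 * fs), 1), fs)
  expect_equal(notch_line_noise(dc)$samples[1, mid], rep(2, length(mid)), tolerance = 1e-4)

  s100 <- recording(matrix(sin(2 * pi * 100 * t), 1), fs)
  out100 <- notch_line_noise(s100)$samples[1, ]
  # amplitude of the fitted 100 Hz sinusoid must be preserved within 1%
  fit <- stats::lm(out100[mid] ~ sin(2 * pi * 100 * t[mid]) + cos(2 * pi * 100 * t[mid]) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  expect_equal(amp, 1, tolerance = 0.01)

  expect_error(notch_line_noise(recording(matrix(t, 1), 300)), "180")
})

test_that("common average referencing matches hand arithmetic and rejects common mode", {
  rec <- recording(rbind(c(1, 1, 1), c(3, 3, 3)), 500)
  out <- common_average_reference(rec)
  expect_equal(out$samples, rbind(c(-1, -1, -1), c(1, 1, 1)))

  set.seed(4)
  x <- matrix(rnorm(3 * 100), 3)
  common <- rnorm(100)
  a <- common_average_reference(recording(x, 500))$samples
  b <- common_average_reference(recording(sweep(x, 2, common, "+"), 500))$samples
  expect_equal(a, b, tolerance = 1e-12)

  # CAR is idempotent once the across-channel mean is zero
  again <- common_average_reference(recording(a, 500))$samples
  expect_equal(again, a, tolerance = 1e-12)

  # bad channel: excluded from the mean, still referenced
  ch <- data.frame(name = c("a", "b", "c"), label = "x",
                   good = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  rec3 <- recording(rbind(c(1, 1), c(3, 3), c(100, 100)), 500, ch)
  out3 <- common_average_reference(rec3)
  expect_equal(out3$samples, rbind(c(-1, -1), c(1, 1), c(98, 98)))
  expect_error(common_average_reference(recording(rbind(c(1, 1), c(3, 3)), 500,
    data.frame(name = c("a", "b"), label = "x", good = c(TRUE, FALSE)))), "good")
})

test_that("delay-corrected envelope aligns with the true modulation to the sample", {
  am <- fx_am_recording()
  spec <- design_band_filter(500, c(90, 110), 10)
  true_env2 <- am$am^2

  corr <- band_power(am$rec, spec, correct_delay = TRUE)
  ok <- which(corr$valid)
  lag <- function(a, b) {
    cc <- stats::ccf(a, b, lag.max = 150, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  expect_lte(abs(lag(corr$power[1, ok], true_env2[ok])), 1)

  raw <- band_power(am$rec, spec, correct_delay = FALSE)
  ok2 <- which(raw$valid)[-(1:300)]  # skip the startup transient
  expect_lte(abs(lag(raw$power[1, ok2], true_env2[ok2]) -
                   round(spec$group_delay * 500)), 1)

  # zero in, zero out; and short records are refused
  z <- band_power(recording(matrix(0, 1, 5000), 500), spec)
  expect_true(all(z$power[1, z$valid] == 0))
  expect_error(band_power(recording(matrix(0, 1, 300), 500), spec), "short")
  expect_error(band_power(recording(matrix(0, 1, 5000), 1000), spec), "1000")
  expect_true(all(corr$power[1, corr$valid] >= 0))
})

test_that("notching line noise leaves the high-gamma envelope essentially unchanged", {
  cfg <- sim_config(n_channels = 2, n_trials = 6, channel_roles = c("production", "silent"),
                    modulation_snr = 2, line_noise_amp = 0.5, seed = 13)
  sim <- generate_recording(cfg)
  spec <- design_band_filter(500, c(70, 200), 10)
  # only the 60 Hz notch: the 120/180 Hz harmonics sit inside the band and
  # their removal is a real (intended) envelope change
  e1 <- band_power(sim$recording, spec)
  e2 <- band_power(notch_line_noise(sim$recording, harmonics = 60), spec)
  ok <- e1$valid & e2$valid
  rel <- sqrt(mean((e1$power[, ok] - e2$power[, ok])^2)) / sqrt(mean(e1$power[, ok]^2))
  expect_lt(rel, 0.01)
})

test_that("spectrogram localises tones and band-limited bursts", {
  fs <- 500
  t <- (0:(8 * fs - 1)) / fs
  tone <- recording(matrix(sin(2 * pi * 60 * t), 1), fs)
  sg <- stft_power(tone)
  prof <- apply(sg$power[1, , ], 1, mean)
  expect_lt(abs(sg$freq[which.max(prof)] - 60), 500 / round(0.512 * fs))

  set.seed(8)
  burst_env <- as.numeric(t > 3 & t < 5)
  x <- rnorm(length(t), sd = 0.1)
  carrier <- sin(2 * pi * 110 * t)
  burst <- recording(matrix(x + 3 * burst_env * carrier, 1), fs)
  sb <- stft_power(burst)
  hg <- sb$freq >= 100 & sb$freq <= 120   # rows containing the planted carrier
  lo <- sb$freq >= 5 & sb$freq <= 40
  during <- sb$time > 3.2 & sb$time < 4.8
  d_hg <- mean(sb$power[1, hg, during]) - mean(sb$power[1, hg, !during])
  d_lo <- mean(sb$power[1, lo, during]) - mean(sb$power[1, lo, !during])
  expect_gt(d_hg, 1)          # an order of magnitude in log10 power
  expect_lt(abs(d_lo), 0.3)   # no burst leakage into low frequencies
  expect_error(stft_power(tone, window = 0.2, step = 0.3), "exceed")
})

test_that("epoching follows the sample-count convention and drops unusable trials", {
  env <- fx_flat_envelope(c(2, 3), n = 20000)
  ev <- fx_events(4)
  ep <- epoch(env, ev, "voice_onset", c(-1, 0.5))
  expect_equal(dim(ep$data), c(4, 2, 751))
  expect_true(all(ep$data[, 1, ] == 2))

  # constant envelope + z-scoring: zeros with a warning, not NaN
  expect_warning(expect_warning(  # one warning per constant channel
    epz <- epoch(env, ev, "voice_onset", c(-1, 0.5), z_score = TRUE),
    "zero variance"), "zero variance")
  expect_true(all(epz$data == 0))

  # a trial whose window leaves the record is dropped and reported
  ev2 <- fx_events(4)
  ev2$voice_onset_s[4] <- 20000 / 500 - 0.1
  ev2$voice_offset_s[4] <- ev2$voice_onset_s[4] + 0.6
  ep2 <- epoch(env, ev2, "voice_onset", c(-1, 0.5))
  expect_equal(dim(ep2$data)[1], 3)
  expect_equal(attr(ep2, "dropped"), 4)
  # invalid (masked) samples poison the touching trial only
  env$valid[1:3000] <- FALSE
  env$power[, 1:3000] <- NA
  ep3 <- epoch(env, ev, "voice_onset", c(-1, 0.5))
  expect_equal(dim(ep3$data)[1], 3)
})
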
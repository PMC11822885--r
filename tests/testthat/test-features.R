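test_that("window means reproduce brute-force block averages", {
  env <- fx_flat_envelope(c(2, 2), n = 5000)
  m <- window_mean_power(env, end_time = 4, n_windows = 4)
  expect_equal(m, matrix(2, 2, 4))

  # ramp envelope: power(t) = t on [0, 0.4); oracle = mean of each 100 ms block
  fs <- 500
  n <- 5000
  ramp <- fx_flat_envelope(0, n = n, nch = 1)
  ramp$power[1, ] <- (0:(n - 1)) / fs
  got <- window_mean_power(ramp, end_time = 0.4, n_windows = 4)
  oracle <- vapply(0:3, function(j) {
    idx <- (j * 50 + 1):(j * 50 + 50)       # samples of [0.1j, 0.1j+0.1)
    mean(ramp$power[1, idx])
  }, numeric(1))
  expect_equal(as.numeric(got), oracle)
  expect_equal(as.numeric(got), c(0.05, 0.15, 0.25, 0.35), tolerance = 0.011)

  one <- window_mean_power(ramp, end_time = 0.4, n_windows = 1)
  expect_equal(as.numeric(one), oracle[4])

  # spans touching invalid samples come back NA
  ramp$valid[1:10] <- FALSE
  expect_true(anyNA(window_mean_power(ramp, end_time = 0.4, n_windows = 4)))
  expect_false(anyNA(window_mean_power(ramp, end_time = 0.5, n_windows = 4)))
})

test_that("class windows anchor where the task dictates and are never offset", {
  # envelope whose power equals elapsed time: a window mean identifies its centre
  fs <- 500; n <- 40000
  env <- fx_flat_envelope(0, n = n, nch = 1)
  env$power[1, ] <- (0:(n - 1)) / fs
  ev_vis <- fx_events(4, task = "visual_delay")
  ev_aud <- fx_events(4, task = "auditory_repetition", iti = 1.2)

  f_vis <- build_feature_set(env, ev_vis, "silence", offset = 0, n_windows = 1, seed = 1)
  f_aud <- build_feature_set(env, ev_aud, "silence", offset = 0, n_windows = 1, seed = 1)
  sil_vis <- f_vis$x[f_vis$y == "silence", 1]
  sil_aud <- f_aud$x[f_aud$y == "silence", 1]
  # single 100 ms window starting at voice_offset + anchor: mean = anchor + 0.05 - dt/2
  expect_equal(sort(sil_vis - ev_vis$voice_offset_s), rep(1.549, 4), tolerance = 1e-3)
  expect_equal(sort(sil_aud - ev_aud$voice_offset_s), rep(0.549, 4), tolerance = 1e-3)

  # speech windows move with the offset; contrast rows stay bit-identical
  f0 <- build_feature_set(env, ev_vis, "silence", offset = 0, seed = 3)
  f1 <- build_feature_set(env, ev_vis, "silence", offset = -0.5, seed = 3)
  expect_identical(f0$x[f0$y == "silence", ], f1$x[f1$y == "silence", ])
  expect_equal(mean(f0$x[f0$y == "speech_intent", ] - f1$x[f1$y == "speech_intent", ]),
               0.5, tolerance = 1e-3)

  # the mid-delay probe ends 1 s after the stimulus left the screen
  fd <- build_feature_set(env, ev_vis, "delay", offset = 0, n_windows = 1, seed = 1)
  del <- fd$x[fd$y == "delay", 1]
  expect_equal(sort(del - ev_vis$stimulus_offset_s), rep(0.949, 4), tolerance = 1e-3)
})

test_that("classes are balanced by seeded subsampling, reproducibly", {
  fs <- 500; n <- 40000
  env <- fx_flat_envelope(c(1, 1), n = n)
  ev <- fx_events(8)
  # mask the pre-voice span of trials 6-8: their speech rows drop, silence stays
  for (k in 6:8) {
    idx <- floor((ev$voice_onset_s[k] - 0.45) * fs):ceiling(ev$voice_onset_s[k] * fs)
    env$valid[idx] <- FALSE
    env$power[, idx] <- NA
  }
  f <- build_feature_set(env, ev, "silence", offset = 0, seed = 9)
  expect_equal(as.numeric(table(f$y)), c(5, 5))
  f2 <- build_feature_set(env, ev, "silence", offset = 0, seed = 9)
  expect_identical(f$trial_id, f2$trial_id)
  f3 <- build_feature_set(env, ev, "silence", offset = 0, seed = 10)
  expect_false(identical(f$trial_id[f$y == "silence"], f3$trial_id[f3$y == "silence"]) &&
               identical(f$trial_id, f3$trial_id))
})

test_that("delay contrast requires an instructed delay and empty classes error by name", {
  env <- fx_flat_envelope(c(1, 1), n = 40000)
  ev_nodelay <- fx_events(4)
  ev_nodelay$go_cue_s <- ev_nodelay$stimulus_offset_s  # no instructed delay
  ev_nodelay$task <- "visual_nodelay"
  ev_nodelay <- trial_events(as.data.frame(ev_nodelay))
  expect_error(build_feature_set(env, ev_nodelay, "delay"), "instructed delay")

  ev <- fx_events(3, t0 = 100)  # all events beyond the record
  expect_error(build_feature_set(env, ev, "silence"), "speech_intent")
})

test_that("speech windows carry more high-gamma power than silence on production channels", {
  fx <- fx_signal()
  f <- build_feature_set(fx$env, fx$events, "silence", offset = 0, seed = 2)
  # channel 1 is a production channel; compare its mean window power by class
  prod_cols <- grep("^ch01_", colnames(f$x))
  sp <- rowMeans(f$x[f$y == "speech_intent", prod_cols])
  si <- rowMeans(f$x[f$y == "silence", prod_cols])
  expect_lt(stats::wilcox.test(sp, si, alternative = "greater")$p.value, 0.01)
  # CSV export keeps one row per trial with provenance
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_set(f, p)
  back <- utils::read.csv(p, check.names = FALSE)
  expect_equal(nrow(back), nrow(f$x))
  expect_true(all(c("trial_id", "label", "offset_s", "band") %in% names(back)))
})
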
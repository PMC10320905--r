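test_that("channel selection restricts and orders, and names missing channels", {
  cfg <- sim_config(n_channels = 80, sampling_rate = 200, trial_duration = 2)
  rec <- generate_recording(cfg, "VOICE", 1)
  sel <- select_channels(rec, motor_channels())
  expect_equal(nrow(sel$data), 18L)
  expect_identical(sel$labels, motor_channels())
  expect_identical(sel$data["C3", ], rec$data["C3", ])

  again <- select_channels(sel, motor_channels())
  expect_identical(again$data, sel$data)

  expect_error(select_channels(rec, c("C3", "XX9")), "XX9")
})

test_that("trimming keeps [6, 51) and epoching yields 45 one-second epochs", {
  for (rate in c(200, 1200)) {
    cfg <- sim_config(n_channels = 2, channel_labels = c("C3", "C4"),
                      sampling_rate = rate, trial_duration = 60)
    rec <- generate_recording(cfg, "VOICE", 1)
    ep <- trim_and_epoch(rec)
    expect_equal(dim(ep$data), c(45L, 2L, rate))
    # epoch 1 must be exactly samples [6*rate, 7*rate) of the input
    expect_identical(ep$data[1, 1, ], unname(rec$data[1, (6 * rate + 1):(7 * rate)]))
    expect_identical(ep$data[45, 2, ], unname(rec$data[2, (50 * rate + 1):(51 * rate)]))
  }
})

test_that("recordings shorter than the trim window are rejected", {
  cfg <- sim_config(n_channels = 1, channel_labels = "C3",
                    sampling_rate = 200, trial_duration = 20)
  rec <- generate_recording(cfg, "VOICE", 1)
  expect_error(trim_recording(rec, 6, 51), "51")
})

test_that("channel selection and epoching commute", {
  cfg <- sim_config(n_channels = 6, sampling_rate = 200, trial_duration = 8)
  rec <- generate_recording(cfg, "VOICE", 1)
  chans <- cfg$channel_labels[c(5, 2)]
  a <- epoch_recording(trim_recording(select_channels(rec, chans), 6, 8))
  b <- trim_and_epoch(rec, 6, 8)
  b_sel <- b$data[, match(chans, b$labels), , drop = FALSE]
  expect_equal(a$data, b_sel)
})

test_that("downsampling 1200 to 200 Hz preserves in-band content", {
  t <- (0:(1200 * 10 - 1)) / 1200
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), "C3", 1200)
  dn <- downsample_recording(rec, 200)
  expect_equal(dn$rate, 200)
  expect_equal(ncol(dn$data), ncol(rec$data) / 6L)
  # steady-state amplitude preserved within 1%
  mid <- 400:1600
  expect_equal(rms(dn$data[1, mid]), sqrt(0.5), tolerance = 0.01)
  # dominant frequency still 10 Hz
  ep <- epoch_recording(eeg_recording(dn$data[, 1:2000, drop = FALSE], "C3", 200))
  avg <- average_periodograms(welch_periodogram(ep))
  expect_equal(avg$freqs[which.max(avg$psd[1, ])], 10, tolerance = 0.3)

  expect_identical(downsample_recording(rec, 1200), rec)
  expect_error(downsample_recording(rec, 500), "divide")
})

test_that("the band-pass filter matches its closed-form magnitude response", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  mid <- (2 * fs):(8 * fs)

  zero <- eeg_recording(matrix(0, 1, length(t)), "C3", fs)
  expect_equal(max(abs(bandpass_filter(zero)$data)), 0)

  # 10 Hz lies in the passband: RMS preserved within 2%
  tone10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), "C3", fs)
  out10 <- bandpass_filter(tone10, 1, 40, 5)
  expect_equal(rms(out10$data[1, mid]) / rms(tone10$data[1, mid]), 1,
               tolerance = 0.02)

  # 50 Hz stopband attenuation equals the analytic magnitude squared
  # (zero-phase application)
  tone50 <- eeg_recording(matrix(sin(2 * pi * 50 * t), 1), "C3", fs)
  out50 <- bandpass_filter(tone50, 1, 40, 5)
  expected <- butter_bandpass_mag(50, fs, 1, 40, 5)^2
  expect_equal(rms(out50$data[1, mid]) / rms(tone50$data[1, mid]), expected,
               tolerance = 0.02 * expected)
  expect_equal(out50$meta$filter$mode, "zero-phase")
  expect_true(all(is.finite(out50$data)))

  expect_error(bandpass_filter(tone10, 0, 40), "band edges")
  expect_error(bandpass_filter(tone10, 1, 120), "band edges")
})

test_that("downsampling plus filtering barely changes in-band band powers", {
  cfg <- sim_config(n_channels = 1, channel_labels = "C3", sampling_rate = 1200,
                    trial_duration = 30, background_rms = 0, line_noise_amp = 0,
                    alpha_spec = osc_spec(10, 4, 2, c(C3 = 1)),
                    beta_spec = osc_spec(21.5, 17, 1, c(C3 = 1)),
                    effect_gains = flat_gains())
  rec <- generate_recording(cfg, "VOICE", 1)
  # reference: native-rate periodogram of the band-limited signal
  ref <- average_periodograms(
    welch_periodogram(trim_and_epoch(rec, 6, 30))
  )
  proc <- preprocess_trial(rec, channels = "C3", trim = c(6, 30))
  got <- average_periodograms(welch_periodogram(proc))
  for (band in list(c(8, 12), c(13, 30))) {
    expect_equal(band_power(got, band), band_power(ref, band),
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})
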
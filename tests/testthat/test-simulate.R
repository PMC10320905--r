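test_that("generation is deterministic and trial-count aware", {
  cfg <- sim_config(n_channels = 4, sampling_rate = 200, trial_duration = 4)
  a <- generate_recording(cfg, "VOICE", 1)
  b <- generate_recording(cfg, "VOICE", 1)
  expect_identical(a$data, b$data)
  c2 <- generate_recording(cfg, "VOICE", 2)
  expect_false(identical(a$data, c2$data))
  expect_error(generate_recording(cfg, "VOICE", 99), "out of range")
  expect_error(generate_recording(cfg, "SLEEP", 1), "unknown task")
})

test_that("a noise-free zero-bandwidth oscillation is a pure sinusoid on its channel", {
  cfg <- sim_config(
    n_channels = 3, channel_labels = c("C3", "C4", "Cz"),
    sampling_rate = 200, trial_duration = 2,
    background_rms = 0, line_noise_amp = 0,
    alpha_spec = osc_spec(10, 0, 2, c(C3 = 1)),
    beta_spec = osc_spec(21.5, 17, 0),
    effect_gains = flat_gains()
  )
  rec <- generate_recording(cfg, "VOICE", 1)
  t <- (seq_len(400) - 1) / 200
  expect_equal(rec$data["C3", ], 2 * sin(2 * pi * 10 * t), tolerance = 1e-12)
  expect_equal(max(abs(rec$data["C4", ])), 0)
  expect_equal(max(abs(rec$data["Cz", ])), 0)
})

test_that("band-limited oscillations peak at their centre frequency", {
  cfg <- tone_config(amplitude = 2, bandwidth = 4, duration = 20)
  avg <- avg_periodogram_of(cfg, trim = c(0, 20))
  pk <- avg$freqs[which.max(avg$psd[1, ])]
  expect_lt(abs(pk - 10), 2)  # within bandwidth/2 of the centre
})

test_that("condition gains scale band power by the square of the gain", {
  bp_for <- function(gain, seed) {
    cfg <- tone_config(gains = flat_gains(VR_MI.alpha = gain), seed = seed)
    mean(band_power(avg_periodogram_of(cfg, task = "VR_MI"), c(8, 12)))
  }
  hi <- vapply(1:60, bp_for, numeric(1), gain = 1.5)
  lo <- vapply(1:60, bp_for, numeric(1), gain = 1.0)
  expect_equal(mean(hi) / mean(lo), 2.25, tolerance = 0.05)
})

test_that("band power increases strictly with the effect gain", {
  mean_bp <- function(gain) {
    mean(vapply(1:25, function(s) {
      cfg <- tone_config(gains = flat_gains(VR_MI.alpha = gain), seed = s,
                         background_rms = 0.5)
      mean(band_power(avg_periodogram_of(cfg, task = "VR_MI"), c(8, 12)))
    }, numeric(1)))
  }
  powers <- vapply(c(1, 1.25, 1.5), mean_bp, numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("channels with zero spatial weight are unaffected by the gains", {
  bp_for <- function(task, seed) {
    cfg <- sim_config(
      n_channels = 2, channel_labels = c("C3", "C4"), sampling_rate = 200,
      trial_duration = 8, background_rms = 1, line_noise_amp = 0,
      alpha_spec = osc_spec(10, 4, 1.3, c(C3 = 1)),  # C4 weight 0
      beta_spec = osc_spec(21.5, 17, 0),
      effect_gains = flat_gains(VR_MI.alpha = 2), seed = seed
    )
    band_power(avg_periodogram_of(cfg, task = task), c(8, 12))
  }
  a <- vapply(1:40, bp_for, numeric(2), task = "VOICE")
  b <- vapply(1:40, bp_for, numeric(2), task = "VR_MI")
  # doubled alpha gain quadruples C3 power but leaves C4 indistinguishable
  expect_gt(mean(b["C3", ]) / mean(a["C3", ]), 2)
  expect_gt(stats::t.test(a["C4", ], b["C4", ])$p.value, 0.001)
})

test_that("artifact injection follows the stated rates and logs every event", {
  cfg <- sim_config(n_channels = 4, sampling_rate = 200, trial_duration = 60)
  rec <- generate_recording(cfg, "VOICE", 1)

  none <- inject_artifacts(rec, artifact_spec(blink_rate = 0, muscle_burst_rate = 0))
  expect_identical(none$recording$data, rec$data)
  expect_equal(nrow(none$log), 0L)

  spec <- artifact_spec(blink_rate = 12, muscle_burst_rate = 0)
  counts <- vapply(1:100, function(s) {
    nrow(inject_artifacts(rec, spec, seed = s)$log)
  }, numeric(1))
  # Poisson with mean 12 per 60-s trial; 100 trials give se ~ 0.35
  expect_equal(mean(counts), 12, tolerance = 0.1)
})

test_that("blink events dominate the background inside their windows", {
  cfg <- tone_config(background_rms = 1, duration = 30)
  rec <- generate_recording(cfg, "VOICE", 1)
  inj <- inject_artifacts(rec, artifact_spec(blink_rate = 10, blink_amplitude = 200,
                                             muscle_burst_rate = 0), seed = 7)
  expect_gt(nrow(inj$log), 0L)
  bg_rms <- rms(rec$data[1, ])
  for (i in seq_len(nrow(inj$log))) {
    i0 <- round(inj$log$onset[i] * rec$rate) + 1
    idx <- i0:(i0 + round(inj$log$duration[i] * rec$rate) - 1)
    expect_gt(max(abs(inj$recording$data[inj$log$channel[i], idx])), 5 * bg_rms)
  }
})
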
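make_epochs <- function(x, rate = 200) {
  eeg_epochs(array(x, dim = c(1, 1, length(x))), rate, "C3")
}

test_that("Welch periodograms integrate to the signal's power", {
  fs <- 200
  n <- 200
  expect_equal(max(welch_periodogram(make_epochs(rep(0, n)))$psd), 0)

  tone <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  p <- welch_periodogram(make_epochs(tone))
  total <- eegmi:::.simpson(p$psd[1, 1, ], p$freqs)
  expect_equal(total, 0.5, tolerance = 0.05)   # A^2/2 for a unit sinusoid
  expect_true(all(p$psd >= 0))
  expect_equal(diff(p$freqs)[1], 0.25)         # 4x zero padding of 1-s epochs

  expect_error(welch_periodogram(make_epochs(tone), segment_length = 999),
               "exceeds")
})

test_that("white noise yields an approximately flat PSD at sigma^2/(rate/2)", {
  cfg <- tone_config(amplitude = 0, background_rms = 2, exponent = 0,
                     duration = 60)
  rec <- generate_recording(cfg, "VOICE", 1)
  avg <- average_periodograms(welch_periodogram(epoch_recording(rec)))
  inner <- avg$psd[1, avg$freqs > 5 & avg$freqs < 95]
  expect_equal(mean(inner), 4 / 100, tolerance = 0.05)
  expect_lt(stats::sd(inner) / mean(inner), 0.5)
})

test_that("periodogram averaging is a pointwise mean with grid checking", {
  x <- sin(2 * pi * 7 * (0:199) / 200)
  p1 <- welch_periodogram(make_epochs(x))
  same <- average_periodograms(list(p1, p1))
  expect_equal(same$psd[1, ], p1$psd[1, 1, ])

  p3 <- p1
  p3$psd <- 3 * p3$psd
  two <- average_periodograms(list(p1, p3))
  expect_equal(two$psd[1, ], 2 * p1$psd[1, 1, ])

  bad <- welch_periodogram(make_epochs(x), zero_pad_factor = 2)
  expect_error(average_periodograms(list(p1, bad)), "grids")
})

test_that("averaging N noise epochs shrinks the PSD variance like 1/N", {
  cfg <- tone_config(amplitude = 0, background_rms = 1, exponent = 0,
                     duration = 50)
  rec <- generate_recording(cfg, "VOICE", 1)
  p <- welch_periodogram(epoch_recording(rec))
  bin <- which.min(abs(p$freqs - 20))
  single_var <- stats::var(p$psd[, 1, bin])
  groups <- matrix(seq_len(50), nrow = 10)  # 5 groups of 10 epochs
  means10 <- apply(groups, 2, function(g) mean(p$psd[g, 1, bin]))
  # variance of a 10-epoch mean should be near single_var/10 (loose MC check)
  expect_lt(stats::var(means10), single_var / 2)
})

test_that("Simpson band powers match analytic and trapezoid oracles", {
  skip_if_not_installed("pracma")
  freqs <- seq(0, 100, by = 0.25)
  flat <- structure(list(freqs = freqs, psd = matrix(2, 1, length(freqs)),
                         labels = "C3", rate = 200, meta = list()),
                    class = "periodogram")
  expect_equal(unname(band_power(flat, c(8, 12))), 2 * 4)      # h * w exactly
  expect_equal(unname(band_power(flat, c(13, 30))), 2 * 17)

  set.seed(5)
  x <- sin(2 * pi * 10 * (0:199) / 200) + rnorm(200, sd = 0.5)
  avg <- average_periodograms(welch_periodogram(make_epochs(x)))
  for (band in list(c(8, 12), c(13, 30), c(1, 40))) {
    idx <- which(avg$freqs >= band[1] & avg$freqs <= band[2])
    trap <- pracma::trapz(avg$freqs[idx], avg$psd[1, idx])
    expect_equal(unname(band_power(avg, band)), trap, tolerance = 0.01)
  }
  # additivity across adjacent bands
  expect_equal(unname(band_power(avg, c(8, 12)) + band_power(avg, c(12, 30))),
               unname(band_power(avg, c(8, 30))), tolerance = 0.01)

  expect_error(band_power(avg, c(90, 120)), "outside")
  # power concentrated at 10 Hz leaves the sub-8 Hz band nearly empty
  pure <- average_periodograms(welch_periodogram(make_epochs(
    sin(2 * pi * 4 * (0:199) / 200))))
  expect_lt(unname(band_power(pure, c(8, 12))), 0.02)
})

test_that("spectral entropy attains its analytic limits exactly", {
  freqs <- seq(1, 40, by = 1)
  n <- length(freqs)
  mk <- function(psd) structure(list(freqs = freqs, psd = matrix(psd, 1),
                                     labels = "C3", rate = 200, meta = list()),
                                class = "periodogram")
  one_bin <- rep(0, n); one_bin[10] <- 5
  expect_equal(as.numeric(spectral_entropy(mk(one_bin))), 0)
  expect_equal(as.numeric(spectral_entropy(mk(rep(3, n)))), log2(n))
  two <- rep(0, n); two[c(3, 30)] <- 7
  expect_equal(as.numeric(spectral_entropy(mk(two))), 1)
  expect_error(spectral_entropy(mk(rep(0, n))), "zero")

  set.seed(9)
  H <- spectral_entropy(mk(runif(n)))
  expect_gte(unname(H), 0)
  expect_lte(unname(H), log2(attr(H, "n_bins")))
})

test_that("adding a narrowband rhythm lowers entropy monotonically", {
  mean_H <- function(amp) {
    mean(vapply(1:30, function(s) {
      cfg <- tone_config(amplitude = amp, background_rms = 1, exponent = 0,
                         seed = s)
      unname(spectral_entropy(avg_periodogram_of(cfg)))
    }, numeric(1)))
  }
  Hs <- vapply(c(0, 1, 3), mean_H, numeric(1))
  expect_true(all(diff(Hs) < 0))
})

test_that("min-max scaling maps onto [-1, 1] with the stated landmarks", {
  expect_equal(minmax_normalise(c(2, 4, 6)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(50)
  y <- minmax_normalise(x)
  expect_equal(max(y), 1)
  expect_equal(min(y), -1)
  expect_equal(sum(y == 1), 1L)
  expect_equal(sum(y == -1), 1L)
  expect_equal(unname(minmax_normalise((max(x) + min(x)) / 2, pool = x)), 0)
  # affine invariance
  expect_equal(minmax_normalise(3 * x + 7), y)
  expect_error(minmax_normalise(rep(1, 5)), "degenerate")
})
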
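# Shared fixtures and independent oracles used across the test files.

# uniform effect-gain matrix with optional per-(task, band) overrides
flat_gains <- function(...) {
  g <- matrix(1, 4, 2,
              dimnames = list(c("VOICE", "MI_VOICE", "VR_MI", "MI_VR"),
                              c("alpha", "beta")))
  ov <- list(...)
  for (nm in names(ov)) {
    parts <- strsplit(nm, "\\.")[[1]]
    g[parts[1], parts[2]] <- ov[[nm]]
  }
  g
}

# a small single-channel configuration for oscillation-level checks
tone_config <- function(amplitude = 1.3, bandwidth = 4, seed = 1,
                        gains = flat_gains(), background_rms = 0,
                        duration = 8, exponent = 1) {
  sim_config(
    n_channels = 1, channel_labels = "C3", sampling_rate = 200,
    trial_duration = duration, background_rms = background_rms,
    background_exponent = exponent, line_noise_amp = 0,
    alpha_spec = osc_spec(10, bandwidth, amplitude, c(C3 = 1)),
    beta_spec = osc_spec(21.5, 17, 0),
    artifact_spec = artifact_spec(blink_rate = 0, muscle_burst_rate = 0),
    effect_gains = gains, seed = seed
  )
}

# epoch-averaged periodogram of one generated trial
avg_periodogram_of <- function(cfg, task = "VOICE", trial = 1,
                               trim = c(6, cfg$trial_duration)) {
  ep <- trim_and_epoch(generate_recording(cfg, task, trial), trim[1], trim[2])
  average_periodograms(welch_periodogram(ep))
}

# Exhaustive-enumeration oracle for the two-sided Wilcoxon signed-rank
# p-value: enumerates all 2^n sign assignments of the ranked absolute
# differences. Valid for small n without ties or zeros.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V <- as.numeric(signs %*% rk)
  p_lo <- mean(V <= W)
  p_hi <- mean(V >= W)
  min(1, 2 * min(p_lo, p_hi))
}

# Closed-form magnitude response at frequency f (Hz) of a digital Butterworth
# band-pass designed by bilinear transform with prewarped edges: the analog
# low-pass prototype magnitude evaluated at the band-pass-mapped frequency.
butter_bandpass_mag <- function(f, fs, low, high, order) {
  warp <- function(g) 2 * fs * tan(pi * g / fs)
  O1 <- warp(low); O2 <- warp(high); O <- warp(f)
  u <- (O^2 - O1 * O2) / (O * (O2 - O1))
  1 / sqrt(1 + u^(2 * order))
}

rms <- function(x) sqrt(mean(x^2))
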
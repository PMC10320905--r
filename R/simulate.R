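#' Oscillation specification
#'
#' Describes one band-limited rhythm: a spectral peak of full width
#' `bandwidth` centred at `center_freq`, generated as white noise shaped by a
#' Gaussian spectral window so that periodograms show realistic peaked-but-
#' broad spectra. `bandwidth = 0` degenerates to a deterministic sinusoid of
#' peak amplitude `base_amplitude`.
#'
#' @param center_freq Centre frequency in Hz.
#' @param bandwidth Full width (FWHM) of the spectral peak in Hz; `>= 0`.
#' @param base_amplitude Peak-equivalent amplitude in microvolts: the
#'   oscillation carries power `base_amplitude^2 / 2`, like a sinusoid of that
#'   peak amplitude.
#' @param spatial_profile Named numeric vector of per-channel weights in
#'   `[0, 1]`, or `NULL` to let [sim_config()] fill in its default (weight 1 on
#'   the motor channels, 0.3 elsewhere).
#' @return An object of class `osc_spec`.
#' @export
osc_spec <- function(center_freq, bandwidth, base_amplitude, spatial_profile = NULL) {
  if (bandwidth < 0) stop("`bandwidth` must be >= 0", call. = FALSE)
  if (base_amplitude < 0) stop("`base_amplitude` must be >= 0", call. = FALSE)
  if (!is.null(spatial_profile)) {
    if (is.null(names(spatial_profile)) ||
        any(spatial_profile < 0 | spatial_profile > 1)) {
      stop("`spatial_profile` must be a named vector of weights in [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 base_amplitude = base_amplitude,
                 spatial_profile = spatial_profile),
            class = "osc_spec")
}

#' Transient artifact specification
#'
#' Rates and magnitudes of the two artifact families injected by
#' [inject_artifacts()]: smooth high-amplitude blink-like bumps (preferring
#' frontal channels) and band-limited muscle bursts. Event times follow a
#' Poisson process at the stated rate.
#'
#' @param blink_rate Blink events per minute.
#' @param blink_amplitude Peak blink amplitude in microvolts.
#' @param blink_duration Blink duration in seconds.
#' @param muscle_burst_rate Muscle bursts per minute.
#' @param muscle_band Frequency range of muscle activity, Hz.
#' @param muscle_amplitude RMS amplitude of a burst in microvolts.
#' @param muscle_duration Burst duration in seconds.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(blink_rate = 10, blink_amplitude = 40,
                          blink_duration = 0.4, muscle_burst_rate = 4,
                          muscle_band = c(20, 45), muscle_amplitude = 8,
                          muscle_duration = 0.3) {
  if (blink_rate < 0 || muscle_burst_rate < 0) {
    stop("artifact rates must be >= 0", call. = FALSE)
  }
  if (blink_duration <= 0 || muscle_duration <= 0) {
    stop("artifact durations must be > 0", call. = FALSE)
  }
  structure(list(blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 blink_duration = blink_duration,
                 muscle_burst_rate = muscle_burst_rate,
                 muscle_band = muscle_band,
                 muscle_amplitude = muscle_amplitude,
                 muscle_duration = muscle_duration),
            class = "artifact_spec")
}

#' Simulation configuration for one synthetic subject
#'
#' Describes the montage, rates, trial structure, spectral content and
#' condition effects of a synthetic recording session. Defaults emulate the
#' study conditions: an 80-channel 10-10 montage at 1200 Hz, 1-minute trials
#' (3 VOICE, 2 MI after VOICE, 3 VR+MI, 2 MI after VR), 1/f background,
#' alpha (10 Hz) and beta (21.5 Hz) rhythms concentrated on the 18 motor-area
#' channels, 50 Hz line noise and transient artifacts. Condition effects are
#' multiplicative amplitude gains per (task, band) applied through the
#' oscillations' spatial profiles, so a gain g multiplies band power by g^2 on
#' fully weighted channels.
#'
#' Amplitudes are on the scale at which the artifact-attenuation thresholds
#' (`k1 = 8`, `k2 = 35` coefficient units) leave artifact-free signal in the
#' filter's identity region; see the methods vignette.
#'
#' @param n_channels Number of channels (subset of the 80-channel montage).
#' @param channel_labels Channel names; default the first `n_channels` labels
#'   of [montage_1010()], reordered so the motor channels are always included.
#' @param sampling_rate Acquisition rate in Hz.
#' @param trial_duration Trial length in seconds.
#' @param trials_per_task Named integer vector of trial counts per task code.
#' @param background_exponent Spectral slope gamma of the 1/f^gamma background.
#' @param background_rms Background RMS amplitude in microvolts.
#' @param alpha_spec,beta_spec [osc_spec()] objects for the two rhythms.
#' @param line_noise_amp Peak amplitude of 50 Hz line noise in microvolts.
#' @param artifact_spec An [artifact_spec()].
#' @param effect_gains Numeric matrix, tasks x bands (`"alpha"`, `"beta"`),
#'   of multiplicative amplitude gains; all entries must be positive.
#' @param seed Master seed; per-(task, trial) substreams are derived from it
#'   so adding trials never changes earlier ones.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(sampling_rate = 200, trial_duration = 10)
#' cfg$effect_gains
sim_config <- function(n_channels = 80,
                       channel_labels = NULL,
                       sampling_rate = 1200,
                       trial_duration = 60,
                       trials_per_task = c(VOICE = 3, MI_VOICE = 2,
                                           VR_MI = 3, MI_VR = 2),
                       background_exponent = 1,
                       background_rms = 1,
                       alpha_spec = osc_spec(10, 4, 1.3),
                       beta_spec = osc_spec(21.5, 17, 0.7),
                       line_noise_amp = 0.5,
                       artifact_spec = eegmi::artifact_spec(),
                       effect_gains = NULL,
                       seed = 1) {
  if (is.null(channel_labels)) {
    all_labels <- montage_1010()$label
    if (n_channels > length(all_labels)) {
      stop("`n_channels` exceeds the 80-channel montage", call. = FALSE)
    }
    # keep the motor channels available even for small montages
    channel_labels <- unique(c(
      intersect(motor_channels(), all_labels),
      all_labels
    ))[seq_len(max(n_channels, 0L))]
    if (n_channels <= 18L) channel_labels <- motor_channels()[seq_len(n_channels)]
  }
  n_channels <- length(channel_labels)
  if (n_channels < 1L) stop("at least one channel is required", call. = FALSE)
  if (any(trials_per_task < 1)) stop("all trial counts must be >= 1", call. = FALSE)
  bad <- setdiff(names(trials_per_task), names(.eegmi_tasks))
  if (length(bad)) stop("unknown task(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(effect_gains)) {
    effect_gains <- matrix(
      c(1.00, 1.00,
        1.15, 1.10,
        1.50, 1.30,
        1.40, 1.25),
      ncol = 2, byrow = TRUE,
      dimnames = list(names(.eegmi_tasks), c("alpha", "beta"))
    )
  }
  if (any(effect_gains <= 0)) stop("effect gains must be > 0", call. = FALSE)
  hi <- max(alpha_spec$center_freq + alpha_spec$bandwidth,
            beta_spec$center_freq + beta_spec$bandwidth,
            if (line_noise_amp > 0) 50 else 0)
  if (sampling_rate <= 2 * hi) {
    stop("`sampling_rate` must exceed twice the highest generated frequency",
         call. = FALSE)
  }
  fill_profile <- function(spec) {
    if (is.null(spec$spatial_profile)) {
      w <- rep(0.3, n_channels)
      names(w) <- channel_labels
      w[intersect(motor_channels(), channel_labels)] <- 1
      spec$spatial_profile <- w
    } else {
      bad <- setdiff(names(spec$spatial_profile), channel_labels)
      if (length(bad)) {
        stop("spatial_profile names not in montage: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      w <- rep(0, n_channels)
      names(w) <- channel_labels
      w[names(spec$spatial_profile)] <- spec$spatial_profile
      spec$spatial_profile <- w
    }
    spec
  }
  structure(list(
    n_channels = n_channels, channel_labels = channel_labels,
    sampling_rate = sampling_rate, trial_duration = trial_duration,
    trials_per_task = trials_per_task,
    background_exponent = background_exponent, background_rms = background_rms,
    alpha_spec = fill_profile(alpha_spec), beta_spec = fill_profile(beta_spec),
    line_noise_amp = line_noise_amp, artifact_spec = artifact_spec,
    effect_gains = effect_gains, seed = seed
  ), class = "sim_config")
}

# 1/f^gamma noise, unit RMS, one column per channel. Spectral amplitudes fall
# as f^(-gamma/2), clamped below 1 Hz to avoid the DC singularity.
.pink_noise <- function(n, n_ch, gamma, rate) {
  nf <- n %/% 2L
  f <- (1:nf) * rate / n
  scale <- pmax(f, 1)^(-gamma / 2)
  re <- matrix(rnorm(nf * n_ch), nf, n_ch) * scale
  im <- matrix(rnorm(nf * n_ch), nf, n_ch) * scale
  .half_spectrum_to_signal(re, im, n)
}

# Band-limited noise with a Gaussian spectral envelope (FWHM = bandwidth),
# unit RMS per column.
.band_noise <- function(n, n_ch, f0, bw, rate) {
  nf <- n %/% 2L
  f <- (1:nf) * rate / n
  sd_f <- bw / (2 * sqrt(2 * log(2)))
  scale <- exp(-0.5 * ((f - f0) / sd_f)^2)
  re <- matrix(rnorm(nf * n_ch), nf, n_ch) * scale
  im <- matrix(rnorm(nf * n_ch), nf, n_ch) * scale
  .half_spectrum_to_signal(re, im, n)
}

# Assemble a hermitian spectrum from half-spectrum parts and invert; columns
# normalised to unit RMS.
.half_spectrum_to_signal <- function(re, im, n) {
  nf <- nrow(re)
  n_ch <- ncol(re)
  spec <- matrix(0 + 0i, n, n_ch)
  spec[2:(nf + 1L), ] <- complex(real = re, imaginary = im)
  if (n %% 2L == 0L) spec[nf + 1L, ] <- complex(real = re[nf, ], imaginary = 0)
  spec[n:(n - nf + 2L), ] <- Conj(spec[2:nf, ])
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  sweep(x, 2L, rms, "/")
}

#' Generate one synthetic trial
#'
#' Produces a raw multi-channel recording for one (task, trial) cell:
#' 1/f background + alpha and beta oscillations (scaled per channel by the
#' spatial profile and per task/band by `effect_gains`) + 50 Hz line noise.
#' Deterministic given `(seed, task, trial_index)`; artifacts are added
#' separately by [inject_artifacts()].
#'
#' @param config A [sim_config()].
#' @param task Task code (see [experiment_tasks()]).
#' @param trial_index 1-based trial number, `<= trials_per_task[task]`.
#' @return An [eeg_recording()].
#' @export
#' @examples
#' cfg <- sim_config(n_channels = 4, sampling_rate = 200, trial_duration = 2)
#' rec <- generate_recording(cfg, "VR_MI", 1)
#' dim(rec$data)
generate_recording <- function(config, task, trial_index) {
  stopifnot(inherits(config, "sim_config"))
  if (!task %in% names(.eegmi_tasks)) {
    stop("unknown task: ", task, call. = FALSE)
  }
  n_avail <- config$trials_per_task[task]
  if (is.na(n_avail) || trial_index < 1 || trial_index > n_avail) {
    stop(sprintf("trial_index %d out of range for task %s (%s trials)",
                 trial_index, task, n_avail %||% 0), call. = FALSE)
  }
  task_index <- match(task, names(.eegmi_tasks))
  n <- round(config$trial_duration * config$sampling_rate)
  n_ch <- config$n_channels
  set.seed(.substream(config$seed, task_index, trial_index))

  x <- matrix(0, n, n_ch)
  if (config$background_rms > 0) {
    x <- x + config$background_rms *
      .pink_noise(n, n_ch, config$background_exponent, config$sampling_rate)
  }
  t <- (seq_len(n) - 1L) / config$sampling_rate
  for (band in c("alpha", "beta")) {
    spec <- if (band == "alpha") config$alpha_spec else config$beta_spec
    if (spec$base_amplitude <= 0) next
    gain <- config$effect_gains[task, band]
    w <- spec$spatial_profile[config$channel_labels]
    # per-channel amplitude; base_amplitude is peak-equivalent (RMS = A/sqrt(2))
    amp <- spec$base_amplitude * gain * w
    if (spec$bandwidth == 0) {
      osc <- sin(2 * pi * spec$center_freq * t)
      x <- x + outer(osc, amp)
    } else {
      osc <- .band_noise(n, n_ch, spec$center_freq, spec$bandwidth,
                         config$sampling_rate)
      x <- x + sweep(osc, 2L, amp / sqrt(2), "*")
    }
  }
  if (config$line_noise_amp > 0) {
    x <- x + config$line_noise_amp * sin(2 * pi * 50 * t)
  }
  eeg_recording(t(x), config$channel_labels, config$sampling_rate,
                meta = list(task = task, trial = trial_index,
                            seed = config$seed, units = "uV"))
}

#' Inject transient artifacts into a recording
#'
#' Adds blink-like bumps and muscle bursts at Poisson-distributed times and
#' returns both the contaminated recording and a log of every event. Blinks
#' are Gaussian bumps assigned to a frontal channel when the montage has any
#' (labels Fp*/AF*/F*), otherwise to a uniformly drawn channel; muscle bursts
#' are band-limited noise under a Hann envelope on a uniformly drawn channel.
#'
#' @param rec An [eeg_recording()].
#' @param spec An [artifact_spec()].
#' @param seed Integer seed for the event stream.
#' @return A list with elements `recording` (contaminated copy) and `log`
#'   (tibble: kind, channel, onset, duration, amplitude).
#' @export
inject_artifacts <- function(rec, spec, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "artifact_spec"))
  dur <- recording_duration(rec)
  set.seed(.substream(seed))
  data <- rec$data
  log <- list()
  frontal <- grep("^(Fp|AF|F)[0-9z]+$", rec$labels, value = TRUE)
  if (!length(frontal)) frontal <- rec$labels

  add_event <- function(kind, channel, onset, duration, amplitude, wave) {
    i0 <- round(onset * rec$rate) + 1L
    idx <- i0:(i0 + length(wave) - 1L)
    data[channel, idx] <<- data[channel, idx] + wave
    log[[length(log) + 1L]] <<- tibble::tibble(
      kind = kind, channel = channel, onset = onset,
      duration = duration, amplitude = amplitude
    )
  }

  n_blink <- if (spec$blink_rate > 0 && dur > spec$blink_duration) {
    rpois(1L, spec$blink_rate * dur / 60)
  } else 0L
  for (i in seq_len(n_blink)) {
    d <- spec$blink_duration
    onset <- runif(1, 0, dur - d)
    ch <- sample(frontal, 1L)
    m <- round(d * rec$rate)
    tt <- (seq_len(m) - 1L) / rec$rate
    wave <- spec$blink_amplitude * exp(-0.5 * ((tt - d / 2) / (d / 6))^2)
    add_event("blink", ch, onset, d, spec$blink_amplitude, wave)
  }

  n_musc <- if (spec$muscle_burst_rate > 0 && dur > spec$muscle_duration) {
    rpois(1L, spec$muscle_burst_rate * dur / 60)
  } else 0L
  for (i in seq_len(n_musc)) {
    d <- spec$muscle_duration
    onset <- runif(1, 0, dur - d)
    ch <- sample(rec$labels, 1L)
    m <- round(d * rec$rate)
    f0 <- mean(spec$muscle_band)
    bw <- diff(spec$muscle_band)
    burst <- .band_noise(m, 1L, f0, bw, rec$rate)[, 1]
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = m)))
    wave <- spec$muscle_amplitude * burst * env
    add_event("muscle", ch, onset, d, spec$muscle_amplitude, wave)
  }

  log <- if (length(log)) do.call(rbind, log) else
    tibble::tibble(kind = character(), channel = character(),
                   onset = numeric(), duration = numeric(),
                   amplitude = numeric())
  list(
    recording = eeg_recording(data, rec$labels, rec$rate, rec$meta),
    log = log
  )
}
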
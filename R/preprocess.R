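#' Restrict a recording to a set of channels
#'
#' Returns the recording restricted to `channels`, in the requested order. The
#' study analyses the 18 channels over the motor areas ([motor_channels()]).
#'
#' @param rec An [eeg_recording()].
#' @param channels Channel names to keep, in the desired output order.
#' @return An `eeg_recording` with the requested channels.
#' @export
#' @examples
#' cfg <- sim_config(n_channels = 80, sampling_rate = 200, trial_duration = 2)
#' rec <- generate_recording(cfg, "VOICE", 1)
#' sel <- select_channels(rec, motor_channels())
#' sel$labels
select_channels <- function(rec, channels) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(channels, rec$labels)
  if (length(missing)) {
    stop("channel(s) not present in recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eeg_recording(rec$data[channels, , drop = FALSE], channels, rec$rate, rec$meta)
}

#' Trim a recording to an analysis window
#'
#' Keeps the half-open window `[start, end)` seconds. Trial onsets carry
#' machinery transients and trials differ slightly in length, so the default
#' window retains the 6th through 51st second (45 s) of each 1-minute trial.
#'
#' @param rec An `eeg_recording`.
#' @param start,end Window boundaries in seconds.
#' @return Trimmed `eeg_recording`.
#' @export
trim_recording <- function(rec, start = 6, end = 51) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (end <= start) stop("`end` must exceed `start`", call. = FALSE)
  if (recording_duration(rec) < end - 1e-9) {
    stop(sprintf("recording is %.3f s long; %g s are required",
                 recording_duration(rec), end), call. = FALSE)
  }
  i0 <- round(start * rec$rate) + 1L
  i1 <- round(end * rec$rate)
  meta <- rec$meta
  meta$trim <- c(start = start, end = end)
  eeg_recording(rec$data[, i0:i1, drop = FALSE], rec$labels, rec$rate, meta)
}

#' Split a recording into fixed-length epochs
#'
#' @param rec An `eeg_recording` whose duration is an exact multiple of
#'   `epoch_duration`.
#' @param epoch_duration Epoch length in seconds (default 1).
#' @return An [eeg_epochs()] object, epochs x channels x samples.
#' @export
epoch_recording <- function(rec, epoch_duration = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(rec$rate * epoch_duration)
  n <- ncol(rec$data)
  if (n %% spe != 0L) {
    stop("recording length is not a whole number of epochs", call. = FALSE)
  }
  n_ep <- n %/% spe
  # data is channels x samples; reshape to epochs x channels x samples
  arr <- array(rec$data, dim = c(nrow(rec$data), spe, n_ep))
  eeg_epochs(aperm(arr, c(3, 1, 2)), rec$rate, rec$labels, epoch_duration, rec$meta)
}

#' Trim a trial and shape it into 1-s epochs
#'
#' Convenience composition of [trim_recording()] and [epoch_recording()]: the
#' `[start, end)` window is kept and split into non-overlapping epochs, so a
#' 60-s trial yields 45 one-second epochs under the defaults.
#'
#' @inheritParams trim_recording
#' @inheritParams epoch_recording
#' @return An `eeg_epochs` object.
#' @export
#' @examples
#' cfg <- sim_config(n_channels = 4, sampling_rate = 200)
#' ep <- trim_and_epoch(generate_recording(cfg, "VOICE", 1))
#' dim(ep$data)   # 45 x 4 x 200
trim_and_epoch <- function(rec, start = 6, end = 51, epoch_duration = 1) {
  epoch_recording(trim_recording(rec, start, end), epoch_duration)
}

#' Downsample a recording
#'
#' Reduces the sampling rate by an integer factor with anti-alias filtering
#' before decimation (zero-phase low-pass as in [signal::decimate()]). The
#' study downsamples 1200 Hz recordings to 200 Hz.
#'
#' @param rec An `eeg_recording`.
#' @param target_rate Target rate in Hz; must divide `rec$rate`.
#' @return An `eeg_recording` at `target_rate`.
#' @export
downsample_recording <- function(rec, target_rate = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate <= 0) stop("`target_rate` must be positive", call. = FALSE)
  if (abs(rec$rate / target_rate - round(rec$rate / target_rate)) > 1e-9) {
    stop(sprintf("`target_rate` (%g) must divide the sampling rate (%g)",
                 target_rate, rec$rate), call. = FALSE)
  }
  q <- as.integer(round(rec$rate / target_rate))
  if (q == 1L) return(rec)
  out <- NULL
  for (i in seq_len(nrow(rec$data))) {
    y <- signal::decimate(rec$data[i, ], q, ftype = "iir")
    if (is.null(out)) out <- matrix(0, nrow(rec$data), length(y))
    out[i, ] <- y
  }
  meta <- rec$meta
  meta$downsampled_from <- rec$rate
  eeg_recording(out, rec$labels, target_rate, meta)
}

#' Band-pass filter a recording
#'
#' Applies a Butterworth band-pass per channel. Application is zero-phase
#' (forward-backward, [signal::filtfilt()]), which squares the magnitude
#' response; the mode is recorded in `meta$filter`. The study uses a 5th-order
#' 1-40 Hz band to retain motor-related rhythms and reject drift and line
#' noise.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @param order Butterworth order of the underlying band-pass design.
#' @return Filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 1, high = 40, order = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && high > low && high < rec$rate / 2)) {
    stop(sprintf("band edges must satisfy 0 < low < high < rate/2 (got %g-%g Hz at %g Hz)",
                 low, high, rec$rate), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) * 2 / rec$rate, type = "pass")
  out <- matrix(0, nrow(rec$data), ncol(rec$data))
  for (i in seq_len(nrow(out))) {
    out[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  }
  meta <- rec$meta
  meta$filter <- list(type = "butterworth", order = order, band = c(low, high),
                      mode = "zero-phase")
  eeg_recording(out, rec$labels, rec$rate, meta)
}

#' Full preprocessing of one raw trial
#'
#' Stage order: channel selection, trimming at the native rate, downsampling,
#' zero-phase Butterworth band-pass, epoching into 1-s segments.
#'
#' @param rec Raw `eeg_recording`.
#' @param channels Channels to retain (default the 18 motor channels).
#' @param trim Length-2 window in seconds (default `c(6, 51)`).
#' @param target_rate Rate after downsampling (Hz).
#' @param band Band-pass edges in Hz.
#' @param order Butterworth order.
#' @return An `eeg_epochs` object of preprocessed 1-s epochs.
#' @export
preprocess_trial <- function(rec, channels = motor_channels(), trim = c(6, 51),
                             target_rate = 200, band = c(1, 40), order = 5) {
  rec <- select_channels(rec, channels)
  rec <- trim_recording(rec, trim[1], trim[2])
  rec <- downsample_recording(rec, target_rate)
  rec <- bandpass_filter(rec, band[1], band[2], order)
  epoch_recording(rec, 1)
}
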
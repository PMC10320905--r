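.welch_window <- function(name, n) {
  switch(name,
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)),
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)),
    boxcar = rep(1, n),
    stop("unknown window: ", name, call. = FALSE)
  )
}

#' Welch power spectral density of epoched data
#'
#' Per-epoch, per-channel Welch periodogram: each epoch series is split into
#' (possibly overlapping) segments, windowed, zero-padded and transformed;
#' segment periodograms are averaged. With the defaults (segment = whole 1-s
#' epoch, Hamming window, zero-pad factor 4) each 200-sample epoch yields one
#' segment on a 0.25 Hz grid. Scaling is one-sided density (power/Hz): the
#' integral of the PSD over frequency approximates the windowed signal's
#' variance.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param window Window name: `"hamming"` (default), `"hann"`, `"boxcar"`.
#' @param segment_length Segment length in samples; default the full epoch.
#' @param overlap Fractional overlap between segments in `[0, 1)` (only
#'   relevant when `segment_length` is shorter than the epoch).
#' @param zero_pad_factor FFT length as a multiple of `segment_length`.
#' @return An object of class `periodogram`: `freqs` (Hz), `psd` (array,
#'   epochs x channels x frequencies), `labels`, `rate`, and the analysis
#'   parameters in `meta`.
#' @export
#' @examples
#' cfg <- sim_config(n_channels = 2, sampling_rate = 200, trial_duration = 8)
#' ep <- trim_and_epoch(generate_recording(cfg, "VOICE", 1), 6, 8)
#' p <- welch_periodogram(ep)
#' range(p$freqs)
welch_periodogram <- function(epochs, window = "hamming",
                              segment_length = NULL, overlap = 0.5,
                              zero_pad_factor = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  ns <- d[3]
  if (is.null(segment_length)) segment_length <- ns
  if (segment_length > ns) {
    stop("`segment_length` exceeds the epoch length", call. = FALSE)
  }
  if (zero_pad_factor < 1) stop("`zero_pad_factor` must be >= 1", call. = FALSE)
  w <- .welch_window(window, segment_length)
  nfft <- as.integer(round(segment_length * zero_pad_factor))
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq(1L, ns - segment_length + 1L, by = step)
  n_series <- d[1] * d[2]
  X <- t(matrix(epochs$data, n_series, ns))  # samples x series
  acc <- matrix(0, nfft %/% 2L + 1L, n_series)
  for (s in starts) {
    seg <- X[s:(s + segment_length - 1L), , drop = FALSE] * w
    if (nfft > segment_length) {
      seg <- rbind(seg, matrix(0, nfft - segment_length, n_series))
    }
    Y <- mvfft(seg)
    acc <- acc + abs(Y[seq_len(nfft %/% 2L + 1L), , drop = FALSE])^2
  }
  scale <- epochs$rate * sum(w^2) * length(starts)
  psd <- acc / scale
  # one-sided: double every bin except DC (and Nyquist when nfft is even)
  dbl <- seq_len(nrow(psd))
  dbl <- dbl[-1L]
  if (nfft %% 2L == 0L) dbl <- dbl[-length(dbl)]
  psd[dbl, ] <- 2 * psd[dbl, ]
  freqs <- (seq_len(nfft %/% 2L + 1L) - 1L) * epochs$rate / nfft
  out <- array(t(psd), dim = c(d[1], d[2], length(freqs)))
  structure(list(
    freqs = freqs, psd = out, labels = epochs$labels, rate = epochs$rate,
    meta = list(window = window, segment_length = segment_length,
                overlap = overlap, zero_pad_factor = zero_pad_factor,
                n_epochs = d[1])
  ), class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  d <- if (is.matrix(x$psd)) c(NA, dim(x$psd)) else dim(x$psd)
  cat(sprintf("<periodogram> %s x %d channels x %d frequencies (%.2f-%.2f Hz)\n",
              if (is.na(d[1])) "averaged" else paste(d[1], "epochs"),
              d[2], d[3], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Average periodograms across epochs (and trials)
#'
#' Pointwise mean of per-epoch power spectral densities. Accepts a single
#' per-epoch `periodogram` or a list of them (e.g. one per trial of the same
#' task); all must share an identical frequency grid.
#'
#' @param x A `periodogram` or list of `periodogram` objects.
#' @return A `periodogram` whose `psd` is a channels x frequencies matrix;
#'   `meta$n_epochs` records how many epochs were pooled.
#' @export
average_periodograms <- function(x) {
  if (inherits(x, "periodogram")) x <- list(x)
  if (!length(x) || !all(vapply(x, inherits, logical(1), "periodogram"))) {
    stop("`x` must be a periodogram or list of periodograms", call. = FALSE)
  }
  ref <- x[[1L]]
  total <- NULL
  n <- 0L
  for (p in x) {
    if (length(p$freqs) != length(ref$freqs) ||
        max(abs(p$freqs - ref$freqs)) > 1e-9) {
      stop("frequency grids do not match", call. = FALSE)
    }
    if (!identical(p$labels, ref$labels)) {
      stop("channel sets do not match", call. = FALSE)
    }
    m <- if (is.matrix(p$psd)) p$psd * (p$meta$n_epochs %||% 1L) else
      colSums(p$psd)
    k <- if (is.matrix(p$psd)) (p$meta$n_epochs %||% 1L) else dim(p$psd)[1]
    total <- if (is.null(total)) m else total + m
    n <- n + k
  }
  avg <- total / n
  dimnames(avg) <- list(ref$labels, NULL)
  structure(list(freqs = ref$freqs, psd = avg, labels = ref$labels,
                 rate = ref$rate, meta = modifyList(ref$meta, list(n_epochs = n))),
            class = "periodogram")
}

# Composite Simpson's rule on a uniform grid; the odd-interval remainder is
# handled with Simpson's 3/8 rule on the last three intervals.
.simpson <- function(y, x) {
  n <- length(x)
  if (n < 2L) stop("at least two nodes are required", call. = FALSE)
  h <- diff(x)
  if (max(abs(h - h[1])) > 1e-6 * h[1]) {
    stop("Simpson integration requires a uniform grid", call. = FALSE)
  }
  h <- h[1]
  if (n == 2L) return(h * (y[1] + y[2]) / 2)
  m <- n - 1L  # number of intervals
  if (m %% 2L == 0L) {
    i <- seq(1L, n - 2L, by = 2L)
    sum(h / 3 * (y[i] + 4 * y[i + 1L] + y[i + 2L]))
  } else if (m == 3L) {
    3 * h / 8 * (y[1] + 3 * y[2] + 3 * y[3] + y[4])
  } else {
    head_part <- .simpson(y[1:(n - 3L)], x[1:(n - 3L)])
    tail_part <- 3 * h / 8 * (y[n - 3L] + 3 * y[n - 2L] + 3 * y[n - 1L] + y[n])
    head_part + tail_part
  }
}

#' Band power by Simpson's rule
#'
#' Integrates an epoch-averaged power spectral density over a frequency band
#' using composite Simpson quadrature on the grid nodes inside the band
#' (inclusive edges; bins straddling an edge are clipped to in-band nodes).
#' The alpha band is 8-12 Hz, the beta band 13-30 Hz.
#'
#' @param p An averaged `periodogram` (see [average_periodograms()]).
#' @param band Length-2 numeric band `c(low, high)` in Hz, inside the grid.
#' @return Named numeric vector of per-channel band powers (power units).
#' @export
#' @examples
#' \dontrun{band_power(avg, c(8, 12))}
band_power <- function(p, band) {
  stopifnot(inherits(p, "periodogram"))
  if (!is.matrix(p$psd)) {
    stop("`p` must be an epoch-averaged periodogram; see average_periodograms()",
         call. = FALSE)
  }
  if (band[1] >= band[2]) stop("`band` must be increasing", call. = FALSE)
  if (band[1] < min(p$freqs) - 1e-9 || band[2] > max(p$freqs) + 1e-9) {
    stop(sprintf("band %g-%g Hz lies outside the frequency grid (%g-%g Hz)",
                 band[1], band[2], min(p$freqs), max(p$freqs)), call. = FALSE)
  }
  idx <- which(p$freqs >= band[1] - 1e-9 & p$freqs <= band[2] + 1e-9)
  if (length(idx) < 2L) stop("band contains fewer than two grid nodes", call. = FALSE)
  out <- apply(p$psd[, idx, drop = FALSE], 1L, .simpson, x = p$freqs[idx])
  names(out) <- p$labels
  out
}

#' Spectral entropy of an averaged power spectrum
#'
#' Shannon entropy of the power spectral density normalised to a probability
#' distribution over the bins in `[f0, fn]`:
#' `H = -sum p_hat(f) log2 p_hat(f)` with `p_hat(f) = p(f) / sum p(f)`, in
#' bits (`0 log 0` taken as 0). A single-bin spectrum has entropy 0; a flat
#' spectrum over n bins attains the maximum `log2(n)`.
#'
#' @param p An averaged `periodogram`.
#' @param f0,fn Integration range in Hz (default 1-40).
#' @return Named numeric vector of per-channel entropies in bits, with the
#'   number of bins attached as attribute `"n_bins"`.
#' @export
spectral_entropy <- function(p, f0 = 1, fn = 40) {
  stopifnot(inherits(p, "periodogram"))
  if (!is.matrix(p$psd)) {
    stop("`p` must be an epoch-averaged periodogram", call. = FALSE)
  }
  idx <- which(p$freqs >= f0 - 1e-9 & p$freqs <= fn + 1e-9)
  if (!length(idx)) stop("no frequency bins in range", call. = FALSE)
  H <- apply(p$psd[, idx, drop = FALSE], 1L, function(v) {
    s <- sum(v)
    if (s <= 0) stop("PSD is identically zero in the entropy range", call. = FALSE)
    ph <- v / s
    ph <- ph[ph > 0]
    -sum(ph * log2(ph))
  })
  names(H) <- p$labels
  attr(H, "n_bins") <- length(idx)
  H
}

#' Min-max feature scaling to [-1, 1]
#'
#' `x' = 2 (x - min) / (max - min) - 1`. In this pipeline the pooling set is
#' all values of one metric across a subject's experimental tasks, so that 1
#' marks the subject's overall maximum and -1 the overall minimum.
#'
#' @param x Numeric vector, matrix or array to rescale.
#' @param pool Values defining the min and max (default `x` itself); supply
#'   the task-pooled values to normalise one task's values relative to all
#'   tasks.
#' @return Rescaled object of the same shape as `x`.
#' @export
#' @examples
#' minmax_normalise(c(2, 4, 6))
minmax_normalise <- function(x, pool = x) {
  rng <- range(pool, na.rm = TRUE)
  if (!all(is.finite(rng))) stop("`pool` has no finite values", call. = FALSE)
  if (rng[2] <= rng[1]) {
    stop("degenerate input: max equals min, cannot min-max scale", call. = FALSE)
  }
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}
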
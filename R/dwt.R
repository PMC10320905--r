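# Daubechies-4 orthonormal filter bank (8 taps, standard published values).
.db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
.db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                 -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                 -0.0328830116668852, -0.010597401785069032)
.db4_rec_lo <- rev(.db4_dec_lo)
.db4_rec_hi <- rev(.db4_dec_hi)

.dwt_filters <- function(wavelet) {
  if (!identical(wavelet, "db4")) {
    stop("only the 'db4' wavelet is supported", call. = FALSE)
  }
  list(dec_lo = .db4_dec_lo, dec_hi = .db4_dec_hi,
       rec_lo = .db4_rec_lo, rec_hi = .db4_rec_hi)
}

# One periodized analysis step on a samples-x-series matrix. Convention
# matches periodized DWT references: a[k] = sum_j h[j] x[(2k + L/2 - j) mod N]
# (0-based), an orthogonal transform for even N.
.dwt_step <- function(X, wavelet = "db4") {
  flt <- .dwt_filters(wavelet)
  N <- nrow(X)
  if (N %% 2L != 0L) stop("signal length must be even", call. = FALSE)
  L <- length(flt$dec_lo)
  half <- N %/% 2L
  k <- seq_len(half) - 1L
  A <- matrix(0, half, ncol(X))
  D <- matrix(0, half, ncol(X))
  for (j in seq_len(L) - 1L) {
    idx <- (2L * k + L / 2 - j) %% N + 1L
    A <- A + flt$dec_lo[j + 1L] * X[idx, , drop = FALSE]
    D <- D + flt$dec_hi[j + 1L] * X[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

# Inverse of .dwt_step (transpose of the orthogonal analysis operator).
.idwt_step <- function(A, D, wavelet = "db4") {
  flt <- .dwt_filters(wavelet)
  half <- nrow(A)
  N <- 2L * half
  L <- length(flt$dec_lo)
  k <- seq_len(half) - 1L
  X <- matrix(0, N, ncol(A))
  for (j in seq_len(L) - 1L) {
    idx <- (2L * k + L / 2 - j) %% N + 1L
    X[idx, ] <- X[idx, , drop = FALSE] +
      flt$dec_lo[j + 1L] * A + flt$dec_hi[j + 1L] * D
  }
  X
}

# Multi-level periodized DWT of a samples-x-series matrix. Returns a list
# with the approximation block first, then details from coarsest to finest:
# cA<level>, cD<level>, ..., cD1 (matching the usual wavedec layout).
.wavedec <- function(X, level, wavelet = "db4") {
  N <- nrow(X)
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  if (N < 2^level || N %% 2^level != 0L) {
    stop(sprintf("signal length %d is too short for a level-%d transform (must be a multiple of %d)",
                 N, level, 2^level), call. = FALSE)
  }
  details <- vector("list", level)
  A <- X
  for (l in seq_len(level)) {
    s <- .dwt_step(A, wavelet)
    A <- s$A
    details[[l]] <- s$D
  }
  out <- c(list(A), rev(details))
  names(out) <- c(sprintf("cA%d", level), sprintf("cD%d", level:1))
  out
}

.waverec <- function(coeffs, wavelet = "db4") {
  level <- length(coeffs) - 1L
  A <- coeffs[[1L]]
  for (l in seq_len(level)) {
    A <- .idwt_step(A, coeffs[[l + 1L]], wavelet)
  }
  A
}

#' Discrete wavelet decomposition of one epoch signal
#'
#' Periodized db4 DWT at the requested level, returning approximation and
#' detail coefficient arrays together with each array's interquartile range
#' `r` (the dispersion statistic that drives the attenuation thresholds).
#'
#' @param x Numeric vector (one epoch of one channel). Its length must be a
#'   multiple of `2^level`.
#' @param params An [atar_params()] object (wavelet name and level are used).
#' @return A list of class `coefficient_set`: `coefficients` (named list of
#'   numeric vectors, `cA<level>`, `cD<level>` ... `cD1`) and `r` (named
#'   vector of interquartile ranges).
#' @export
#' @examples
#' cs <- dwt_decompose(sin(2 * pi * 10 * (0:199) / 200), atar_params())
#' names(cs$coefficients)
dwt_decompose <- function(x, params = atar_params()) {
  X <- matrix(as.numeric(x), ncol = 1L)
  coeffs <- .wavedec(X, params$level, params$wavelet)
  vecs <- lapply(coeffs, function(m) m[, 1L])
  r <- vapply(vecs, function(v) unname(diff(quantile(v, c(0.25, 0.75)))),
              numeric(1))
  structure(list(coefficients = vecs, r = r,
                 level = params$level, wavelet = params$wavelet),
            class = "coefficient_set")
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' Inverse of [dwt_decompose()]; with unmodified coefficients the input is
#' recovered to numerical precision (the periodized db4 transform is
#' orthonormal).
#'
#' @param cs A `coefficient_set` from [dwt_decompose()].
#' @return Numeric vector of the reconstructed signal.
#' @export
dwt_reconstruct <- function(cs) {
  stopifnot(inherits(cs, "coefficient_set"))
  mats <- lapply(cs$coefficients, function(v) matrix(v, ncol = 1L))
  .waverec(mats, cs$wavelet)[, 1L]
}
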
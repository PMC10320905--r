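#' Construct a raw multi-channel recording
#'
#' The unit exchanged by the acquisition and preprocessing stages: a labelled
#' channels-by-samples matrix with its sampling rate and trial metadata.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param labels Character vector of unique channel names, one per row.
#' @param rate Sampling rate in Hz.
#' @param meta Named list of metadata (task, trial index, subject id, applied
#'   processing); free-form.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, labels, rate, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (length(labels) != nrow(data)) {
    stop("`labels` must have one entry per data row", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("all samples must be finite", call. = FALSE)
  rownames(data) <- labels
  structure(
    list(data = data, labels = as.character(labels), rate = rate, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
    nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate
  ))
  if (!is.null(x$meta$task)) cat("  task:", x$meta$task, " trial:", x$meta$trial %||% NA, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$rate

#' Construct epoched data
#'
#' @param data Numeric array, epochs x channels x samples.
#' @param rate Sampling rate in Hz.
#' @param labels Channel labels (length = dim 2).
#' @param epoch_duration Epoch length in seconds; `dim(data)[3]` must equal
#'   `rate * epoch_duration` exactly.
#' @param meta Metadata list.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, rate, labels, epoch_duration = 1, meta = list()) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-d array", call. = FALSE)
  if (dim(data)[1] < 1L) stop("at least one epoch is required", call. = FALSE)
  if (dim(data)[2] != length(labels)) {
    stop("`labels` must match the channel dimension", call. = FALSE)
  }
  if (dim(data)[3] != round(rate * epoch_duration)) {
    stop("samples per epoch must equal rate * epoch_duration", call. = FALSE)
  }
  structure(
    list(data = data, rate = rate, labels = as.character(labels),
         epoch_duration = epoch_duration, meta = meta),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$rate
  ))
  invisible(x)
}

#' Concatenate epoched data along the epoch axis
#' @param ... `eeg_epochs` objects with identical channels, rate and epoch length.
#' @return A single `eeg_epochs` object.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "eeg_epochs")) {
    xs <- xs[[1]]
  }
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!identical(x$labels, ref$labels) || x$rate != ref$rate ||
        x$epoch_duration != ref$epoch_duration) {
      stop("epoch objects are not compatible", call. = FALSE)
    }
  }
  arrs <- lapply(xs, function(x) x$data)
  total <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(total, dim(ref$data)[2], dim(ref$data)[3]))
  at <- 1L
  for (a in arrs) {
    n <- dim(a)[1]
    out[at:(at + n - 1L), , ] <- a
    at <- at + n
  }
  eeg_epochs(out, ref$rate, ref$labels, ref$epoch_duration, ref$meta)
}
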
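#' Write a trial recording as a plain numeric array with a metadata sidecar
#'
#' Trials are stored as a tab-separated samples x channels matrix with a
#' channel-label header, plus a JSON sidecar (`<file>.json`) carrying the
#' sampling rate, task, trial index and any other metadata — a documented
#' plain-text exchange format readable by any tool.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path for the data file (e.g. `"trial_01.tsv"`).
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(rate = rec$rate, labels = rec$labels,
               n_samples = ncol(rec$data), meta = rec$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial recording written by [write_trial()]
#'
#' @param path Path to the data file; `<path>.json` must exist alongside it.
#' @return An [eeg_recording()].
#' @export
read_trial <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side_path)) {
    stop("trial file or its .json sidecar is missing: ", path, call. = FALSE)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (!identical(colnames(m), as.character(side$labels))) {
    stop("sidecar labels do not match the data header", call. = FALSE)
  }
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  eeg_recording(t(m), side$labels, side$rate, as.list(meta))
}
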
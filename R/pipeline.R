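#' Pipeline configuration
#'
#' Bundles every stage's parameters for an end-to-end run: simulation,
#' preprocessing (channel selection, trimming, downsampling, band-pass),
#' wavelet artifact attenuation, Welch/band-power/entropy settings and the
#' statistics threshold. Defaults equal the study's stated parameters:
#' 1200 to 200 Hz, 5th-order Butterworth 1-40 Hz, trim to the 6th-51st
#' second, db4 level 3 with k1 = 8, k2 = 35, B = 0.1, alpha 8-12 Hz and beta
#' 13-30 Hz, significance 0.01.
#'
#' @param experiment Experiment variant: 1 (four tasks, including VR+MI) or
#'   2 (three tasks, without VR+MI).
#' @param sim A [sim_config()] describing the synthetic subject(s).
#' @param n_subjects Number of synthetic subjects to run.
#' @param channels Channels analysed after selection (default the 18 motor
#'   channels).
#' @param trim Analysis window in seconds, `c(start, end)`.
#' @param target_rate Rate after downsampling, Hz.
#' @param band Band-pass edges, Hz.
#' @param filter_order Butterworth order.
#' @param welch List of Welch settings (`window`, `segment_length`,
#'   `overlap`, `zero_pad_factor`).
#' @param bands Named list of analysis bands (default alpha 8-12, beta 13-30).
#' @param entropy_range Frequency range for spectral entropy, Hz.
#' @param alpha_level Significance threshold for the pair tests.
#' @param artifacts Inject transient artifacts before preprocessing?
#' @param skip_atar Skip the wavelet attenuation stage?
#' @param atar An [atar_params()].
#' @param out_dir Optional output directory for CSV artefacts and manifest.
#' @param seed Master seed for the whole run (defaults to `sim$seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = 1,
                            sim = sim_config(),
                            n_subjects = 1,
                            channels = motor_channels(),
                            trim = c(6, 51),
                            target_rate = 200,
                            band = c(1, 40),
                            filter_order = 5,
                            welch = list(window = "hamming",
                                         segment_length = NULL,
                                         overlap = 0.5, zero_pad_factor = 4),
                            bands = list(alpha = c(8, 12), beta = c(13, 30)),
                            entropy_range = c(1, 40),
                            alpha_level = 0.01,
                            artifacts = TRUE,
                            skip_atar = FALSE,
                            atar = atar_params(),
                            out_dir = NULL,
                            seed = NULL) {
  cfg <- structure(list(
    experiment = experiment, sim = sim, n_subjects = n_subjects,
    channels = channels, trim = trim, target_rate = target_rate, band = band,
    filter_order = filter_order, welch = welch, bands = bands,
    entropy_range = entropy_range, alpha_level = alpha_level,
    artifacts = artifacts, skip_atar = skip_atar, atar = atar,
    out_dir = out_dir, seed = seed %||% sim$seed
  ), class = "pipeline_config")
  cfg$tasks <- intersect(experiment_tasks(experiment),
                         names(sim$trials_per_task))
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every cross-stage invariant without running anything and returns a
#' character vector of violations (empty when the configuration is valid).
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violation messages.
#' @export
#' @examples
#' cfg <- pipeline_config(sim = sim_config(sampling_rate = 200))
#' validate_config(cfg)   # character(0)
validate_config <- function(config) {
  v <- character()
  note <- function(msg) v <<- c(v, msg)
  if (!config$experiment %in% c(1, 2)) note("experiment must be 1 or 2")
  if (config$experiment == 2 && "VR_MI" %in% config$tasks) {
    note("Experiment 2 must not include the VR+MI task")
  }
  if (length(config$tasks) < 2) note("at least two tasks are required")
  sim <- config$sim
  if (any(sim$trials_per_task < 1)) note("all trial counts must be >= 1")
  if (any(sim$effect_gains <= 0)) note("effect gains must be positive")
  if (sim$sampling_rate %% config$target_rate != 0) {
    note(sprintf("target_rate %g does not divide the sampling rate %g",
                 config$target_rate, sim$sampling_rate))
  }
  if (config$target_rate <= 2 * config$band[2]) {
    note(sprintf("band-pass upper edge %g Hz violates Nyquist at %g Hz",
                 config$band[2], config$target_rate))
  }
  if (!(config$band[1] > 0 && config$band[2] > config$band[1])) {
    note("band-pass edges must satisfy 0 < low < high")
  }
  if (config$trim[2] <= config$trim[1]) note("trim window must be increasing")
  if (sim$trial_duration < config$trim[2]) {
    note(sprintf("trial duration %g s is shorter than the trim window end %g s",
                 sim$trial_duration, config$trim[2]))
  }
  missing <- setdiff(config$channels, sim$channel_labels)
  if (length(missing)) {
    note(paste("analysis channels missing from the montage:",
               paste(missing, collapse = ", ")))
  }
  spe <- config$target_rate  # samples per 1-s epoch
  if (!config$skip_atar && spe %% 2^config$atar$level != 0) {
    note(sprintf("epoch length %d is not a multiple of 2^%d (wavelet level)",
                 spe, config$atar$level))
  }
  for (bn in names(config$bands)) {
    b <- config$bands[[bn]]
    if (b[1] >= b[2] || b[2] > config$target_rate / 2) {
      note(sprintf("band '%s' (%g-%g Hz) is invalid at rate %g", bn, b[1],
                   b[2], config$target_rate))
    }
  }
  v
}

# Per-task epoch-averaged periodograms for one subject. The compute core of
# the pipeline, reused at reduced problem sizes.
.task_periodograms <- function(config, subject = 1L) {
  sim <- config$sim
  sim$seed <- .substream(config$seed, subject = subject)
  out <- list()
  for (task in config$tasks) {
    task_index <- match(task, names(.eegmi_tasks))
    per_trial <- list()
    for (trial in seq_len(sim$trials_per_task[[task]])) {
      rec <- generate_recording(sim, task, trial)
      if (isTRUE(config$artifacts)) {
        inj <- inject_artifacts(rec, sim$artifact_spec,
                                seed = .substream(sim$seed + 500009L,
                                                  task_index, trial))
        rec <- inj$recording
      }
      per_trial[[trial]] <- preprocess_trial(
        rec, channels = config$channels, trim = config$trim,
        target_rate = config$target_rate, band = config$band,
        order = config$filter_order
      )
    }
    epochs <- bind_epochs(per_trial)
    if (!isTRUE(config$skip_atar)) {
      epochs <- atar_filter(epochs, config$atar)
    }
    pg <- welch_periodogram(
      epochs, window = config$welch$window %||% "hamming",
      segment_length = config$welch$segment_length,
      overlap = config$welch$overlap %||% 0.5,
      zero_pad_factor = config$welch$zero_pad_factor %||% 4
    )
    out[[task]] <- average_periodograms(pg)
  }
  out
}

#' Band powers per task for one synthetic subject
#'
#' Runs simulate, preprocess, attenuate and Welch-average for one subject and
#' integrates each analysis band per channel.
#'
#' @param config A [pipeline_config()].
#' @param subject Subject index (drives the seed substream).
#' @return Named list: `band_powers[[task]][[band]]` (named per-channel
#'   vectors) and `periodograms[[task]]` (averaged `periodogram` objects).
#' @export
task_band_powers <- function(config, subject = 1L) {
  avg <- .task_periodograms(config, subject)
  bp <- lapply(avg, function(p) {
    lapply(config$bands, function(b) band_power(p, b))
  })
  list(band_powers = bp, periodograms = avg)
}

#' Run the full analysis pipeline
#'
#' For each synthetic subject: generate all trials, preprocess, attenuate
#' artifacts, compute epoch-averaged periodograms per task, min-max normalise
#' them pooled across the subject's tasks, integrate alpha/beta band powers,
#' compute spectral entropy, run the channel-paired Wilcoxon tests for every
#' task pair, and build normalised scalp maps per task for each metric. When
#' `config$out_dir` is set, writes tidy CSVs and a JSON run manifest.
#'
#' @param config A [pipeline_config()]; must pass [validate_config()].
#' @return A list of class `pipeline_result`: `subjects` (per-subject lists
#'   with `periodograms`, `normalised_periodograms`, `band_powers`,
#'   `entropy`, `pair_tests`, `scalp_maps`), `pair_tests` (combined tibble),
#'   `table` (formatted p-value table), `manifest`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim = sim_config(
#'   n_channels = 18, sampling_rate = 200, trial_duration = 12,
#'   trials_per_task = c(VOICE = 1, MI_VOICE = 1, VR_MI = 1, MI_VR = 1)),
#'   trim = c(6, 12))
#' res <- run_pipeline(cfg)
#' res$table
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid pipeline configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  montage <- montage_1010()
  subjects <- list()
  all_tests <- list()
  for (s in seq_len(config$n_subjects)) {
    avg <- .task_periodograms(config, s)
    fr <- config$entropy_range
    fidx <- which(avg[[1]]$freqs >= fr[1] - 1e-9 & avg[[1]]$freqs <= fr[2] + 1e-9)

    # normalised periodograms, pooled across the subject's tasks
    pooled_psd <- unlist(lapply(avg, function(p) p$psd[, fidx]))
    norm_pg <- lapply(avg, function(p) {
      m <- minmax_normalise(p$psd[, fidx, drop = FALSE], pool = pooled_psd)
      list(freqs = p$freqs[fidx], psd = m, labels = p$labels)
    })

    bp <- lapply(avg, function(p) lapply(config$bands, function(b) band_power(p, b)))
    ent <- lapply(avg, function(p) spectral_entropy(p, fr[1], fr[2]))

    tests <- pair_tests(bp, subject = s, alpha = config$alpha_level)
    all_tests[[s]] <- tests

    maps <- list()
    metrics <- c(names(config$bands), "entropy")
    for (metric in metrics) {
      vals <- lapply(config$tasks, function(task) {
        if (metric == "entropy") ent[[task]] else bp[[task]][[metric]]
      })
      names(vals) <- config$tasks
      pool <- unlist(vals)
      if (max(pool) > min(pool)) {
        maps[[metric]] <- lapply(vals, scalp_map, montage = montage, pool = pool)
      }
    }

    subjects[[s]] <- list(
      periodograms = avg, normalised_periodograms = norm_pg,
      band_powers = bp, entropy = ent, pair_tests = tests, scalp_maps = maps
    )
  }
  combined <- do.call(rbind, all_tests)
  table <- build_table(combined, alpha = config$alpha_level)
  manifest <- list(
    package = as.character(utils::packageVersion("eegmi")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    stages = list(
      tasks = config$tasks,
      trials_per_task = as.list(config$sim$trials_per_task[config$tasks]),
      channels = config$channels,
      trim = config$trim,
      sampling = c(native = config$sim$sampling_rate,
                   analysis = config$target_rate),
      filter = c(order = config$filter_order, low = config$band[1],
                 high = config$band[2], mode = "zero-phase"),
      atar = if (config$skip_atar) "skipped" else
        config$atar[c("wavelet", "level", "k1", "k2", "B", "exponent_sign",
                      "coefficient_scope")],
      welch = config$welch,
      bands = config$bands,
      alpha_level = config$alpha_level
    ),
    files = character()
  )
  result <- structure(list(subjects = subjects, pair_tests = combined,
                           table = table, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    result$manifest$files <- .write_outputs(result, config)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subject(s), %d pair tests\n",
              length(x$subjects), nrow(x$pair_tests)))
  invisible(x)
}

# tidy CSV outputs + manifest
.write_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  rows_bp <- list(); rows_ent <- list(); rows_pg <- list()
  for (s in seq_along(result$subjects)) {
    sub <- result$subjects[[s]]
    for (task in names(sub$band_powers)) {
      for (band in names(sub$band_powers[[task]])) {
        v <- sub$band_powers[[task]][[band]]
        rows_bp[[length(rows_bp) + 1L]] <- data.frame(
          subject = s, task = task, band = band,
          channel = names(v), power = as.numeric(v))
      }
      e <- sub$entropy[[task]]
      rows_ent[[length(rows_ent) + 1L]] <- data.frame(
        subject = s, task = task, channel = names(e),
        entropy_bits = as.numeric(e))
      np <- sub$normalised_periodograms[[task]]
      rows_pg[[length(rows_pg) + 1L]] <- data.frame(
        subject = s, task = task,
        channel = rep(np$labels, times = length(np$freqs)),
        freq = rep(np$freqs, each = length(np$labels)),
        psd_norm = as.numeric(np$psd))
    }
  }
  emit(do.call(rbind, rows_bp), "band_powers.csv")
  emit(do.call(rbind, rows_ent), "entropy.csv")
  emit(do.call(rbind, rows_pg), "periodograms_normalised.csv")
  emit(as.data.frame(result$pair_tests), "pair_tests.csv")
  emit(as.data.frame(result$table), "pair_table.csv")
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- result$manifest
  manifest$files <- c(files, manifest_path)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$files
}
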
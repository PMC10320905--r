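#' Channel-paired Wilcoxon signed-rank test
#'
#' Compares two tasks' per-channel band powers with the Wilcoxon signed-rank
#' test, pairing the same channels across tasks (n = 18 motor channels in the
#' study layout). Zero differences are dropped before ranking; tied absolute
#' differences receive mid-ranks. The two-sided p-value comes from the exact
#' null distribution of the signed-rank statistic when the effective n is at
#' most 25 and there are no ties, and otherwise from the normal approximation
#' with continuity correction and tie-corrected variance.
#'
#' @param a,b Numeric vectors of per-channel values for the two tasks, same
#'   length and channel order; length at least 5.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @param alpha Significance threshold for the `significant` flag (default
#'   0.01, the level used in the study's tables).
#' @return A one-row tibble: `n`, `n_used` (non-zero differences),
#'   `statistic` (sum of positive ranks), `p_value`, `method`, `degenerate`
#'   (all differences zero), `significant`.
#' @export
#' @examples
#' set.seed(1)
#' wilcoxon_pair(rnorm(18, 1), rnorm(18))
wilcoxon_pair <- function(a, b, mode = c("auto", "exact", "approx"),
                          alpha = 0.01) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    stop("`a` and `b` must be in the same channel order", call. = FALSE)
  }
  if (length(a) < 5L) stop("at least 5 pairs are required", call. = FALSE)
  d <- a - b
  nz <- d != 0
  n <- sum(nz)
  if (n == 0L) {
    return(tibble::tibble(n = length(a), n_used = 0L, statistic = NA_real_,
                          p_value = 1, method = "degenerate",
                          degenerate = TRUE, significant = FALSE))
  }
  dd <- d[nz]
  rk <- rank(abs(dd))
  W <- sum(rk[dd > 0])
  ties <- anyDuplicated(abs(dd)) > 0L
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = n <= 25L && !ties
  )
  if (use_exact && ties) {
    stop("exact test is unavailable with tied absolute differences", call. = FALSE)
  }
  if (use_exact) {
    p_lo <- psignrank(W, n)
    p_hi <- psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- W - mu
    z <- z - sign(z) * 0.5          # continuity correction
    p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
    method <- "normal-approx"
  }
  tibble::tibble(n = length(a), n_used = n, statistic = W, p_value = p,
                 method = method, degenerate = FALSE,
                 significant = p < alpha)
}

# canonical ordering of task-pair columns (matching the study's table layout)
.pair_order <- function() {
  combn_pairs <- utils::combn(names(.eegmi_tasks), 2L)
  apply(combn_pairs, 2L, paste, collapse = " vs ")
}

#' Paired tests for every task pair of a subject
#'
#' Runs [wilcoxon_pair()] for every unordered pair of tasks, for each band,
#' pairing per-channel band powers.
#'
#' @param band_powers Named list: `band_powers[[task]][[band]]` is a named
#'   numeric vector of per-channel band powers.
#' @param subject Subject identifier carried into the result.
#' @param alpha Significance threshold (default 0.01).
#' @return Tibble with one row per (pair, band): `subject`, `band`, `task_a`,
#'   `task_b`, `pair`, `n`, `statistic`, `p_value`, `significant`.
#' @export
pair_tests <- function(band_powers, subject = 1L, alpha = 0.01) {
  tasks <- names(band_powers)
  bad <- setdiff(tasks, names(.eegmi_tasks))
  if (length(bad)) stop("unknown task(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bands <- names(band_powers[[1L]])
  out <- list()
  if (length(tasks) >= 2L) {
    prs <- utils::combn(tasks, 2L)
    for (band in bands) {
      for (j in seq_len(ncol(prs))) {
        ta <- prs[1L, j]; tb <- prs[2L, j]
        res <- wilcoxon_pair(band_powers[[ta]][[band]],
                             band_powers[[tb]][[band]], alpha = alpha)
        out[[length(out) + 1L]] <- tibble::tibble(
          subject = subject, band = band, task_a = ta, task_b = tb,
          pair = paste(ta, tb, sep = " vs "),
          n = res$n, statistic = res$statistic, p_value = res$p_value,
          significant = res$significant
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Format pair-test results as a study-style p-value table
#'
#' One row per subject per band; one column per canonical task pair, in the
#' study's column order. Cells show the p-value (`"<0.001"` below 0.001),
#' suffixed with `*` when below the significance threshold; pairs absent from
#' a subject's experiment (e.g. VR+MI pairs in Experiment 2) render as `"-"`.
#'
#' @param results Tibble from [pair_tests()] (possibly several subjects).
#' @param alpha Significance threshold used for the `*` marking.
#' @return A tibble with columns `subject`, `band` and the six pair columns.
#' @export
build_table <- function(results, alpha = 0.01) {
  stopifnot(all(c("subject", "band", "pair", "p_value") %in% names(results)))
  canon <- .pair_order()
  bad <- setdiff(unique(results$pair), canon)
  if (length(bad)) {
    stop("unknown task pair(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fmt <- function(p) {
    base <- if (p < 0.001) "<0.001" else sprintf("%.3f", p)
    if (p < alpha) paste0(base, "*") else base
  }
  keys <- unique(results[, c("subject", "band")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$subject == keys$subject[i] &
                     results$band == keys$band[i], ]
    cells <- vapply(canon, function(pr) {
      hit <- which(sub$pair == pr)
      if (!length(hit)) "-" else fmt(sub$p_value[hit[1L]])
    }, character(1))
    c(list(subject = keys$subject[i], band = keys$band[i]), as.list(cells))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  })))
}
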
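test_that("degenerate and extreme paired inputs give the analytic p-values", {
  a <- stats::setNames(rnorm(18), paste0("ch", 1:18))
  res <- wilcoxon_pair(a, a)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$statistic))

  # all 18 differences positive: the exact two-sided tail is 2 * 2^-18
  b <- a - abs(rnorm(18)) - 0.1
  res2 <- wilcoxon_pair(a, b)
  expect_equal(res2$method, "exact")
  expect_equal(res2$p_value, 2 * 2^-18)
  expect_true(res2$significant)

  expect_error(wilcoxon_pair(a[1:10], b), "same length")
  expect_error(wilcoxon_pair(a[1:3], b[1:3]), "at least 5")
})

test_that("exact p-values agree with exhaustive sign enumeration", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    res <- wilcoxon_pair(a, b, mode = "exact")
    expect_equal(res$p_value, enum_signed_rank_p(a - b), tolerance = 1e-12)
  }
})

test_that("exact p-values also agree with the reference implementation", {
  set.seed(32)
  for (i in 1:25) {
    a <- rnorm(18); b <- rnorm(18)
    res <- wilcoxon_pair(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(res$statistic, unname(ref$statistic))
  }
})

test_that("tied differences fall back to the corrected normal approximation", {
  a <- c(5, 4, 3, 2, 1, 6, 7, 8)
  b <- a - c(1, 1, 2, 2, 3, 3, 4, 4)   # tied |differences|
  res <- wilcoxon_pair(a, b)
  expect_equal(res$method, "normal-approx")
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                             correct = TRUE))
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-9)
  expect_error(wilcoxon_pair(a, b, mode = "exact"), "tied")
})

test_that("null p-values are uniform up to discreteness", {
  set.seed(40)
  p <- vapply(1:4000, function(i) {
    wilcoxon_pair(rnorm(18), rnorm(18))$p_value
  }, numeric(1))
  expect_gt(mean(p <= 0.05), 0.04)
  expect_lt(mean(p <= 0.05), 0.062)
  expect_gt(mean(p <= 0.5), 0.47)
  expect_lt(mean(p <= 0.5), 0.53)
})

test_that("pair tests cover every task pair and the table renders them", {
  set.seed(50)
  tasks <- c("VOICE", "MI_VOICE", "VR_MI", "MI_VR")
  bp <- lapply(stats::setNames(tasks, tasks), function(t) {
    list(alpha = stats::setNames(rnorm(18, 10), paste0("ch", 1:18)),
         beta = stats::setNames(rnorm(18, 5), paste0("ch", 1:18)))
  })
  res <- pair_tests(bp, subject = 1)
  expect_equal(nrow(res), choose(4, 2) * 2)   # 6 pairs x 2 bands
  tab <- build_table(res)
  expect_equal(nrow(tab), 2L)                  # one row per band
  expect_equal(ncol(tab), 2L + 6L)

  # Experiment 2 subjects lack the VR+MI pairs: those columns render "-"
  bp2 <- bp[c("VOICE", "MI_VOICE", "MI_VR")]
  res2 <- pair_tests(bp2, subject = 8)
  tab2 <- build_table(res2)
  vr_cols <- grep("VR_MI", names(tab2), value = TRUE)
  expect_length(vr_cols, 3L)
  expect_true(all(tab2[, vr_cols] == "-"))

  # significance marking at the 0.01 threshold
  res3 <- res[1, ]
  res3$p_value <- 0.005
  expect_match(build_table(res3)[[res3$pair]], "\\*")
  res3$p_value <- 0.02
  expect_no_match(build_table(res3)[[res3$pair]], "\\*")

  res_bad <- res3
  res_bad$pair <- "VOICE vs NAP"
  expect_error(build_table(res_bad), "unknown task pair")
})

test_that("an injected alpha gain is detected by the paired test", {
  reject <- vapply(1:10, function(s) {
    sim <- sim_config(
      n_channels = 18, sampling_rate = 200, trial_duration = 12,
      trials_per_task = c(VOICE = 1, VR_MI = 1),
      effect_gains = flat_gains(VR_MI.alpha = 1.5), seed = s
    )
    cfg <- pipeline_config(experiment = 1, sim = sim, trim = c(6, 12))
    cfg$tasks <- c("VOICE", "VR_MI")
    bp <- task_band_powers(cfg)$band_powers
    wilcoxon_pair(bp$VR_MI$alpha, bp$VOICE$alpha)$p_value < 0.01
  }, logical(1))
  expect_gte(sum(reject), 9L)
})
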
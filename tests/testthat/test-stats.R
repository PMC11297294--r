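test_that("identical groups give the identity case t = 0, p = 1", {
  r <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 4)
  # constant equal groups are the degenerate identity case too
  r2 <- t_test_independent(c(2, 2), c(2, 2))
  expect_equal(r2$t_statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_error(
    t_test_independent(c(2, 2), c(3, 3)),
    "Degenerate"
  )
})

test_that("a large shift is detected with the closed-form statistic", {
  r <- t_test_independent(c(11, 12, 13), c(1, 2, 3))
  expect_equal(r$t_statistic, 10 / sqrt(1 * (2 / 3)), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_lt(r$p_value, 0.001)
})

test_that("t-test agrees with the formula recomputed from scratch", {
  g1 <- c(5.1, 4.9, 5.0, 5.2)
  g2 <- c(5.6, 5.8, 5.5, 5.7)
  r <- t_test_independent(g1, g2)
  # independent second implementation straight from the definitions
  sp2 <- (3 * var(g1) + 3 * var(g2)) / 6
  t_manual <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$t_statistic, t_manual, tolerance = 1e-9)
  expect_equal(r$p_value, 2 * pt(-abs(t_manual), 6), tolerance = 1e-9)
  expect_equal(r$cohens_d, (mean(g1) - mean(g2)) / sqrt(sp2), tolerance = 1e-9)
  # group CIs use each group's own SE and critical value
  expect_equal(
    r$ci95_1,
    mean(g1) + c(-1, 1) * qt(0.975, 3) * sd(g1) / 2,
    tolerance = 1e-9
  )
  # and the whole thing matches stats::t.test as an independent cross-check
  ref <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(r$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("t-test p-value sits within Monte-Carlo error of a permutation oracle", {
  set.seed(99)
  g1 <- rnorm(8, 0.8)
  g2 <- rnorm(8, 0)
  r <- t_test_independent(g1, g2)
  pooled <- c(g1, g2)
  n_perm <- 4000
  tstat <- function(a, b) {
    sp2 <- (var(a) * (length(a) - 1) + var(b) * (length(b) - 1)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  exceed <- replicate(n_perm, {
    idx <- sample(16, 8)
    abs(tstat(pooled[idx], pooled[-idx])) >= abs(r$t_statistic)
  })
  p_perm <- mean(exceed)
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm) + 1e-3
  expect_lt(abs(r$p_value - p_perm), 4 * mc_se + 0.01)
})

test_that("Welch variant relaxes the equal-variance assumption", {
  set.seed(4)
  g1 <- rnorm(10, 0, 1)
  g2 <- rnorm(25, 0, 5)
  r <- t_test_independent(g1, g2, var_equal = FALSE)
  ref <- t.test(g1, g2)
  expect_equal(r$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("tidy and glance return one-row tibbles", {
  r <- t_test_independent(c(1, 2, 3), c(4, 5, 6))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$estimate, -3)
  expect_named(glance(r), c("statistic", "df", "p.value", "cohens_d"))
  expect_equal(nrow(tidy(pearson_correlation(1:5, c(2, 1, 4, 3, 5)))), 1)
  expect_equal(nrow(tidy(posthoc_power_t(0.5, 10, 10))), 1)
})

test_that("correlation handles exact, reversed and independent inputs", {
  r <- pearson_correlation(1:10, 2 * (1:10) + 1)
  expect_equal(r$r, 1, tolerance = 1e-12)
  r2 <- pearson_correlation(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r2$r, -1, tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(1000)
  y <- rnorm(1000)
  r3 <- pearson_correlation(x, y)
  expect_lt(abs(r3$r), 0.1)
  expect_equal(r3$n, 1000)
  # p-value matches the t transform
  r4 <- pearson_correlation(x[1:30], x[1:30] * 0.5 + rnorm(30))
  tt <- r4$r * sqrt((r4$n - 2) / (1 - r4$r^2))
  expect_equal(r4$p_value, 2 * pt(-abs(tt), r4$n - 2), tolerance = 1e-9)
})

test_that("degenerate correlations are flagged, not raised", {
  r <- pearson_correlation(rep(1, 5), 1:5)
  expect_true(is.na(r$r))
  expect_match(r$note, "constant")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
  # missing pairs are dropped before computing
  r2 <- pearson_correlation(c(1, 2, 3, NA), c(2, 4, 6, 1))
  expect_equal(r2$n, 3)
  expect_equal(r2$r, 1, tolerance = 1e-12)
})

test_that("spearman option ranks before correlating", {
  x <- c(1, 2, 3, 4, 100)
  y <- c(1, 4, 9, 16, 10000)
  expect_equal(pearson_correlation(x, y, method = "spearman")$r, 1)
})

test_that("power function satisfies the analytic anchors", {
  expect_equal(posthoc_power_t(0, 19, 19)$power, 0.05, tolerance = 1e-9)
  expect_gt(
    posthoc_power_t(0.8, 19, 19)$power,
    posthoc_power_t(0.3, 19, 19)$power
  )
  expect_gt(
    posthoc_power_t(0.5, 40, 40)$power,
    posthoc_power_t(0.5, 10, 10)$power
  )
  # equal-n case matches base power.t.test as an independent reference;
  # power.t.test drops the opposite-tail rejection term (~3e-4 here)
  ref <- power.t.test(n = 19, delta = 0.5, sd = 1, sig.level = 0.05)
  expect_equal(posthoc_power_t(0.5, 19, 19)$power, ref$power, tolerance = 2e-3)
  expect_gte(posthoc_power_t(0.5, 19, 19)$power, ref$power)
  expect_error(posthoc_power_t(0.5, 1, 10), "n >= 2")
  expect_error(posthoc_power_t(0.5, 10, 10, alpha = 0), "alpha")
})

test_that("headline report is deterministic and flags tiny arms", {
  exp <- generate_experiment(generator_config(
    n_participants = 4, trial_duration_s = 20, seed = 15
  ))
  res <- analyze_experiment(exp)
  beh <- behaviour_table(exp$trials)
  r1 <- headline_report(res$attention, beh, exp$trials)
  r2 <- headline_report(res$attention, beh, exp$trials)
  expect_identical(r1$comparisons, r2$comparisons)
  expect_identical(r1$correlations, r2$correlations)
  expect_match(r1$footer, "No multiple-testing adjustment")
  expect_true(all(c(
    "ai_screen_fixations", "xai_qdiff_fixations",
    "blink_rate_conventional_vs_ai"
  ) %in% r1$comparisons$comparison))

  # a single unsafe trial makes the safe/unsafe comparisons non-computable
  att1 <- res$attention
  one_unsafe <- unique(att1[att1$condition == "unsafe",
    c("participant_id", "scenario_id")
  ])[1, ]
  keep <- att1$condition == "safe" |
    (att1$participant_id == one_unsafe$participant_id &
      att1$scenario_id == one_unsafe$scenario_id)
  r3 <- headline_report(att1[keep, ], beh, exp$trials)
  ai <- r3$comparisons[r3$comparisons$comparison == "ai_screen_fixations" &
    r3$comparisons$level == "trial", ]
  expect_match(ai$note, "not computable")
  expect_true(is.na(ai$p.value))
})

test_that("report tables write to disk with the no-adjustment footer", {
  exp <- generate_experiment(generator_config(
    n_participants = 3, trial_duration_s = 15, seed = 16
  ))
  res <- analyze_experiment(exp)
  rep <- headline_report(res$attention, behaviour_table(exp$trials), exp$trials)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "comparisons.csv", "roi_metrics.csv", "chance_ratios.csv",
    "correlations.csv", "report_summary.md"
  )))))
  md <- readLines(file.path(dir, "report_summary.md"))
  expect_true(any(grepl("No multiple-testing adjustment", md)))
})
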
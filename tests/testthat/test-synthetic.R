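test_that("generated experiments have the study cardinality and design", {
  exp <- generate_experiment(generator_config(
    n_participants = 19, trial_duration_s = 2, seed = 1
  ))
  expect_equal(nrow(exp$trials), 228) # 19 x 6 x 2 drugs
  expect_equal(length(exp$gaze), 114)
  expect_equal(nrow(validate_design(exp$trials)), 0)
  per <- dplyr::count(
    dplyr::distinct(exp$trials, participant_id, scenario_id, condition),
    participant_id, condition
  )
  expect_true(all(per$n[per$condition == "safe"] == 4))
  expect_true(all(per$n[per$condition == "unsafe"] == 2))
})

test_that("seeded generation is bit-reproducible", {
  cfg <- generator_config(n_participants = 2, trial_duration_s = 5, seed = 77)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$gaze, e2$gaze)
  expect_identical(e1$tracks, e2$tracks)
  e3 <- generate_experiment(generator_config(
    n_participants = 2, trial_duration_s = 5, seed = 78
  ))
  expect_false(identical(e1$gaze[[1]], e3$gaze[[1]]))
})

test_that("a unit multiplier plants equal AI-screen attention across conditions", {
  cfg <- generator_config(
    n_participants = 6, trial_duration_s = 2, unsafe_ai_multiplier = 1,
    seed = 5
  )
  exp <- generate_experiment(cfg)
  att <- exp$ground_truth$attention
  ai <- att[att$roi_id == "ai_recommendation", ]
  # expected shares derive from the participant profile only: within a
  # participant, safe and unsafe trials get identical expectations
  agg <- dplyr::summarise(
    dplyr::group_by(ai, participant_id, condition),
    e = mean(expected_share), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg, names_from = condition, values_from = e)
  expect_equal(wide$safe, wide$unsafe, tolerance = 1e-12)
})

test_that("generator rejects invalid configurations before any output", {
  expect_error(
    generator_config(attention_shares = c(
      mannequin = -0.1, monitor = 0.3, chart = 0.2, ai_screen = 0.4,
      elsewhere = 0.2
    )),
    "non-negative"
  )
  expect_error(generator_config(trial_duration_s = 0), "positive")
  expect_error(generator_config(fluid_reference = c(1, 2)), "six scenarios")
  d <- withr::local_tempdir()
  expect_error(generate_experiment(list(seed = 1), dir = d), "generator_config")
  expect_false(file.exists(file.path(d, "trials.csv")))
})

test_that("uniform gaze has the advertised size, seed and box coverage", {
  g <- generate_uniform_gaze(100, 120, seed = 3)
  expect_equal(nrow(g), 12000)
  expect_identical(g, generate_uniform_gaze(100, 120, seed = 3))
  inside <- mean(g$x >= 0.4 & g$x < 0.6 & g$y >= 0.3 & g$y < 0.4)
  expect_lt(abs(inside - 0.02), 3 * sqrt(0.02 * 0.98 / 12000))
  f <- withr::local_tempfile(fileext = ".csv")
  generate_uniform_gaze(1, 120, seed = 4, path = f)
  expect_identical(
    readLines(f),
    {
      f2 <- withr::local_tempfile(fileext = ".csv")
      generate_uniform_gaze(1, 120, seed = 4, path = f2)
      readLines(f2)
    }
  )
})

test_that("detectors recover planted events at default thresholds", {
  exp <- generate_experiment(generator_config(
    n_participants = 2, trial_duration_s = 120, seed = 19
  ))
  for (key in names(exp$gaze)[1:4]) {
    g <- exp$gaze[[key]]
    gt <- exp$ground_truth[[key]]
    fx <- detect_fixations(g)
    st <- event_match_stats(gt$fixations, fx)
    expect_gte(st$recall, 0.95)
    expect_gte(st$precision, 0.95)
    bl <- detect_blinks(g)
    stb <- event_match_stats(gt$blinks, bl)
    if (nrow(gt$blinks)) {
      expect_gte(stb$recall, 0.95)
      expect_gte(stb$precision, 0.95)
    }
  }
})

test_that("pipeline recovers planted per-ROI structure over many trials", {
  # 34 participants x 6 one-minute trials = 204 trials
  cfg <- generator_config(n_participants = 34, trial_duration_s = 60, seed = 23)
  exp <- generate_experiment(cfg)
  res <- analyze_experiment(exp)
  att <- res$attention
  gt <- dplyr::bind_rows(
    lapply(names(exp$gaze), function(k) {
      cbind(key = k, exp$ground_truth[[k]]$per_roi)
    })
  )
  att$key <- paste0(att$participant_id, "_s", att$scenario_id)
  m <- dplyr::inner_join(att, gt, by = c("key", "roi_id"))
  expect_equal(nrow(m), 204 * 10) # 9 ROIs + elsewhere per trial
  for (roi in c("ai_screen", "chart", "monitor", "mannequin", "xai_qdiff")) {
    d <- m[m$roi_id == roi, ]
    # fixation counts: measured mean within 3 SE of the planted mean
    se <- sd(d$n_fixations) / sqrt(nrow(d))
    expect_lt(
      abs(mean(d$n_fixations) - mean(d$planted_fixations)), 3 * se + 1e-9
    )
    # blink rates, compared over the planted dwell so denominators match
    ok <- d$planted_dwell_ms > 0
    got_rate <- sum(d$blink_rate_bpm[ok] * d$gaze_time_ms[ok] / 60000,
      na.rm = TRUE
    ) / sum(d$planted_dwell_ms[ok]) * 60000
    want_rate <- sum(d$planted_blinks[ok]) / sum(d$planted_dwell_ms[ok]) * 60000
    n_blinks <- sum(d$planted_blinks[ok])
    se_rate <- want_rate / sqrt(max(n_blinks, 1))
    expect_lt(abs(got_rate - want_rate), 3 * se_rate + 1e-9)
  }
})

test_that("explanation panels rotate position between trials", {
  exp <- generate_experiment(generator_config(
    n_participants = 1, trial_duration_s = 2, seed = 31
  ))
  pos_of <- function(key) {
    tr <- exp$tracks[[key]]
    q <- tr[tr$roi_id == "xai_qdiff", ][1, ]
    c(q$x_min, q$y_min)
  }
  ord <- exp$trials[exp$trials$drug == "fluid", ]
  keys <- paste0("P01_s", ord$scenario_id[order(ord$order_index)])
  p1 <- pos_of(keys[1])
  p2 <- pos_of(keys[2])
  expect_false(isTRUE(all.equal(p1, p2, tolerance = 0.01)))
})
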
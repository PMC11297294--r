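test_that("box_at follows the zero-order-hold convention", {
  defs <- two_roi_defs()
  tracks <- dplyr::bind_rows(
    static_tracks(two_roi_boxes(), t = 100),
    static_tracks(two_roi_boxes(), t = 200)
  )
  tracks$x_min[tracks$t == 200 & tracks$roi_id == "chart"] <- 0.05

  b <- box_at(tracks, "chart", 200) # exactly at an observation
  expect_equal(b$x_min, 0.05)
  b <- box_at(tracks, "chart", 150) # between frames: earlier frame holds
  expect_equal(b$x_min, 0.0)
  b <- box_at(tracks, "chart", 50) # before the first frame
  expect_false(b$visible)
  expect_true(is.na(b$x_min))
  expect_error(box_at(tracks, "nope", 100), "nope")

  # invisible observations hide the box
  tracks$visible[tracks$t == 200 & tracks$roi_id == "chart"] <- FALSE
  expect_false(box_at(tracks, "chart", 250)$visible)
})

test_that("points are assigned to the smallest ROI plus its ancestors", {
  defs <- two_roi_defs()
  tracks <- static_tracks(two_roi_boxes())
  # inside the panel (child of screen): both ids
  expect_setequal(
    assign_point(0.6, 0.6, 10, tracks, defs)[[1]],
    c("panel", "screen")
  )
  # inside screen but outside the panel
  expect_equal(assign_point(0.52, 0.85, 10, tracks, defs)[[1]], "screen")
  # inside nothing
  expect_equal(length(assign_point(0.40, 0.45, 10, tracks, defs)[[1]]), 0)
})

test_that("overlapping siblings resolve by area then lexicographic roi_id", {
  defs <- roi_definitions(c("big", "s2", "s1"))
  boxes <- tibble::tibble(
    roi_id = c("big", "s2", "s1"),
    x_min = c(0.0, 0.4, 0.5), y_min = c(0, 0.4, 0.4),
    x_max = c(1.0, 0.6, 0.7), y_max = c(1, 0.6, 0.6)
  )
  tracks <- static_tracks(boxes)
  # point in both 0.2 x 0.2 siblings: tie on area -> lexicographically first
  expect_true("s1" %in% assign_point(0.55, 0.45, 0, tracks, defs)[[1]])
  expect_false("s2" %in% assign_point(0.55, 0.45, 0, tracks, defs)[[1]])
  # point only in s2
  expect_true("s2" %in% assign_point(0.45, 0.45, 0, tracks, defs)[[1]])
  # half-open boundary: the shared edge belongs to the box it opens
  expect_true("s1" %in% assign_point(0.5, 0.45, 0, tracks, defs)[[1]])
})

test_that("chance gaze proportion is the time-weighted clipped box area", {
  defs <- roi_definitions("roi")
  full <- static_tracks(tibble::tibble(
    roi_id = "roi", x_min = 0, y_min = 0, x_max = 1, y_max = 1
  ))
  expect_equal(chance_gaze_proportion(full, "roi", 1000), 1.0)

  small <- static_tracks(tibble::tibble(
    roi_id = "roi", x_min = 0.1, y_min = 0.2, x_max = 0.3, y_max = 0.3
  ))
  expect_equal(chance_gaze_proportion(small, "roi", 1000), 0.02)

  # visible half the trial at area 0.04 -> 0.02
  half <- tibble::tibble(
    t = c(0, 500), roi_id = "roi",
    x_min = 0.1, y_min = 0.1, x_max = 0.3, y_max = 0.3,
    visible = c(TRUE, FALSE)
  )
  expect_equal(chance_gaze_proportion(half, "roi", 1000), 0.02)

  # boxes sticking out of the world-view are clipped for area
  out <- static_tracks(tibble::tibble(
    roi_id = "roi", x_min = 0.9, y_min = 0, x_max = 1.3, y_max = 0.5
  ))
  expect_equal(chance_gaze_proportion(out, "roi", 1000), 0.05)
})

test_that("actual-to-chance ratio handles the documented cases", {
  expect_equal(actual_to_chance_ratio(0.25, 0.02), 12.5)
  expect_equal(actual_to_chance_ratio(0.3, 0.3), 1.0)
  expect_true(is.na(actual_to_chance_ratio(0.3, 0)))
  expect_error(actual_to_chance_ratio(-0.1, 0.2), "non-negative")
})

test_that("attention summary equals a brute-force per-sample tally", {
  defs <- two_roi_defs()
  boxes <- two_roi_boxes()
  tracks <- static_tracks(boxes)
  set.seed(42)
  g <- tibble::tibble(
    t = (0:19) * 10,
    x = runif(20), y = runif(20), confidence = 1
  )
  trial <- list(participant_id = "P01", scenario_id = 1L, condition = "safe")
  att <- summarize_attention(
    g, detect_fixations(g), detect_blinks(g), tracks, defs, trial
  )
  want <- tally_oracle(g, boxes, defs)
  for (id in names(want)) {
    expect_equal(
      att$gaze_time_ms[att$roi_id == id], unname(want[[id]]),
      tolerance = 1e-9, info = id
    )
  }
  expect_equal(sum(att$actual_gaze_proportion[
    att$roi_id %in% c("screen", "chart", "elsewhere")
  ]), 1, tolerance = 1e-9)
})

test_that("static single-ROI trial gives the textbook gaze time and blink rate", {
  defs <- roi_definitions("roi")
  tracks <- static_tracks(tibble::tibble(
    roi_id = "roi", x_min = 0.4, y_min = 0.4, x_max = 0.6, y_max = 0.6
  ))
  g <- constant_stream(60 * 120) # 60 s at the box centre
  # 12 planted blinks of 100 ms each
  for (k in 1:12) {
    g$confidence[(k * 500):(k * 500 + 11)] <- 0.1
  }
  fx <- detect_fixations(g)
  bl <- detect_blinks(g)
  expect_equal(nrow(bl), 12)
  att <- summarize_attention(
    g, fx, bl, tracks, defs,
    list(participant_id = "P01", scenario_id = 1L, condition = "safe")
  )
  roi <- att[att$roi_id == "roi", ]
  expect_equal(roi$gaze_time_ms, 60000, tolerance = 1e-9)
  expect_equal(roi$blink_rate_bpm, 12, tolerance = 1e-9)
  expect_equal(roi$actual_gaze_proportion, 1, tolerance = 1e-9)
  expect_equal(roi$chance_gaze_proportion, 0.04, tolerance = 1e-9)

  # no fixation centroids in an ROI -> zero count, missing duration
  empty <- att[att$roi_id == "roi", ]
  tracks2 <- static_tracks(tibble::tibble(
    roi_id = "roi", x_min = 0.8, y_min = 0.8, x_max = 0.9, y_max = 0.9
  ))
  att2 <- summarize_attention(
    g, fx, bl, tracks2, defs,
    list(participant_id = "P01", scenario_id = 1L, condition = "safe")
  )
  expect_equal(att2$n_fixations[att2$roi_id == "roi"], 0L)
  expect_true(is.na(att2$mean_fixation_duration_ms[att2$roi_id == "roi"]))
})

test_that("attention metrics are invariant to ROI track row order", {
  exp <- generate_experiment(generator_config(
    n_participants = 1, trial_duration_s = 20, seed = 9
  ))
  key <- names(exp$gaze)[1]
  g <- exp$gaze[[key]]
  tracks <- exp$tracks[[key]]
  trial <- exp$trials[1, ]
  fx <- detect_fixations(g)
  bl <- detect_blinks(g)
  a1 <- summarize_attention(g, fx, bl, tracks, exp$definitions, trial)
  set.seed(1)
  shuffled <- tracks[sample(nrow(tracks)), ]
  a2 <- summarize_attention(g, fx, bl, shuffled, exp$definitions, trial)
  expect_equal(as.data.frame(a1), as.data.frame(a2), tolerance = 1e-12)
})

test_that("parent gaze time brackets its children", {
  exp <- generate_experiment(generator_config(
    n_participants = 2, trial_duration_s = 30, seed = 11
  ))
  res <- analyze_experiment(exp)
  att <- res$attention
  leafs <- c(
    "ai_recommendation", "xai_qdiff", "xai_mortality",
    "xai_features", "xai_examples"
  )
  for (key in unique(paste(att$participant_id, att$scenario_id))) {
    a <- att[paste(att$participant_id, att$scenario_id) == key, ]
    parent <- a$gaze_time_ms[a$roi_id == "ai_screen"]
    kids <- a$gaze_time_ms[a$roi_id %in% leafs]
    expect_gte(parent + 1e-9, max(kids))
    expect_lte(parent, sum(kids) + 1e-9)
    # mutually exclusive top-level ROIs never exceed the trial duration
    top <- a$gaze_time_ms[a$roi_id %in% c(
      "mannequin", "monitor", "chart", "ai_screen", "elsewhere"
    )]
    expect_lte(sum(top), 30000 + 1000 / 120 + 1e-6)
  }
})
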
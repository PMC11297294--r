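test_that("influence of AI reproduces the endpoint and midpoint cases", {
  expect_equal(influence_of_ai(500, 200, 200), 1.0) # advice adopted
  expect_equal(influence_of_ai(500, 500, 200), 0.0) # advice ignored
  expect_equal(influence_of_ai(500, 350, 200), 0.5) # midpoint
  expect_true(is.na(influence_of_ai(200, 150, 200))) # degenerate denominator
  expect_true(is.na(influence_of_ai(200, 150, 200.5, epsilon = 1))) # within eps
  expect_error(influence_of_ai(-1, 0, 1), "non-negative")
})

test_that("influence clamps to [0, 1] only when asked", {
  # overshoot past the advice
  expect_equal(influence_of_ai(500, 100, 200, clamp = FALSE), 4 / 3)
  expect_equal(influence_of_ai(500, 100, 200, clamp = TRUE), 1)
  # movement away from the advice
  expect_equal(influence_of_ai(500, 600, 200, clamp = FALSE), -1 / 3)
  expect_equal(influence_of_ai(500, 600, 200, clamp = TRUE), 0)
})

test_that("influence is invariant to affine dose rescaling", {
  set.seed(13)
  for (i in 1:50) {
    p <- runif(1, 0, 500)
    a <- runif(1, 0, 500)
    f <- runif(1, 0, 500)
    if (abs(a - p) < 1) next
    sc <- runif(1, 0.1, 10)
    sh <- runif(1, 0, 100)
    expect_equal(
      influence_of_ai(sc * p + sh, sc * f + sh, sc * a + sh, clamp = FALSE),
      influence_of_ai(p, f, a, clamp = FALSE),
      tolerance = 1e-9
    )
  }
})

test_that("practice variation measures distance from the group mean", {
  expect_equal(practice_variation(c(100, 200, 300)), c(100, 0, 100))
  expect_equal(practice_variation(c(5, 5, 5, 5)), rep(0, 4))
  expect_equal(practice_variation(c(0, 100)), c(50, 50))
  expect_error(practice_variation(100), "at least 2")
  # leave-one-out variant excludes the own dose from the reference
  expect_equal(practice_variation(c(0, 100), leave_one_out = TRUE), c(100, 100))
  # total variation is minimal (zero) exactly when all doses agree
  set.seed(2)
  for (i in 1:20) {
    d <- runif(5, 0, 400)
    expect_gte(sum(practice_variation(d)), 0)
  }
  expect_equal(sum(practice_variation(rep(77, 5))), 0)
})

test_that("advice distance echoes the reported magnitudes", {
  expect_equal(advice_distance(200, 200), 0)
  expect_equal(advice_distance(371, 200), 171) # safe-condition fluid scale
  expect_equal(advice_distance(0.10, 0.40), 0.30) # unsafe vasopressor scale
})

test_that("behaviour_table computes all metrics per trial x drug", {
  exp <- generate_experiment(generator_config(
    n_participants = 19, trial_duration_s = 2, seed = 21
  ))
  beh <- behaviour_table(exp$trials)
  expect_equal(nrow(beh), 228)
  expect_true(all(beh$practice_variation >= 0))
  expect_true(all(beh$advice_distance >= 0))
  expect_true(all(is.na(beh$influence_raw) == !beh$influence_defined))
  expect_true(all(beh$influence_clamped >= 0 & beh$influence_clamped <= 1,
    na.rm = TRUE
  ))
  # practice variation matches a direct per-scenario computation
  one <- exp$trials[exp$trials$scenario_id == 3 & exp$trials$drug == "fluid", ]
  direct <- practice_variation(setNames(one$initial_dose, one$participant_id))
  got <- beh[beh$scenario_id == 3 & beh$drug == "fluid", ]
  expect_equal(
    got$practice_variation[match(names(direct), got$participant_id)],
    unname(direct)
  )
})

test_that("influence recovers the planted weight exactly at zero noise", {
  cfg <- generator_config(
    n_participants = 19, trial_duration_s = 2,
    baseline_sd = c(fluid = 0, vasopressor = 0),
    post_noise_sd = c(fluid = 0, vasopressor = 0),
    seed = 33
  )
  exp <- generate_experiment(cfg)
  beh <- behaviour_table(exp$trials)
  joined <- dplyr::inner_join(
    beh, exp$ground_truth$weights,
    by = c("participant_id", "scenario_id", "condition", "drug")
  )
  expect_equal(nrow(joined), 228)
  expect_true(all(joined$influence_defined))
  expect_equal(joined$influence_raw, joined$planted_w, tolerance = 1e-9)
})

test_that("joining behaviour and attention yields one row per trial x drug", {
  exp <- generate_experiment(generator_config(
    n_participants = 4, trial_duration_s = 20, seed = 8
  ))
  res <- analyze_experiment(exp)
  beh <- behaviour_table(exp$trials)
  joined <- join_behaviour_attention(beh, res$attention, exp$trials)
  expect_equal(nrow(joined), 4 * 6 * 2)
  expect_true(all(c(
    "n_fixations_ai_screen", "blink_rate_bpm_ai_screen",
    "rating_qdiff", "practice_variation"
  ) %in% names(joined)))
  expect_equal(nrow(qc_report(joined)$keys_behaviour_only), 0)

  # rows with undefined influence and missing ratings are kept, not dropped
  tr <- exp$trials
  tr$initial_dose[1] <- tr$ai_dose[1]
  tr$rating_qdiff[tr$participant_id == "P02"] <- NA_integer_
  beh2 <- behaviour_table(tr)
  joined2 <- join_behaviour_attention(beh2, res$attention, tr)
  expect_equal(nrow(joined2), 4 * 6 * 2)
  expect_true(any(!joined2$influence_defined))
  expect_true(all(is.na(joined2$rating_qdiff[joined2$participant_id == "P02"])))

  # one-sided keys are reported in the QC, not silently dropped
  part <- res$attention[res$attention$participant_id != "P01", ]
  joined3 <- join_behaviour_attention(beh, part, exp$trials)
  expect_equal(unique(qc_report(joined3)$keys_behaviour_only$participant_id), "P01")
})
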
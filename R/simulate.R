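leaf_rois <- c(
  "mannequin", "monitor", "chart", "ai_recommendation",
  "xai_qdiff", "xai_mortality", "xai_features", "xai_examples"
)

#' Synthetic-experiment generator configuration
#'
#' Defines the study conditions emulated by [generate_experiment()]: 19
#' participants, six sepsis scenarios per participant (four with a safe and
#' two with an unsafe AI recommendation, first trial always safe), 120 Hz
#' gaze sampling, 5.4-minute trials, saccade-fixation-blink gaze dynamics
#' over a simulation-suite ROI layout with joint head-motion drift, and an
#' advice-taking prescribing model with a planted weight on advice.
#'
#' Attention is modelled hierarchically. Each participant draws a stable
#' profile: shares over the major surfaces (mannequin, monitor, chart, AI
#' screen, elsewhere) from a Dirichlet with concentration
#' `participant_concentration`, and a within-AI-screen split (recommendation
#' panel plus four explanation panels) with concentration
#' `split_concentration`. Each trial re-draws both around the participant
#' profile (`trial_concentration`, `trial_split_concentration`). Under an
#' unsafe recommendation the expected AI-screen share is multiplied by
#' `unsafe_ai_multiplier` (non-AI shares rescale so the total stays 1), so
#' the planted ratio of expected AI-screen fixation counts between conditions
#' equals the multiplier.
#'
#' @param n_participants Number of physicians (default 19).
#' @param sample_rate_hz Gaze sampling rate (default 120).
#' @param trial_duration_s Trial length in seconds (default 324, i.e. the
#'   5.4-minute mean scenario completion time).
#' @param roi_frame_rate_hz ROI track frame rate (default 5).
#' @param head_motion_sd Per-frame SD of the joint random-walk drift applied
#'   to all ROI boxes (normalized units, default 0.003).
#' @param head_motion_max Drift is capped at this absolute offset (default
#'   0.04).
#' @param attention_shares Named expected shares over
#'   `mannequin, monitor, chart, ai_screen, elsewhere`; normalized to 1.
#' @param ai_screen_split Named expected split of AI-screen attention over
#'   `ai_recommendation` and the four explanation panels; normalized to 1.
#' @param participant_concentration,trial_concentration Dirichlet
#'   concentrations for the major shares at participant and trial level.
#' @param split_concentration,trial_split_concentration Same for the
#'   within-AI-screen split.
#' @param unsafe_ai_multiplier Multiplier on the expected AI-screen share
#'   under the unsafe condition (default 962/704).
#' @param fixation_mean_ms Named mean fixation duration per leaf ROI and
#'   `elsewhere` (ms).
#' @param fixation_sdlog Log-scale SD of the lognormal fixation durations.
#' @param fixation_min_ms Physiological floor on planted fixation durations.
#' @param fixation_jitter_sd Per-sample gaze jitter SD within a fixation.
#' @param saccade_gap_ms Range of inter-fixation saccade durations (ms).
#' @param blink_rate_bpm Named blink rate per leaf ROI and `elsewhere`
#'   (blinks per minute of dwell).
#' @param blink_duration_mean_ms,blink_duration_sdlog,blink_duration_range_ms
#'   Lognormal blink-duration model, truncated to the given range.
#' @param fluid_reference,vaso_reference Per-scenario consensus doses
#'   (ml/h; mcg/kg/min).
#' @param safe_advice_factor Safe AI advice = reference x this factor
#'   (named per drug).
#' @param unsafe_fluid_advice Unsafe fluid advice (extreme underdose,
#'   default 0 ml/h).
#' @param unsafe_vaso_extra Unsafe vasopressor advice = reference + this
#'   (extreme overdose, default 0.35 mcg/kg/min).
#' @param baseline_sd Named per-drug SD of the pre-reveal dose around the
#'   scenario reference.
#' @param advice_weight_beta List with `safe` and `unsafe` Beta(a, b)
#'   parameters for the planted weight on advice.
#' @param post_noise_sd Named per-drug SD of post-reveal prescription noise.
#' @param rating_mean,rating_sd Per-panel mean/SD of the 0-4 usefulness
#'   ratings (drawn once per participant, independent of attention by
#'   construction).
#' @param seed Integer seed; all randomness flows from it through
#'   per-participant substreams, so runs are bit-reproducible.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_participants = 19,
    sample_rate_hz = 120,
    trial_duration_s = 324,
    roi_frame_rate_hz = 5,
    head_motion_sd = 0.003,
    head_motion_max = 0.04,
    attention_shares = c(
      mannequin = 0.156, monitor = 0.225, chart = 0.144,
      ai_screen = 0.390, elsewhere = 0.085
    ),
    ai_screen_split = c(
      ai_recommendation = 0.574, xai_qdiff = 0.1065, xai_mortality = 0.1065,
      xai_features = 0.1065, xai_examples = 0.1065
    ),
    participant_concentration = 17,
    trial_concentration = 31,
    split_concentration = 50,
    trial_split_concentration = 28,
    unsafe_ai_multiplier = 962 / 704,
    fixation_mean_ms = c(
      mannequin = 135, monitor = 150, chart = 150, ai_recommendation = 150,
      xai_qdiff = 150, xai_mortality = 150, xai_features = 150,
      xai_examples = 150, elsewhere = 140
    ),
    fixation_sdlog = 0.3,
    fixation_min_ms = 90,
    fixation_jitter_sd = 0.003,
    saccade_gap_ms = c(30, 80),
    blink_rate_bpm = c(
      mannequin = 14.7, monitor = 15.2, chart = 6.1, ai_recommendation = 19.9,
      xai_qdiff = 19.9, xai_mortality = 19.9, xai_features = 19.9,
      xai_examples = 19.9, elsewhere = 12
    ),
    blink_duration_mean_ms = 150,
    blink_duration_sdlog = 0.25,
    blink_duration_range_ms = c(60, 450),
    fluid_reference = c(500, 250, 100, 300, 150, 400),
    vaso_reference = c(0.10, 0.15, 0.20, 0.25, 0.30, 0.40),
    safe_advice_factor = c(fluid = 1.25, vasopressor = 1.3),
    unsafe_fluid_advice = 0,
    unsafe_vaso_extra = 0.35,
    baseline_sd = c(fluid = 270, vasopressor = 0.05),
    advice_weight_beta = list(safe = c(2, 2), unsafe = c(1, 5)),
    post_noise_sd = c(fluid = 30, vasopressor = 0.02),
    rating_mean = c(qdiff = 3.2, mortality = 3.2, features = 3.2, examples = 1.4),
    rating_sd = c(qdiff = 1.0, mortality = 1.0, features = 1.0, examples = 1.3),
    seed = 1L) {
  cfg <- as.list(environment())
  if (any(attention_shares < 0) || any(ai_screen_split < 0)) {
    abort("Attention shares must be non-negative.")
  }
  if (any(blink_rate_bpm < 0)) abort("Blink rates must be non-negative.")
  if (length(fluid_reference) != 6 || length(vaso_reference) != 6) {
    abort("Reference doses must cover the six scenarios.")
  }
  if (trial_duration_s <= 0 || sample_rate_hz <= 0) {
    abort("Durations and rates must be positive.")
  }
  cfg$attention_shares <- attention_shares / sum(attention_shares)
  cfg$ai_screen_split <- ai_screen_split / sum(ai_screen_split)
  structure(cfg, class = "generator_config")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  x / sum(x)
}

# simulation-suite layout; the explanation panels rotate position by trial
scene_layout <- function(order_index = 1) {
  panels <- c("xai_qdiff", "xai_mortality", "xai_features", "xai_examples")
  rot <- (seq_along(panels) + order_index - 2) %% 4 + 1
  tibble::new_tibble(list(
    roi_id = c(
      "mannequin", "monitor", "chart", "ai_screen", "ai_recommendation",
      panels[rot]
    ),
    x_min = c(0.30, 0.05, 0.72, 0.60, 0.60, 0.60, 0.75, 0.60, 0.75),
    y_min = c(0.55, 0.10, 0.60, 0.05, 0.05, 0.11, 0.11, 0.18, 0.18),
    x_max = c(0.70, 0.23, 0.97, 0.90, 0.90, 0.75, 0.90, 0.75, 0.90),
    y_max = c(0.85, 0.20, 0.96, 0.25, 0.11, 0.18, 0.18, 0.25, 0.25)
  ), nrow = 9L)
}

# point in no (inflated) layout box, for "elsewhere" fixations
sample_elsewhere <- function(n, layout, inset) {
  x <- runif(n)
  y <- runif(n)
  for (i in 1:50) {
    inside <- rep(FALSE, n)
    for (j in seq_len(nrow(layout))) {
      inside <- inside | (x >= layout$x_min[j] - inset & x < layout$x_max[j] + inset &
        y >= layout$y_min[j] - inset & y < layout$y_max[j] + inset)
    }
    if (!any(inside)) break
    x[inside] <- runif(sum(inside))
    y[inside] <- runif(sum(inside))
  }
  cbind(x, y)
}

# one trial's gaze stream, ROI track and ground truth, given leaf weights
simulate_trial_stream <- function(weights, layout, cfg) {
  dur_ms <- cfg$trial_duration_s * 1000
  leaf_names <- c(leaf_rois, "elsewhere")
  # --- event schedule: fixation [+ blink] + saccade, repeated
  n_guess <- ceiling(dur_ms / 90) + 20
  rois <- sample(leaf_names, n_guess, replace = TRUE, prob = weights[leaf_names])
  mu <- log(cfg$fixation_mean_ms[rois]) - cfg$fixation_sdlog^2 / 2
  fix_dur <- pmax(cfg$fixation_min_ms, rlnorm(n_guess, mu, cfg$fixation_sdlog))
  sacc <- runif(n_guess, cfg$saccade_gap_ms[1], cfg$saccade_gap_ms[2])
  p_blink <- pmin(1, cfg$blink_rate_bpm[rois] / 60000 * fix_dur)
  has_blink <- runif(n_guess) < p_blink
  blink_dur <- numeric(n_guess)
  nb <- sum(has_blink)
  if (nb) {
    blink_dur[has_blink] <- pmin(
      cfg$blink_duration_range_ms[2],
      pmax(
        cfg$blink_duration_range_ms[1],
        rlnorm(
          nb,
          log(cfg$blink_duration_mean_ms) - cfg$blink_duration_sdlog^2 / 2,
          cfg$blink_duration_sdlog
        )
      )
    )
  }
  ends <- cumsum(fix_dur + blink_dur + sacc)
  k <- which(ends >= dur_ms)[1]
  if (is.na(k)) k <- n_guess # pathological config; stream simply runs short
  idx <- seq_len(k)
  rois <- rois[idx]
  fix_dur <- fix_dur[idx]
  sacc <- sacc[idx]
  has_blink <- has_blink[idx]
  blink_dur <- blink_dur[idx]
  fix_start <- c(0, ends[idx - 1])[seq_len(k)]
  blink_start <- fix_start + fix_dur
  sacc_start <- blink_start + blink_dur

  # --- fixation centroids in base scene coordinates
  inset <- 4 * cfg$fixation_jitter_sd
  cx <- numeric(k)
  cy <- numeric(k)
  for (r in unique(rois)) {
    sel <- which(rois == r)
    if (r == "elsewhere") {
      pts <- sample_elsewhere(length(sel), layout, inset)
      cx[sel] <- pts[, 1]
      cy[sel] <- pts[, 2]
    } else {
      b <- layout[layout$roi_id == r, ]
      cx[sel] <- runif(length(sel), b$x_min + inset, b$x_max - inset)
      cy[sel] <- runif(length(sel), b$y_min + inset, b$y_max - inset)
    }
  }

  # --- head-motion drift shared by boxes and gaze
  frame_dt <- 1000 / cfg$roi_frame_rate_hz
  n_frames <- ceiling(dur_ms / frame_dt) + 1
  hx <- pmax(pmin(cumsum(c(0, rnorm(n_frames - 1, 0, cfg$head_motion_sd))),
    cfg$head_motion_max
  ), -cfg$head_motion_max)
  hy <- pmax(pmin(cumsum(c(0, rnorm(n_frames - 1, 0, cfg$head_motion_sd))),
    cfg$head_motion_max
  ), -cfg$head_motion_max)
  frame_t <- (seq_len(n_frames) - 1) * frame_dt

  # --- samples
  n_samp <- floor(dur_ms * cfg$sample_rate_hz / 1000)
  t <- (seq_len(n_samp) - 1) * (1000 / cfg$sample_rate_hz)
  seg_fix <- findInterval(t, fix_start) # which cycle a sample falls in
  in_fix <- t < blink_start[seg_fix]
  in_blink <- !in_fix & t < sacc_start[seg_fix]
  # positions: fixation/blink hold the centroid; saccades interpolate
  x <- cx[seg_fix]
  y <- cy[seg_fix]
  sac <- !(in_fix | in_blink)
  if (any(sac)) {
    i <- seg_fix[sac]
    nxt <- pmin(i + 1, k)
    frac <- (t[sac] - sacc_start[i]) / sacc[i]
    x[sac] <- cx[i] + frac * (cx[nxt] - cx[i])
    y[sac] <- cy[i] + frac * (cy[nxt] - cy[i])
  }
  hold <- in_fix | in_blink
  x[hold] <- x[hold] + rnorm(sum(hold), 0, cfg$fixation_jitter_sd)
  y[hold] <- y[hold] + rnorm(sum(hold), 0, cfg$fixation_jitter_sd)
  fi <- findInterval(t, frame_t)
  x <- x + hx[fi]
  y <- y + hy[fi]
  confidence <- runif(n_samp, 0.85, 1)
  if (any(in_blink)) confidence[in_blink] <- runif(sum(in_blink), 0.05, 0.30)
  gaze <- tibble::new_tibble(
    list(t = t, x = x, y = y, confidence = confidence),
    nrow = n_samp
  )

  # --- ROI tracks: all boxes drift jointly, always visible
  n_box <- nrow(layout)
  tracks <- tibble::new_tibble(list(
    t = rep(frame_t, times = n_box),
    roi_id = rep(layout$roi_id, each = n_frames),
    x_min = rep(layout$x_min, each = n_frames) + rep(hx, n_box),
    y_min = rep(layout$y_min, each = n_frames) + rep(hy, n_box),
    x_max = rep(layout$x_max, each = n_frames) + rep(hx, n_box),
    y_max = rep(layout$y_max, each = n_frames) + rep(hy, n_box),
    visible = rep(TRUE, n_frames * n_box)
  ), nrow = n_frames * n_box)

  # --- ground truth (realized planted events and per-ROI tallies)
  fix_events <- tibble::new_tibble(list(
    onset_ms = fix_start, offset_ms = blink_start, duration_ms = fix_dur,
    roi_id = rois, centroid_x = cx, centroid_y = cy
  ), nrow = k)
  blink_events <- tibble::new_tibble(list(
    onset_ms = blink_start[has_blink],
    offset_ms = sacc_start[has_blink],
    duration_ms = blink_dur[has_blink],
    roi_id = rois[has_blink]
  ), nrow = sum(has_blink))
  tally <- function(v, by) {
    out <- setNames(rep(0, length(leaf_names)), leaf_names)
    s <- tapply(v, by, sum)
    out[names(s)] <- s
    out
  }
  n_fix <- tally(rep(1, k), rois)
  n_blink <- tally(as.numeric(has_blink), rois)
  dwell <- tally(fix_dur + blink_dur, rois)
  agg <- function(v) {
    c(
      v[c("mannequin", "monitor", "chart")],
      ai_screen = sum(v[setdiff(leaf_rois, c("mannequin", "monitor", "chart"))]),
      v[setdiff(leaf_names, c("mannequin", "monitor", "chart"))]
    )
  }
  per_roi <- tibble::tibble(
    roi_id = names(agg(n_fix)),
    planted_fixations = unname(agg(n_fix)),
    planted_blinks = unname(agg(n_blink)),
    planted_dwell_ms = unname(agg(dwell))
  )
  list(
    gaze = gaze, tracks = tracks,
    ground_truth = list(
      fixations = fix_events, blinks = blink_events, per_roi = per_roi
    )
  )
}

# per-trial leaf weights given participant profile and condition
trial_leaf_weights <- function(majors_p, split_p, condition, cfg) {
  majors <- majors_p
  if (condition == "unsafe") {
    target <- min(majors[["ai_screen"]] * cfg$unsafe_ai_multiplier, 0.95)
    rest <- 1 - majors[["ai_screen"]]
    majors[names(majors) != "ai_screen"] <-
      majors[names(majors) != "ai_screen"] * (1 - target) / rest
    majors[["ai_screen"]] <- target
  }
  majors_t <- setNames(
    rdirichlet1(cfg$trial_concentration * majors), names(majors)
  )
  split_t <- setNames(
    rdirichlet1(cfg$trial_split_concentration * split_p), names(split_p)
  )
  expected <- c(
    majors[c("mannequin", "monitor", "chart")],
    majors[["ai_screen"]] * split_p,
    elsewhere = majors[["elsewhere"]]
  )
  realized <- c(
    majors_t[c("mannequin", "monitor", "chart")],
    majors_t[["ai_screen"]] * split_t,
    elsewhere = majors_t[["elsewhere"]]
  )
  list(expected = expected, realized = realized,
       expected_ai_screen = unname(majors[["ai_screen"]]))
}

#' Generate a complete seeded synthetic experiment
#'
#' Emits, per participant, a permuted six-trial session (first trial safe,
#' four safe + two unsafe overall), and per trial a 120 Hz gaze stream built
#' as alternating fixations and saccades with blinks inserted as
#' pupil-confidence dips in the inter-fixation gaps, a moving ROI box track,
#' and pre/post-reveal prescriptions following
#' `final = initial + w x (advice - initial) + noise` with the planted weight
#' `w` drawn per trial and drug. Ground truth (planted events, per-ROI
#' tallies, planted weights and expected attention shares) is returned for
#' every trial.
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory; when given, the experiment is
#'   written to disk (`trials.csv`, `roi_definitions.yaml`, `config.yaml`,
#'   `ground_truth.json`, and per-trial `gaze/` and `tracks/` CSVs).
#' @return Invisibly when `dir` is given, otherwise a list:
#'   `trials` (tibble, one row per trial x drug), `gaze` and `tracks` (named
#'   lists of tibbles keyed `<participant>_s<scenario>`), `ground_truth`
#'   (named list per trial plus `$weights` tibble of planted advice weights
#'   and `$attention` tibble of expected/realized shares), `definitions`,
#'   and `config`.
#' @export
generate_experiment <- function(config = generator_config(), dir = NULL) {
  cfg <- config
  if (!inherits(cfg, "generator_config")) abort("config must be a generator_config().")
  definitions <- default_roi_definitions()
  set.seed(cfg$seed)
  participant_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_participants)
  pids <- sprintf("P%02d", seq_len(cfg$n_participants))
  seniority_pool <- c("consultant", "SpR", "SHO")

  gaze <- list()
  tracks <- list()
  gt <- list()
  n_trials <- cfg$n_participants * 6L
  # flat accumulators (one tibble() per experiment, not per trial)
  tr <- list(
    participant_id = character(2 * n_trials), scenario_id = integer(2 * n_trials),
    condition = character(2 * n_trials), order_index = integer(2 * n_trials),
    drug = character(2 * n_trials), initial_dose = numeric(2 * n_trials),
    final_dose = numeric(2 * n_trials), ai_dose = numeric(2 * n_trials),
    rating_qdiff = integer(2 * n_trials), rating_mortality = integer(2 * n_trials),
    rating_features = integer(2 * n_trials), rating_examples = integer(2 * n_trials),
    seniority = character(2 * n_trials)
  )
  planted_w <- numeric(2 * n_trials)
  att <- list(
    participant_id = character(), scenario_id = integer(), condition = character(),
    roi_id = character(), expected_share = numeric(), realized_share = numeric()
  )
  row <- 0L

  for (p in seq_len(cfg$n_participants)) {
    set.seed(participant_seeds[p])
    pid <- pids[p]
    seniority <- sample(seniority_pool, 1, prob = c(0.2, 0.4, 0.4))
    # condition assignment and order: 2 unsafe scenarios, first trial safe
    unsafe_scen <- sample(1:6, 2)
    cond_of <- ifelse(1:6 %in% unsafe_scen, "unsafe", "safe")
    repeat {
      ord <- sample(1:6) # ord[i] = scenario at position i
      if (cond_of[ord[1]] == "safe") break
    }
    # stable attention profile
    majors_p <- setNames(
      rdirichlet1(cfg$participant_concentration * cfg$attention_shares),
      names(cfg$attention_shares)
    )
    split_p <- setNames(
      rdirichlet1(cfg$split_concentration * cfg$ai_screen_split),
      names(cfg$ai_screen_split)
    )
    ratings <- as.integer(round(pmin(4, pmax(0, rnorm(4, cfg$rating_mean, cfg$rating_sd)))))

    for (pos in 1:6) {
      scen <- ord[pos]
      cond <- cond_of[scen]
      w <- trial_leaf_weights(majors_p, split_p, cond, cfg)
      layout <- scene_layout(order_index = pos)
      sim <- simulate_trial_stream(w$realized, layout, cfg)
      key <- paste0(pid, "_s", scen)
      gaze[[key]] <- sim$gaze
      tracks[[key]] <- sim$tracks
      gt[[key]] <- sim$ground_truth
      nw <- length(w$expected)
      att$participant_id <- c(att$participant_id, rep(pid, nw))
      att$scenario_id <- c(att$scenario_id, rep(scen, nw))
      att$condition <- c(att$condition, rep(cond, nw))
      att$roi_id <- c(att$roi_id, names(w$expected))
      att$expected_share <- c(att$expected_share, unname(w$expected))
      att$realized_share <- c(att$realized_share, unname(w$realized))

      # prescriptions
      for (drug in c("fluid", "vasopressor")) {
        ref <- if (drug == "fluid") {
          cfg$fluid_reference[scen]
        } else {
          cfg$vaso_reference[scen]
        }
        advice <- if (cond == "safe") {
          ref * cfg$safe_advice_factor[[drug]]
        } else if (drug == "fluid") {
          cfg$unsafe_fluid_advice
        } else {
          ref + cfg$unsafe_vaso_extra
        }
        initial <- max(0, ref + rnorm(1, 0, cfg$baseline_sd[[drug]]))
        ab <- cfg$advice_weight_beta[[cond]]
        wt <- rbeta(1, ab[1], ab[2])
        final <- max(0, initial + wt * (advice - initial) +
          rnorm(1, 0, cfg$post_noise_sd[[drug]]))
        row <- row + 1L
        tr$participant_id[row] <- pid
        tr$scenario_id[row] <- scen
        tr$condition[row] <- cond
        tr$order_index[row] <- pos
        tr$drug[row] <- drug
        tr$initial_dose[row] <- initial
        tr$final_dose[row] <- final
        tr$ai_dose[row] <- advice
        tr$rating_qdiff[row] <- ratings[1]
        tr$rating_mortality[row] <- ratings[2]
        tr$rating_features[row] <- ratings[3]
        tr$rating_examples[row] <- ratings[4]
        tr$seniority[row] <- seniority
        planted_w[row] <- wt
      }
    }
  }

  trials <- tibble::as_tibble(tr)
  exp <- list(
    trials = trials,
    gaze = gaze,
    tracks = tracks,
    ground_truth = c(gt, list(
      weights = tibble::tibble(
        participant_id = tr$participant_id, scenario_id = tr$scenario_id,
        condition = tr$condition, drug = tr$drug, planted_w = planted_w
      ),
      attention = tibble::as_tibble(att)
    )),
    definitions = definitions,
    config = cfg
  )
  if (is.null(dir)) {
    return(exp)
  }
  write_experiment(exp, dir)
  invisible(exp)
}

# write a generated experiment as the canonical CSV/YAML/JSON tree
write_experiment <- function(exp, dir) {
  dir.create(file.path(dir, "gaze"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE, recursive = TRUE)
  write_trials(exp$trials, file.path(dir, "trials.csv"))
  write_roi_definitions(exp$definitions, file.path(dir, "roi_definitions.yaml"))
  for (key in names(exp$gaze)) {
    write_gaze_stream(exp$gaze[[key]], file.path(dir, "gaze", paste0(key, ".csv")))
    write_roi_tracks(exp$tracks[[key]], file.path(dir, "tracks", paste0(key, ".csv")))
  }
  cfg <- exp$config
  yaml::write_yaml(
    lapply(unclass(cfg), function(x) if (is.list(x)) x else unname(x)),
    file.path(dir, "config.yaml")
  )
  jsonlite::write_json(
    exp$ground_truth, file.path(dir, "ground_truth.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}

#' Uniform-gaze stream (chance-gaze oracle input)
#'
#' Samples i.i.d. uniform over the unit square at full confidence — the
#' baseline under which every ROI's actual-to-chance gaze ratio is 1.
#'
#' @param duration_s Stream length in seconds.
#' @param sample_rate_hz Sampling rate.
#' @param seed Integer seed.
#' @param path Optional CSV output path.
#' @return The gaze tibble (`t, x, y, confidence`).
#' @examples
#' g <- generate_uniform_gaze(10, 120, seed = 1)
#' nrow(g)
#' @export
generate_uniform_gaze <- function(duration_s, sample_rate_hz, seed, path = NULL) {
  if (duration_s <= 0 || sample_rate_hz <= 0) {
    abort("duration_s and sample_rate_hz must be positive.")
  }
  set.seed(seed)
  n <- floor(duration_s * sample_rate_hz)
  out <- tibble::tibble(
    t = (seq_len(n) - 1) * (1000 / sample_rate_hz),
    x = runif(n),
    y = runif(n),
    confidence = 1
  )
  if (!is.null(path)) write_gaze_stream(out, path)
  out
}

#' Match detected events against planted ground truth
#'
#' Two events match when they overlap in time by at least half the shorter
#' event's duration. Used to score detector recall (planted events matched)
#' and precision (detected events matched) on synthetic streams.
#'
#' @param planted,detected Event tibbles with `onset_ms` and `offset_ms`.
#' @return A list with `recall`, `precision`, `n_planted`, `n_detected`.
#' @export
event_match_stats <- function(planted, detected) {
  if (!nrow(planted) || !nrow(detected)) {
    return(list(
      recall = if (nrow(planted)) 0 else NA_real_,
      precision = if (nrow(detected)) 0 else NA_real_,
      n_planted = nrow(planted), n_detected = nrow(detected)
    ))
  }
  matched_p <- logical(nrow(planted))
  matched_d <- logical(nrow(detected))
  j <- 1
  for (i in seq_len(nrow(planted))) {
    while (j <= nrow(detected) && detected$offset_ms[j] < planted$onset_ms[i]) {
      j <- j + 1
    }
    jj <- j
    while (jj <= nrow(detected) && detected$onset_ms[jj] <= planted$offset_ms[i]) {
      ov <- min(planted$offset_ms[i], detected$offset_ms[jj]) -
        max(planted$onset_ms[i], detected$onset_ms[jj])
      shorter <- min(
        planted$offset_ms[i] - planted$onset_ms[i],
        detected$offset_ms[jj] - detected$onset_ms[jj]
      )
      if (ov >= 0.5 * shorter) {
        matched_p[i] <- TRUE
        matched_d[jj] <- TRUE
      }
      jj <- jj + 1
    }
  }
  list(
    recall = mean(matched_p), precision = mean(matched_d),
    n_planted = nrow(planted), n_detected = nrow(detected)
  )
}
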
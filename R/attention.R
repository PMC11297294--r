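#' Bounding box of an ROI at a time point
#'
#' ROI boxes are sampled at video frame times; between frames the most recent
#' observation at or before the query time applies (zero-order hold). Before
#' the first observation, or when the held observation is flagged invisible,
#' the ROI is not visible.
#'
#' @param tracks ROI track tibble (see [read_roi_tracks()]).
#' @param roi_id Single ROI identifier present in `tracks`.
#' @param t Numeric vector of query times (ms).
#' @return A tibble with one row per query time: `t, x_min, y_min, x_max,
#'   y_max, visible`. Box fields are `NA` when not visible.
#' @export
box_at <- function(tracks, roi_id, t) {
  obs <- tracks[tracks$roi_id == roi_id, ]
  if (!nrow(obs)) abort(paste0("No track observations for roi_id '", roi_id, "'."))
  obs <- obs[order(obs$t), ]
  idx <- findInterval(t, obs$t)
  vis <- idx >= 1
  idx[!vis] <- 1L # placeholder, masked below
  vis <- vis & obs$visible[idx]
  tibble::tibble(
    t = t,
    x_min = ifelse(vis, obs$x_min[idx], NA_real_),
    y_min = ifelse(vis, obs$y_min[idx], NA_real_),
    x_max = ifelse(vis, obs$x_max[idx], NA_real_),
    y_max = ifelse(vis, obs$y_max[idx], NA_real_),
    visible = vis
  )
}

# per-ROI track columns, ordered by roi_id then time, for the scan kernel
split_tracks <- function(tracks, ids) {
  lapply(ids, function(id) {
    o <- tracks[tracks$roi_id == id, ]
    o <- o[order(o$t), ]
    list(
      t = o$t, x_min = o$x_min, y_min = o$y_min,
      x_max = o$x_max, y_max = o$y_max, visible = o$visible
    )
  })
}

# Smallest-area visible ROI containing each point (half-open boxes:
# x_min <= x < x_max, y_min <= y < y_max). Ties on area go to the
# lexicographically smallest roi_id. Returns a character vector, NA when the
# point is inside no visible ROI.
assign_smallest <- function(x, y, t, tracks, definitions, split = NULL) {
  ids <- sort(definitions$roi_id)
  if (is.null(split)) split <- split_tracks(tracks, ids)
  ord <- order(t)
  idx <- assign_min_area_scan(t[ord], x[ord], y[ord], split)
  hit <- idx > 0
  picked <- rep(NA_character_, length(t))
  picked[hit] <- ids[idx[hit]]
  out <- rep(NA_character_, length(t))
  out[ord] <- picked
  out
}

#' Assign a gaze point to hierarchical ROIs
#'
#' A point is assigned to the smallest-area visible ROI containing it plus all
#' of that ROI's ancestors, so gaze on an explanation panel also counts as
#' gaze on the enclosing AI screen. Containment is half-open
#' (`x_min <= x < x_max`) so abutting panels partition the screen. Area ties
#' go to the lexicographically smallest `roi_id`.
#'
#' @param x,y Normalized world-view coordinates (vectors of equal length).
#' @param t Query times in ms.
#' @param tracks ROI track tibble.
#' @param definitions `roi_definitions` tibble (a forest).
#' @return A list, one character vector of roi_ids per point (empty when the
#'   point lies inside no visible ROI).
#' @examples
#' \dontrun{
#' assign_point(0.8, 0.8, 1000, tracks, default_roi_definitions())
#' }
#' @export
assign_point <- function(x, y, t, tracks, definitions) {
  definitions <- validate_roi_definitions(definitions)
  smallest <- assign_smallest(x, y, t, tracks, definitions)
  anc <- roi_ancestors(definitions)
  lapply(smallest, function(id) {
    if (is.na(id)) character() else c(id, anc[[id]])
  })
}

#' Chance ("visual real-estate") gaze proportion of an ROI
#'
#' The gaze proportion an ROI would receive from gaze falling uniformly over
#' the world-view: the time-weighted mean, across the trial span, of the ROI
#' box area clipped to the unit square, counting zero while the ROI is not
#' visible.
#'
#' @param tracks ROI track tibble.
#' @param roi_id Single ROI identifier.
#' @param trial_span Either a single number (trial runs 0..span ms) or a
#'   length-2 vector `c(start, end)`.
#' @return Proportion in \[0, 1\].
#' @examples
#' \dontrun{
#' chance_gaze_proportion(tracks, "monitor", 324000)
#' }
#' @export
chance_gaze_proportion <- function(tracks, roi_id, trial_span) {
  if (length(trial_span) == 1) trial_span <- c(0, trial_span)
  span <- diff(trial_span)
  if (!is.finite(span) || span <= 0) abort("trial_span must be positive.")
  obs <- tracks[tracks$roi_id == roi_id, ]
  if (!nrow(obs)) abort(paste0("No track observations for roi_id '", roi_id, "'."))
  obs <- obs[order(obs$t), ]
  a <- pmax(0, pmin(obs$x_max, 1) - pmax(obs$x_min, 0)) *
    pmax(0, pmin(obs$y_max, 1) - pmax(obs$y_min, 0))
  a[!obs$visible] <- 0
  # piecewise-constant area over [start, end]; zero before the first frame
  keep <- obs$t < trial_span[2]
  tt <- pmax(obs$t[keep], trial_span[1])
  aa <- a[keep]
  if (!length(tt)) return(0)
  # hold the pre-start frame value from the start of the span
  before <- tt <= trial_span[1]
  if (any(before)) {
    i0 <- max(which(before))
    tt <- c(trial_span[1], tt[!before])
    aa <- c(aa[i0], aa[!before])
  }
  dt <- diff(c(tt, trial_span[2]))
  sum(aa * dt) / span
}

#' Ratio of actual to chance gaze
#'
#' @param actual Observed gaze proportion(s) in \[0, 1\].
#' @param chance Chance gaze proportion(s) in \[0, 1\].
#' @return `actual / chance`; `NA` where `chance` is zero. A ratio of 1 means
#'   the ROI draws exactly the attention its visual real-estate predicts.
#' @examples
#' actual_to_chance_ratio(0.25, 0.02)
#' @export
actual_to_chance_ratio <- function(actual, chance) {
  if (any(actual < 0, na.rm = TRUE) || any(chance < 0, na.rm = TRUE)) {
    abort("Proportions must be non-negative.")
  }
  ifelse(chance > 0, actual / chance, NA_real_)
}

#' Per-trial, per-ROI attention summary
#'
#' Computes the four attention metrics per ROI — gaze time, fixation count,
#' mean fixation duration, blink rate — together with the actual and chance
#' gaze proportions and their ratio. Gaze time sums each sample's interval to
#' the next sample (capped at twice the nominal period, so tracking dropouts
#' do not inflate dwell); fixations are attributed by their centroid at the
#' fixation's temporal midpoint; blinks by the last confident gaze point
#' before onset. Gaze attributed to a child ROI also counts towards its
#' ancestors. The per-ROI blink-rate denominator is the ROI's own gaze time
#' (rates are then comparable across ROIs of different dwell). Samples inside
#' no ROI accumulate in an implicit `elsewhere` row so proportions are
#' well-defined.
#'
#' @param samples Gaze tibble (`t, x, y, confidence`).
#' @param fixations Tibble from [detect_fixations()].
#' @param blinks Tibble from [detect_blinks()].
#' @param tracks ROI track tibble.
#' @param definitions `roi_definitions` tibble.
#' @param trial A one-trial slice of the trials table (or a list) supplying
#'   `participant_id`, `scenario_id`, `condition`.
#' @return A tibble, one row per ROI plus `elsewhere`:
#'   `participant_id, scenario_id, condition, roi_id, gaze_time_ms,
#'   n_fixations, mean_fixation_duration_ms, blink_rate_bpm,
#'   actual_gaze_proportion, chance_gaze_proportion, actual_to_chance_ratio`.
#'   A QC attribute notes blinks that could not be attributed and ROIs with
#'   blinks but zero gaze time.
#' @export
summarize_attention <- function(samples, fixations, blinks, tracks,
                                definitions, trial) {
  definitions <- validate_roi_definitions(definitions)
  if (!nrow(samples)) abort("No gaze samples.")
  stopifnot_sorted(samples$t, "gaze samples")
  trial <- as.list(dplyr::distinct(
    tibble::as_tibble(trial[c("participant_id", "scenario_id", "condition")])
  ))
  ids <- definitions$roi_id
  anc <- roi_ancestors(definitions)
  # members(roi) = roi plus all descendants
  members <- lapply(ids, function(id) {
    c(id, ids[purrr::map_lgl(anc[ids], function(a) id %in% a)])
  })
  names(members) <- ids

  t <- samples$t
  period <- if (length(t) > 1) median(diff(t)) else 1
  dt <- c(pmin(diff(t), 2 * period), period)
  exposure <- sum(dt)
  span <- c(t[1], t[length(t)] + period)

  split <- split_tracks(tracks, sort(ids))
  smallest <- assign_smallest(samples$x, samples$y, t, tracks, definitions,
    split = split
  )
  smallest[is.na(smallest)] <- "elsewhere"
  leaf_time <- rowsum(dt, smallest)
  time_of <- function(id) {
    m <- intersect(members[[id]], rownames(leaf_time))
    sum(leaf_time[m, 1])
  }
  gaze_time <- vapply(ids, time_of, numeric(1), USE.NAMES = FALSE)
  elsewhere_time <- if ("elsewhere" %in% rownames(leaf_time)) {
    leaf_time["elsewhere", 1]
  } else {
    0
  }

  # fixations: centroid at temporal midpoint
  if (nrow(fixations)) {
    mid <- (fixations$onset_ms + fixations$offset_ms) / 2
    fx <- assign_smallest(
      fixations$centroid_x, fixations$centroid_y, mid, tracks, definitions,
      split = split
    )
    n_fix <- integer(length(ids))
    mean_dur <- rep(NA_real_, length(ids))
    for (j in seq_along(ids)) {
      sel <- fx %in% members[[ids[j]]]
      n_fix[j] <- sum(sel)
      if (n_fix[j]) mean_dur[j] <- mean(fixations$duration_ms[sel])
    }
  } else {
    n_fix <- rep(0L, length(ids))
    mean_dur <- rep(NA_real_, length(ids))
  }

  # blinks: attributed via the last confident gaze point before onset
  qc <- list(n_blinks_unattributed = 0L, notes = character())
  if (nrow(blinks)) {
    ok <- !is.na(blinks$last_good_x)
    qc$n_blinks_unattributed <- sum(!ok)
    bx <- rep(NA_character_, nrow(blinks))
    if (any(ok)) {
      bx[ok] <- assign_smallest(
        blinks$last_good_x[ok], blinks$last_good_y[ok], blinks$onset_ms[ok],
        tracks, definitions,
        split = split
      )
    }
    n_blink <- vapply(
      ids, function(id) sum(bx %in% members[[id]]), integer(1),
      USE.NAMES = FALSE
    )
  } else {
    n_blink <- rep(0L, length(ids))
  }
  blink_rate <- ifelse(gaze_time > 0, n_blink / gaze_time * 60000, NA_real_)
  zero_dwell <- gaze_time == 0 & n_blink > 0
  if (any(zero_dwell)) {
    qc$notes <- c(qc$notes, paste0(
      "blinks attributed to ROI(s) with zero gaze time: ",
      paste(ids[zero_dwell], collapse = ", ")
    ))
  }

  chance <- vapply(
    ids, function(id) chance_gaze_proportion(tracks, id, span), numeric(1),
    USE.NAMES = FALSE
  )
  actual <- gaze_time / exposure

  nr <- length(ids) + 1L
  out <- tibble::new_tibble(list(
    participant_id = rep(trial$participant_id, nr),
    scenario_id = rep(trial$scenario_id, nr),
    condition = rep(trial$condition, nr),
    roi_id = c(ids, "elsewhere"),
    gaze_time_ms = unname(c(gaze_time, elsewhere_time)),
    n_fixations = unname(c(n_fix, NA_integer_)),
    mean_fixation_duration_ms = unname(c(mean_dur, NA_real_)),
    blink_rate_bpm = unname(c(blink_rate, NA_real_)),
    actual_gaze_proportion = unname(c(actual, elsewhere_time / exposure)),
    chance_gaze_proportion = unname(c(chance, NA_real_)),
    actual_to_chance_ratio = unname(
      c(actual_to_chance_ratio(actual, chance), NA_real_)
    )
  ), nrow = nr)
  set_qc(out, qc)
}

#' Write attention summaries to CSV
#'
#' @param attention Attention summary tibble (rows from
#'   [summarize_attention()], possibly several trials bound together).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attention <- function(attention, path) {
  readr::write_csv(attention, path, progress = FALSE)
  invisible(path)
}
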
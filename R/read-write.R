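#' Read a gaze-sample stream
#'
#' Reads one trial's gaze samples: one row per sample with session-relative
#' timestamp, normalized world-view coordinates (origin top-left, x rightward,
#' y downward, world-view = unit square) and pupil-detection confidence in
#' \[0, 1\]. Coordinates may fall outside the unit square (gaze off-world);
#' they are preserved, never clipped. Samples below `min_confidence` are
#' flagged in the QC report but never dropped — blink detection needs them.
#'
#' @param path CSV with columns `t_ms,x_norm,y_norm,confidence`.
#' @param min_confidence Confidence below which a sample is flagged
#'   low-confidence (default 0.6).
#' @param time_unit Unit of the time column: `"ms"` (default) or `"s"`
#'   (converted to milliseconds at ingest).
#' @return A tibble with columns `t, x, y, confidence`, sorted by `t` with
#'   duplicate timestamps collapsed to the last record. The QC report
#'   (see [qc_report()]) counts rows read, low-confidence rows, off-world
#'   rows, duplicates collapsed, and whether reordering was needed.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("t_ms,x_norm,y_norm,confidence", "0,0.5,0.5,1", "8,0.5,0.5,1"), f)
#' g <- read_gaze_stream(f)
#' qc_report(g)$rows_read
#' @export
read_gaze_stream <- function(path, min_confidence = 0.6, time_unit = c("ms", "s")) {
  time_unit <- match.arg(time_unit)
  raw <- read_csv_strict(path, c("t_ms", "x_norm", "y_norm", "confidence"), "gaze")
  out <- tibble::tibble(
    t = as.numeric(raw$t_ms) * if (time_unit == "s") 1000 else 1,
    x = as.numeric(raw$x_norm),
    y = as.numeric(raw$y_norm),
    confidence = as.numeric(raw$confidence)
  )
  if (any(out$confidence < 0 | out$confidence > 1, na.rm = TRUE)) {
    abort("confidence must lie in [0, 1].")
  }
  rows_read <- nrow(out)
  reordered <- is.unsorted(out$t)
  # stable sort, then collapse duplicate timestamps keeping the LAST record
  ord <- order(out$t) # order() is stable
  out <- out[ord, ]
  dup <- duplicated(out$t, fromLast = TRUE)
  n_dup <- sum(dup)
  out <- out[!dup, ]
  qc <- list(
    rows_read = rows_read,
    rows_kept = nrow(out),
    n_low_confidence = sum(out$confidence < min_confidence),
    n_off_world = sum(out$x < 0 | out$x > 1 | out$y < 0 | out$y > 1),
    n_duplicate_t = n_dup,
    reordered = reordered,
    min_confidence = min_confidence
  )
  if (reordered) {
    qc$notes <- "timestamps were not monotone in the file; samples re-sorted (stable)"
  }
  set_qc(out, qc)
}

#' Write a gaze-sample stream
#'
#' Inverse of [read_gaze_stream()]; numeric values round-trip exactly.
#'
#' @param samples Tibble with columns `t, x, y, confidence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_stream <- function(samples, path) {
  readr::write_csv(
    tibble::tibble(
      t_ms = samples$t, x_norm = samples$x,
      y_norm = samples$y, confidence = samples$confidence
    ),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read ROI track streams
#'
#' One row per (frame time, ROI): the ROI's bounding box in normalized
#' world-view coordinates plus a visibility flag. Between frames the box is
#' held (zero-order hold, see [box_at()]). When `visible` is false the box
#' fields are ignored and may be empty.
#'
#' @param path CSV with columns
#'   `t_ms,roi_id,x_min,y_min,x_max,y_max,visible`.
#' @param definitions A `roi_definitions` tibble; every `roi_id` in the file
#'   must appear there.
#' @return A tibble sorted by `roi_id`, then `t`.
#' @export
read_roi_tracks <- function(path, definitions) {
  definitions <- validate_roi_definitions(definitions)
  raw <- read_csv_strict(
    path, c("t_ms", "roi_id", "x_min", "y_min", "x_max", "y_max", "visible"),
    "ROI track"
  )
  out <- tibble::tibble(
    t = as.numeric(raw$t_ms),
    roi_id = as.character(raw$roi_id),
    x_min = as.numeric(raw$x_min),
    y_min = as.numeric(raw$y_min),
    x_max = as.numeric(raw$x_max),
    y_max = as.numeric(raw$y_max),
    visible = as.logical(raw$visible)
  )
  unknown <- setdiff(out$roi_id, definitions$roi_id)
  if (length(unknown)) {
    abort(paste0(
      "ROI track file contains roi_id(s) absent from definitions: ",
      paste(unknown, collapse = ", ")
    ))
  }
  bad <- which(out$visible &
    (out$x_min > out$x_max | out$y_min > out$y_max))
  if (length(bad)) {
    abort(paste0(
      "Degenerate box (min > max) in ROI track rows: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  dplyr::arrange(out, .data$roi_id, .data$t)
}

#' Write ROI tracks
#'
#' @param tracks Tibble as returned by [read_roi_tracks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_tracks <- function(tracks, path) {
  readr::write_csv(
    tibble::tibble(
      t_ms = tracks$t, roi_id = tracks$roi_id,
      x_min = tracks$x_min, y_min = tracks$y_min,
      x_max = tracks$x_max, y_max = tracks$y_max,
      visible = tracks$visible
    ),
    path, progress = FALSE
  )
  invisible(path)
}

trial_required_cols <- c(
  "participant_id", "scenario_id", "condition", "order_index", "drug",
  "initial_dose", "final_dose", "ai_dose",
  "rating_qdiff", "rating_mortality", "rating_features", "rating_examples",
  "seniority"
)

#' Read trial records
#'
#' One row per trial x drug: participant, scenario (1-6), safety condition,
#' position in the participant's session, pre-reveal (`initial_dose`) and
#' post-reveal (`final_dose`) prescriptions, the AI-recommended dose, post-hoc
#' XAI usefulness ratings (0-4, may be missing) and seniority grade. Dose
#' units are preserved as given (ml/h for fluid, mcg/kg/min for vasopressor).
#' Missing ratings stay missing, never zero.
#'
#' @param path CSV with the columns listed in the package README.
#' @return A tibble of trial records.
#' @export
read_trials <- function(path) {
  raw <- read_csv_strict(path, trial_required_cols, "trials")
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    scenario_id = as.integer(raw$scenario_id),
    condition = as.character(raw$condition),
    order_index = as.integer(raw$order_index),
    drug = as.character(raw$drug),
    initial_dose = as.numeric(raw$initial_dose),
    final_dose = as.numeric(raw$final_dose),
    ai_dose = as.numeric(raw$ai_dose),
    rating_qdiff = as.integer(raw$rating_qdiff),
    rating_mortality = as.integer(raw$rating_mortality),
    rating_features = as.integer(raw$rating_features),
    rating_examples = as.integer(raw$rating_examples),
    seniority = as.character(raw$seniority)
  )
  bad_cond <- setdiff(unique(out$condition), c("safe", "unsafe"))
  if (length(bad_cond)) {
    abort(paste0(
      "condition must be 'safe' or 'unsafe'; found: ",
      paste(bad_cond, collapse = ", ")
    ))
  }
  doses <- c(out$initial_dose, out$final_dose, out$ai_dose)
  if (any(doses < 0, na.rm = TRUE)) abort("Doses must be non-negative.")
  ratings <- cbind(
    raw$rating_qdiff, raw$rating_mortality, raw$rating_features,
    raw$rating_examples
  )
  if (any(ratings < 0 | ratings > 4, na.rm = TRUE)) {
    abort("Usefulness ratings must lie in 0-4 when present.")
  }
  out
}

#' Write trial records
#'
#' @param trials Tibble as returned by [read_trials()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[, trial_required_cols], path, progress = FALSE)
  invisible(path)
}

#' Check trial records against the experiment design
#'
#' The design requires, per participant: exactly six trials (scenarios 1-6),
#' four under a safe and two under an unsafe AI recommendation, and the first
#' trial encountered (order_index 1) safe — the study mitigation against
#' unsafe advice shaking confidence early.
#'
#' @param trials A trials tibble (per-drug rows are deduplicated internally).
#' @return A tibble of violations (`participant_id`, `rule`, `detail`);
#'   zero rows when the design is satisfied. Violations are data, not errors.
#' @examples
#' \dontrun{
#' validate_design(read_trials("trials.csv"))
#' }
#' @export
validate_design <- function(trials) {
  per_trial <- dplyr::distinct(
    trials, .data$participant_id, .data$scenario_id,
    .data$condition, .data$order_index
  )
  res <- dplyr::group_map(
    dplyr::group_by(per_trial, .data$participant_id),
    function(d, key) {
      v <- list()
      if (nrow(d) != 6 || !setequal(d$scenario_id, 1:6)) {
        v <- c(v, list(c("six_scenarios", paste0(nrow(d), " trials"))))
      }
      n_safe <- sum(d$condition == "safe")
      n_unsafe <- sum(d$condition == "unsafe")
      if (n_safe != 4 || n_unsafe != 2) {
        v <- c(v, list(c(
          "four_safe_two_unsafe",
          paste0(n_safe, " safe, ", n_unsafe, " unsafe")
        )))
      }
      first <- d$condition[d$order_index == 1]
      if (length(first) != 1 || first != "safe") {
        v <- c(v, list(c("first_trial_safe", paste0(
          "first trial condition: ",
          if (length(first)) first else "absent"
        ))))
      }
      if (!length(v)) {
        return(tibble::tibble(
          participant_id = character(), rule = character(), detail = character()
        ))
      }
      tibble::tibble(
        participant_id = key$participant_id,
        rule = purrr::map_chr(v, 1),
        detail = purrr::map_chr(v, 2)
      )
    }
  )
  dplyr::bind_rows(res)
}
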
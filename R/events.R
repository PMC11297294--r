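#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' A fixation occurs when the eyes cease scanning and hold the foveal area of
#' the visual field in one place. The I-DT criterion used here: a maximal
#' window of consecutive samples — all with confidence at or above
#' `min_confidence` — is a fixation iff its time span is at least
#' `min_duration` and its dispersion, `(max x - min x) + (max y - min y)`,
#' does not exceed `dispersion_threshold`. Windows are grown greedily
#' left-to-right (a sample that could either extend the current fixation or
#' start the next one extends the current one) and never overlap.
#' Low-confidence samples terminate a window.
#'
#' @param samples Gaze tibble with columns `t, x, y, confidence`, sorted by
#'   `t` (as returned by [read_gaze_stream()]).
#' @param dispersion_threshold Maximum dispersion, normalized world-view
#'   units (default 0.03).
#' @param min_duration Minimum fixation span in ms (default 80).
#' @param min_confidence Samples below this confidence cannot belong to a
#'   fixation (default 0.6).
#' @return A tibble with one row per fixation: `onset_ms, offset_ms,
#'   duration_ms, centroid_x, centroid_y, dispersion, n_samples`. The
#'   centroid is the arithmetic mean of the member samples.
#' @examples
#' g <- tibble::tibble(
#'   t = seq(0, 320, by = 8), x = 0.5, y = 0.5, confidence = 1
#' )
#' detect_fixations(g)
#' @export
detect_fixations <- function(samples, dispersion_threshold = 0.03,
                             min_duration = 80, min_confidence = 0.6) {
  if (dispersion_threshold <= 0 || min_duration <= 0) {
    abort("dispersion_threshold and min_duration must be positive.")
  }
  empty <- tibble::tibble(
    onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
    centroid_x = numeric(), centroid_y = numeric(), dispersion = numeric(),
    n_samples = integer()
  )
  if (!nrow(samples)) return(empty)
  stopifnot_sorted(samples$t, "gaze samples")
  m <- idt_scan(
    samples$t, samples$x, samples$y, samples$confidence,
    dispersion_threshold, min_duration, min_confidence
  )
  if (!nrow(m)) return(empty)
  tibble::new_tibble(list(
    onset_ms = m[, 1], offset_ms = m[, 2], duration_ms = m[, 3],
    centroid_x = m[, 4], centroid_y = m[, 5], dispersion = m[, 6],
    n_samples = as.integer(m[, 7])
  ), nrow = nrow(m))
}

#' Detect blinks from pupil-confidence dips
#'
#' Blinks are maximal runs of samples whose confidence falls below
#' `confidence_threshold`. Runs separated by gaps shorter than `merge_gap`
#' are merged (momentary half-open-eye recoveries). Merged runs shorter than
#' `min_duration` are discarded as noise; runs longer than `max_duration` are
#' not blinks but tracking signal loss, reported separately in the QC
#' attribute. Blink onset is the time of the first low-confidence sample;
#' offset is the time of the first confident sample after the run (end of
#' stream: last low time plus one nominal sample period). `last_good_x/y`
#' record gaze at the last confident sample before onset, used downstream to
#' attribute the blink to an ROI.
#'
#' @param samples Gaze tibble with columns `t, x, y, confidence`, time-sorted.
#' @param confidence_threshold Samples strictly below this are blink
#'   candidates (default 0.5).
#' @param min_duration,max_duration Physiological blink duration bounds in ms
#'   (defaults 50 and 500).
#' @param merge_gap Gaps shorter than this (ms) between low runs are merged
#'   (default 20).
#' @return A tibble `onset_ms, offset_ms, duration_ms, last_good_x,
#'   last_good_y`, with a QC attribute listing runs discarded as signal loss.
#' @export
detect_blinks <- function(samples, confidence_threshold = 0.5,
                          min_duration = 50, max_duration = 500,
                          merge_gap = 20) {
  empty <- tibble::tibble(
    onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
    last_good_x = numeric(), last_good_y = numeric()
  )
  qc <- list(n_signal_loss = 0L, signal_loss_ms = 0)
  if (!nrow(samples)) return(set_qc(empty, qc))
  stopifnot_sorted(samples$t, "gaze samples")
  t <- samples$t
  low <- samples$confidence < confidence_threshold
  if (!any(low)) return(set_qc(empty, qc))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  li <- which(r$values)
  # run onset/offset times: onset = first low sample, offset = recovery time
  period <- if (length(t) > 1) median(diff(t)) else 0
  onset <- t[starts[li]]
  offset <- ifelse(ends[li] < length(t), t[ends[li] + 1], t[ends[li]] + period)
  last_good_idx <- starts[li] - 1 # 0 when the stream opens low
  # merge runs separated by gaps < merge_gap
  if (length(onset) > 1) {
    gap <- onset[-1] - offset[-length(offset)]
    grp <- cumsum(c(1, as.integer(gap >= merge_gap)))
    onset <- as.numeric(tapply(onset, grp, min))
    last_good_idx <- as.numeric(tapply(last_good_idx, grp, min))
    offset <- as.numeric(tapply(offset, grp, max))
  }
  dur <- offset - onset
  loss <- dur > max_duration
  keep <- dur >= min_duration & !loss
  qc <- list(
    n_signal_loss = sum(loss),
    signal_loss_ms = sum(dur[loss])
  )
  out <- tibble::tibble(
    onset_ms = as.numeric(onset[keep]),
    offset_ms = as.numeric(offset[keep]),
    duration_ms = as.numeric(dur[keep]),
    last_good_x = as.numeric(ifelse(last_good_idx[keep] >= 1,
      samples$x[pmax(last_good_idx[keep], 1)], NA_real_
    )),
    last_good_y = as.numeric(ifelse(last_good_idx[keep] >= 1,
      samples$y[pmax(last_good_idx[keep], 1)], NA_real_
    ))
  )
  set_qc(out, qc)
}

#' Events per minute
#'
#' @param events An event tibble (or an event count).
#' @param exposure_ms Exposure time in milliseconds; must be positive.
#' @return Events per minute: `count / exposure_ms * 60000`.
#' @examples
#' event_rate(10, 60000)
#' @export
event_rate <- function(events, exposure_ms) {
  if (!is.numeric(exposure_ms) || length(exposure_ms) != 1 || exposure_ms <= 0) {
    abort("exposure_ms must be a single positive number.")
  }
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / exposure_ms * 60000
}

#' Write an event table to CSV
#'
#' @param events Fixation or blink tibble from [detect_fixations()] or
#'   [detect_blinks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}
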
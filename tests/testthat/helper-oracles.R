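# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles re-derive the contracts by exhaustive search and share no
# code with the implementations they check.

# Exhaustive I-DT oracle: for each candidate start, scan every end index,
# recomputing dispersion from scratch; keep the greedy-left maximal window.
idt_oracle <- function(samples, dispersion_threshold, min_duration,
                       min_confidence) {
  t <- samples$t
  x <- samples$x
  y <- samples$y
  conf <- samples$confidence
  n <- length(t)
  rows <- list()
  s <- 1
  while (s <= n) {
    if (conf[s] < min_confidence) {
      s <- s + 1
      next
    }
    best_e <- NA_integer_
    for (e in s:n) {
      if (conf[e] < min_confidence) break
      disp <- (max(x[s:e]) - min(x[s:e])) + (max(y[s:e]) - min(y[s:e]))
      if (disp > dispersion_threshold) break
      if (t[e] - t[s] >= min_duration) best_e <- e
    }
    if (!is.na(best_e)) {
      e <- best_e
      rows[[length(rows) + 1]] <- data.frame(
        onset_ms = t[s], offset_ms = t[e], duration_ms = t[e] - t[s],
        centroid_x = mean(x[s:e]), centroid_y = mean(y[s:e]),
        dispersion = (max(x[s:e]) - min(x[s:e])) + (max(y[s:e]) - min(y[s:e])),
        n_samples = e - s + 1
      )
      s <- e + 1
    } else {
      s <- s + 1
    }
  }
  if (!length(rows)) {
    return(data.frame(
      onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
      centroid_x = numeric(), centroid_y = numeric(), dispersion = numeric(),
      n_samples = integer()
    ))
  }
  do.call(rbind, rows)
}

# Sample-by-sample blink oracle: walk the stream, open a run on the first
# low-confidence sample, close on recovery, then merge/filter afterwards.
blink_oracle <- function(samples, confidence_threshold, min_duration,
                         max_duration, merge_gap) {
  t <- samples$t
  conf <- samples$confidence
  n <- length(t)
  period <- if (n > 1) median(diff(t)) else 0
  runs <- list()
  i <- 1
  while (i <= n) {
    if (conf[i] < confidence_threshold) {
      j <- i
      while (j < n && conf[j + 1] < confidence_threshold) j <- j + 1
      runs[[length(runs) + 1]] <- c(
        onset = t[i],
        offset = if (j < n) t[j + 1] else t[j] + period,
        last_good = i - 1
      )
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(runs)) {
    return(data.frame(
      onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric()
    ))
  }
  m <- do.call(rbind, runs)
  merged <- list(m[1, ])
  if (nrow(m) > 1) {
    for (r in 2:nrow(m)) {
      prev <- merged[[length(merged)]]
      if (m[r, "onset"] - prev["offset"] < merge_gap) {
        prev["offset"] <- m[r, "offset"]
        merged[[length(merged)]] <- prev
      } else {
        merged[[length(merged) + 1]] <- m[r, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  dur <- m[, "offset"] - m[, "onset"]
  keep <- dur >= min_duration & dur <= max_duration
  data.frame(
    onset_ms = m[keep, "onset"], offset_ms = m[keep, "offset"],
    duration_ms = dur[keep]
  )
}

# random gaze stream with fixation-like plateaus, jumps and confidence dips
random_stream <- function(n, seed) {
  set.seed(seed)
  t <- cumsum(runif(n, 5, 12))
  x <- numeric(n)
  y <- numeric(n)
  cx <- runif(1)
  cy <- runif(1)
  for (i in seq_len(n)) {
    if (runif(1) < 0.15) {
      cx <- runif(1)
      cy <- runif(1)
    }
    x[i] <- cx + rnorm(1, 0, 0.004)
    y[i] <- cy + rnorm(1, 0, 0.004)
  }
  conf <- ifelse(runif(n) < 0.1, runif(n, 0, 0.4), runif(n, 0.7, 1))
  tibble::tibble(t = t, x = x, y = y, confidence = conf)
}

# regular 120 Hz stream at a fixed point
constant_stream <- function(n, x = 0.5, y = 0.5, conf = 1, dt = 1000 / 120,
                            t0 = 0) {
  tibble::tibble(
    t = t0 + (seq_len(n) - 1) * dt, x = x, y = y, confidence = conf
  )
}

# single-frame (static) ROI tracks from a layout-like data frame
static_tracks <- function(boxes, t = 0) {
  tibble::tibble(
    t = t, roi_id = boxes$roi_id,
    x_min = boxes$x_min, y_min = boxes$y_min,
    x_max = boxes$x_max, y_max = boxes$y_max,
    visible = TRUE
  )
}

# exhaustive per-sample attention tally used against summarize_attention():
# assigns each sample to the smallest containing box by direct enumeration
tally_oracle <- function(samples, boxes, defs) {
  anc <- list()
  for (i in seq_len(nrow(defs))) {
    id <- defs$roi_id[i]
    chain <- character()
    cur <- defs$parent_id[i]
    while (!is.na(cur)) {
      chain <- c(chain, cur)
      cur <- defs$parent_id[match(cur, defs$roi_id)]
    }
    anc[[id]] <- chain
  }
  t <- samples$t
  period <- median(diff(t))
  dt <- c(pmin(diff(t), 2 * period), period)
  time_per_roi <- setNames(rep(0, nrow(defs) + 1), c(defs$roi_id, "elsewhere"))
  for (i in seq_along(t)) {
    hits <- boxes[samples$x[i] >= boxes$x_min & samples$x[i] < boxes$x_max &
      samples$y[i] >= boxes$y_min & samples$y[i] < boxes$y_max, ]
    if (!nrow(hits)) {
      time_per_roi[["elsewhere"]] <- time_per_roi[["elsewhere"]] + dt[i]
      next
    }
    areas <- (hits$x_max - hits$x_min) * (hits$y_max - hits$y_min)
    winner <- hits$roi_id[order(areas, hits$roi_id)][1]
    for (id in c(winner, anc[[winner]])) {
      time_per_roi[[id]] <- time_per_roi[[id]] + dt[i]
    }
  }
  time_per_roi
}

# tiny two-ROI definitions used in attribution tests
two_roi_defs <- function() {
  roi_definitions(
    roi_id = c("screen", "panel", "chart"),
    parent_id = c(NA, "screen", NA)
  )
}

two_roi_boxes <- function() {
  tibble::tibble(
    roi_id = c("screen", "panel", "chart"),
    x_min = c(0.5, 0.55, 0.0), y_min = c(0.5, 0.55, 0.0),
    x_max = c(0.9, 0.75, 0.3), y_max = c(0.9, 0.75, 0.4)
  )
}
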
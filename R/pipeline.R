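#' Event-detection and attribution parameters
#'
#' All thresholds used by the detection and attribution stages, exposed in
#' one place so a pipeline config can override any of them.
#'
#' @param dispersion_threshold,fixation_min_duration_ms,fixation_min_confidence
#'   I-DT fixation parameters (see [detect_fixations()]).
#' @param blink_confidence_threshold,blink_min_duration_ms,blink_max_duration_ms,blink_merge_gap_ms
#'   Blink parameters (see [detect_blinks()]).
#' @param min_confidence Ingest QC flag threshold (see [read_gaze_stream()]).
#' @return A named list of class `detection_params`.
#' @export
detection_params <- function(dispersion_threshold = 0.03,
                             fixation_min_duration_ms = 80,
                             fixation_min_confidence = 0.6,
                             blink_confidence_threshold = 0.5,
                             blink_min_duration_ms = 50,
                             blink_max_duration_ms = 500,
                             blink_merge_gap_ms = 20,
                             min_confidence = 0.6) {
  structure(as.list(environment()), class = "detection_params")
}

#' Analyse one trial's gaze stream
#'
#' Runs event detection and ROI attribution for a single trial: fixations
#' (I-DT), blinks (confidence dips), and the per-ROI attention summary.
#'
#' @param samples Gaze tibble (`t, x, y, confidence`).
#' @param tracks ROI track tibble for the same trial.
#' @param definitions `roi_definitions` tibble.
#' @param trial The trial's row(s) of the trials table.
#' @param params A [detection_params()] list.
#' @return List with `fixations`, `blinks`, `attention`.
#' @export
analyze_trial <- function(samples, tracks, definitions, trial,
                          params = detection_params()) {
  fixations <- detect_fixations(
    samples,
    dispersion_threshold = params$dispersion_threshold,
    min_duration = params$fixation_min_duration_ms,
    min_confidence = params$fixation_min_confidence
  )
  blinks <- detect_blinks(
    samples,
    confidence_threshold = params$blink_confidence_threshold,
    min_duration = params$blink_min_duration_ms,
    max_duration = params$blink_max_duration_ms,
    merge_gap = params$blink_merge_gap_ms
  )
  attention <- summarize_attention(
    samples, fixations, blinks, tracks, definitions, trial
  )
  list(fixations = fixations, blinks = blinks, attention = attention)
}

#' Analyse a whole (in-memory) experiment
#'
#' Maps [analyze_trial()] over every trial of a generated or loaded
#' experiment and binds the per-ROI attention rows.
#'
#' @param exp Experiment list as returned by [generate_experiment()]
#'   (`trials`, `gaze`, `tracks`, `definitions`).
#' @param params A [detection_params()] list.
#' @param keep_events Also return the bound fixation/blink tables (heavier;
#'   default `FALSE`).
#' @return List with `attention` (tibble) and, when `keep_events = TRUE`,
#'   `fixations` and `blinks` tibbles carrying participant/scenario keys.
#' @export
analyze_experiment <- function(exp, params = detection_params(),
                               keep_events = FALSE) {
  keys <- names(exp$gaze)
  att <- vector("list", length(keys))
  fixs <- if (keep_events) vector("list", length(keys)) else NULL
  blks <- if (keep_events) vector("list", length(keys)) else NULL
  for (i in seq_along(keys)) {
    key <- keys[i]
    m <- regmatches(key, regexec("^(.+)_s(\\d+)$", key))[[1]]
    trial <- exp$trials[
      exp$trials$participant_id == m[2] &
        exp$trials$scenario_id == as.integer(m[3]),
    ]
    res <- analyze_trial(
      exp$gaze[[key]], exp$tracks[[key]], exp$definitions, trial, params
    )
    att[[i]] <- res$attention
    if (keep_events) {
      fixs[[i]] <- dplyr::mutate(
        res$fixations,
        participant_id = m[2], scenario_id = as.integer(m[3]), .before = 1
      )
      blks[[i]] <- dplyr::mutate(
        res$blinks,
        participant_id = m[2], scenario_id = as.integer(m[3]), .before = 1
      )
    }
  }
  out <- list(attention = dplyr::bind_rows(att))
  if (keep_events) {
    out$fixations <- dplyr::bind_rows(fixs)
    out$blinks <- dplyr::bind_rows(blks)
  }
  out
}

read_pipeline_config <- function(path) {
  if (is.null(path)) {
    return(detection_params())
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(detection_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(detection_params, raw)
}

#' Run the full analysis pipeline over an input directory
#'
#' Ingest, validate, detect events, attribute attention, compute behaviour
#' metrics and emit the headline report, with a run manifest recording the
#' config snapshot, input digests and software version. Expects the layout
#' written by [simulate_experiment()]: `trials.csv`, `roi_definitions.yaml`,
#' and per-trial `gaze/<participant>_s<scenario>.csv` plus matching
#' `tracks/` files.
#'
#' On a validation failure the first error is reported with the offending
#' file and partial outputs are removed.
#'
#' @param input Input directory.
#' @param output Output directory (created).
#' @param config Optional YAML file overriding [detection_params()] values.
#' @return The output directory, invisibly. Side effects: `events_fixations.csv`,
#'   `events_blinks.csv`, `attention.csv`, `behaviour.csv`, `design_violations.csv`,
#'   report tables, `manifest.json`, and a `pipeline.log`.
#' @export
run_pipeline <- function(input, output, config = NULL) {
  params <- read_pipeline_config(config)
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output, "pipeline.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  cleanup_and_abort <- function(msg) {
    unlink(list.files(output, full.names = TRUE), recursive = TRUE)
    abort(msg)
  }

  trials_path <- file.path(input, "trials.csv")
  defs_path <- file.path(input, "roi_definitions.yaml")
  for (p in c(trials_path, defs_path)) {
    if (!file.exists(p)) cleanup_and_abort(paste0("Missing input file: ", p))
  }
  trials <- tryCatch(read_trials(trials_path),
    error = function(e) cleanup_and_abort(conditionMessage(e))
  )
  definitions <- tryCatch(read_roi_definitions(defs_path),
    error = function(e) cleanup_and_abort(conditionMessage(e))
  )
  logf("read %d trial rows, %d ROI definitions", nrow(trials), nrow(definitions))

  violations <- validate_design(trials)
  readr::write_csv(violations, file.path(output, "design_violations.csv"),
    progress = FALSE
  )
  if (nrow(violations)) {
    logf("design violations: %d (see design_violations.csv)", nrow(violations))
  }

  keys <- unique(paste0(trials$participant_id, "_s", trials$scenario_id))
  att <- list()
  fixs <- list()
  blks <- list()
  inputs_digested <- c(trials_path, defs_path)
  for (key in keys) {
    gaze_path <- file.path(input, "gaze", paste0(key, ".csv"))
    tracks_path <- file.path(input, "tracks", paste0(key, ".csv"))
    for (p in c(gaze_path, tracks_path)) {
      if (!file.exists(p)) cleanup_and_abort(paste0("Missing input file: ", p))
    }
    m <- regmatches(key, regexec("^(.+)_s(\\d+)$", key))[[1]]
    trial <- trials[
      trials$participant_id == m[2] & trials$scenario_id == as.integer(m[3]),
    ]
    res <- tryCatch(
      {
        samples <- read_gaze_stream(gaze_path, min_confidence = params$min_confidence)
        tr <- read_roi_tracks(tracks_path, definitions)
        analyze_trial(samples, tr, definitions, trial, params)
      },
      error = function(e) {
        cleanup_and_abort(paste0("Trial ", key, ": ", conditionMessage(e)))
      }
    )
    att[[key]] <- res$attention
    fixs[[key]] <- dplyr::mutate(
      res$fixations,
      participant_id = m[2], scenario_id = as.integer(m[3]), .before = 1
    )
    blks[[key]] <- dplyr::mutate(
      res$blinks,
      participant_id = m[2], scenario_id = as.integer(m[3]), .before = 1
    )
    inputs_digested <- c(inputs_digested, gaze_path, tracks_path)
  }
  attention <- dplyr::bind_rows(att)
  logf("analysed %d trials", length(keys))

  behaviour <- behaviour_table(trials)
  report <- headline_report(attention, behaviour, trials)

  write_attention(attention, file.path(output, "attention.csv"))
  write_behaviour(behaviour, file.path(output, "behaviour.csv"))
  write_events(dplyr::bind_rows(fixs), file.path(output, "events_fixations.csv"))
  write_events(dplyr::bind_rows(blks), file.path(output, "events_blinks.csv"))
  write_report(report, output)
  logf("wrote attention (%d rows), behaviour (%d rows), report tables",
    nrow(attention), nrow(behaviour))

  manifest <- list(
    package_version = as.character(utils::packageVersion("clingaze")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(params),
    inputs = as.list(tools::md5sum(sort(unique(inputs_digested))))
  )
  jsonlite::write_json(manifest, file.path(output, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(output)
}

#' Generate a synthetic experiment on disk
#'
#' Thin wrapper over [generate_experiment()] that writes the fixture tree
#' [run_pipeline()] consumes.
#'
#' @param config A [generator_config()] (or path to a YAML file of
#'   generator settings).
#' @param output Output directory.
#' @param seed Optional seed overriding the config's.
#' @return The output directory, invisibly.
#' @export
simulate_experiment <- function(config = generator_config(), output, seed = NULL) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    known <- names(formals(generator_config))
    unknown <- setdiff(names(raw), known)
    if (length(unknown)) {
      abort(paste0("Unknown generator key(s): ", paste(unknown, collapse = ", ")))
    }
    # restore names dropped by YAML round-trip of named vectors
    defaults <- formals(generator_config)
    for (nm in names(raw)) {
      d <- eval(defaults[[nm]])
      if (!is.null(names(d)) && is.null(names(raw[[nm]])) &&
        length(raw[[nm]]) == length(d)) {
        raw[[nm]] <- setNames(unlist(raw[[nm]]), names(d))
      }
    }
    config <- do.call(generator_config, raw)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  generate_experiment(config, dir = output)
  invisible(output)
}
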
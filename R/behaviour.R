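#' Influence of AI (weight on advice)
#'
#' The Yaniv-style weight-on-advice measure of how far a decision moved toward
#' the advice: `(final - initial) / (advice - initial)`. 0 means the advice
#' was ignored, 1 means it was adopted outright. Undefined when the advice
#' (essentially) equals the initial estimate — the denominator carries no
#' information — which is flagged, not erroneous.
#'
#' @param initial Pre-reveal dose(s) (the physician's own estimate).
#' @param final Post-reveal dose(s).
#' @param advice AI-recommended dose(s).
#' @param epsilon Trials with `|advice - initial| <= epsilon` are undefined
#'   (default `1e-8`; callers working in dose units should pass a unit-aware
#'   tolerance, e.g. 1 ml/h for fluid, 0.01 mcg/kg/min for vasopressor).
#' @param clamp Winsorize the returned influence to \[0, 1\] (default `TRUE`;
#'   over- and under-shooting trials are real, but the headline scale is
#'   bounded). The raw value is kept alongside by [behaviour_table()].
#' @return Numeric vector; `NA` where undefined.
#' @examples
#' influence_of_ai(500, 200, 200) # advice adopted -> 1
#' influence_of_ai(500, 500, 200) # advice ignored -> 0
#' @export
influence_of_ai <- function(initial, final, advice, epsilon = 1e-8,
                            clamp = TRUE) {
  if (any(c(initial, final, advice) < 0, na.rm = TRUE)) {
    abort("Doses must be non-negative.")
  }
  denom <- advice - initial
  out <- ifelse(abs(denom) <= epsilon, NA_real_, (final - initial) / denom)
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out + 0 # normalizes IEEE negative zero
}

#' Practice variation
#'
#' A prescriber's absolute distance from the average of all physicians'
#' pre-reveal prescriptions for one scenario and drug — a proxy for how much
#' of an outlier the prescriber is in that trial. The group mean includes the
#' physician's own dose; set `leave_one_out = TRUE` for the self-excluded
#' variant.
#'
#' @param doses Numeric vector of pre-reveal doses, one per participant
#'   (length at least 2), optionally named.
#' @param leave_one_out Exclude each participant's own dose from the mean.
#' @return Numeric vector of absolute distances, same names as `doses`.
#' @examples
#' practice_variation(c(100, 200, 300))
#' @export
practice_variation <- function(doses, leave_one_out = FALSE) {
  n <- length(doses)
  if (n < 2) abort("practice_variation needs doses from at least 2 participants.")
  ref <- if (leave_one_out) (sum(doses) - doses) / (n - 1) else mean(doses)
  abs(doses - ref)
}

#' Advice distance
#'
#' Absolute distance between the final prescription and the AI
#' recommendation; larger values suggest lower adherence to the advice.
#'
#' @param final Final (post-reveal) dose(s).
#' @param advice AI-recommended dose(s).
#' @return `|final - advice|`, in the dose's own units.
#' @examples
#' advice_distance(371, 200)
#' @export
advice_distance <- function(final, advice) {
  abs(final - advice)
}

#' Per-trial behaviour metrics
#'
#' Computes influence of AI, practice variation and advice distance for every
#' trial x drug row of a trials table. Influence uses a per-drug degenerate
#' denominator tolerance; both raw and \[0, 1\]-clamped influence are kept.
#' Practice variation is computed within scenario x drug across all
#' participants (pre-reveal doses do not depend on the safety condition).
#'
#' @param trials Trials tibble (see [read_trials()]).
#' @param epsilon Named vector of per-drug tolerances for the undefined-
#'   influence rule, in each drug's dose units.
#' @param leave_one_out Passed to [practice_variation()].
#' @return A tibble, one row per trial x drug:
#'   `participant_id, scenario_id, condition, drug, influence_raw,
#'   influence_clamped, influence_defined, practice_variation,
#'   advice_distance`. A QC attribute counts undefined-influence trials.
#' @export
behaviour_table <- function(trials,
                            epsilon = c(fluid = 1, vasopressor = 0.01),
                            leave_one_out = FALSE) {
  eps <- unname(epsilon[trials$drug])
  eps[is.na(eps)] <- 1e-8
  out <- dplyr::mutate(
    trials,
    influence_raw = influence_of_ai(
      .data$initial_dose, .data$final_dose, .data$ai_dose,
      epsilon = eps, clamp = FALSE
    ),
    influence_clamped = pmin(pmax(.data$influence_raw, 0), 1),
    influence_defined = !is.na(.data$influence_raw),
    advice_distance = advice_distance(.data$final_dose, .data$ai_dose)
  )
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$scenario_id, .data$drug),
    practice_variation = practice_variation(
      .data$initial_dose,
      leave_one_out = leave_one_out
    ),
    .before = "advice_distance"
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::select(
    out, "participant_id", "scenario_id", "condition", "drug",
    "influence_raw", "influence_clamped", "influence_defined",
    "practice_variation", "advice_distance"
  )
  set_qc(out, list(n_influence_undefined = sum(!out$influence_defined)))
}

#' Join behaviour, attention and self-report tables
#'
#' Builds the per-trial analysis table used by the statistical layer: one row
#' per participant x scenario x drug, carrying the behaviour metrics, the
#' AI-screen and per-explanation-panel attention metrics (fixation counts,
#' AI-screen blink rate and gaze time), and the usefulness ratings. Missing
#' values propagate; nothing is imputed. Keys present on one side only are
#' listed in the QC attribute, not dropped silently.
#'
#' @param behaviour Tibble from [behaviour_table()].
#' @param attention Attention rows from [summarize_attention()] over the same
#'   trials.
#' @param trials Trials tibble supplying the ratings.
#' @return The joined analysis tibble (one row per behaviour row).
#' @export
join_behaviour_attention <- function(behaviour, attention, trials) {
  keys <- c("participant_id", "scenario_id")
  att_wide <- tidyr::pivot_wider(
    dplyr::select(
      attention, dplyr::all_of(keys), "roi_id",
      "n_fixations", "blink_rate_bpm", "gaze_time_ms"
    ),
    names_from = "roi_id",
    values_from = c("n_fixations", "blink_rate_bpm", "gaze_time_ms")
  )
  ratings <- dplyr::distinct(
    trials, .data$participant_id, .data$scenario_id,
    .data$rating_qdiff, .data$rating_mortality,
    .data$rating_features, .data$rating_examples, .data$seniority
  )
  out <- dplyr::left_join(behaviour, att_wide, by = keys)
  out <- dplyr::left_join(out, ratings, by = keys)
  b_keys <- unique(behaviour[keys])
  a_keys <- unique(attention[keys])
  only_b <- dplyr::anti_join(b_keys, a_keys, by = keys)
  only_a <- dplyr::anti_join(a_keys, b_keys, by = keys)
  set_qc(out, list(
    keys_behaviour_only = only_b,
    keys_attention_only = only_a
  ))
}

#' Write the behaviour table to CSV
#'
#' @param behaviour Tibble from [behaviour_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_behaviour <- function(behaviour, path) {
  readr::write_csv(behaviour, path, progress = FALSE)
  invisible(path)
}
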
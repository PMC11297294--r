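major_rois <- c("mannequin", "monitor", "chart", "ai_screen")
xai_rois <- c("xai_qdiff", "xai_mortality", "xai_features", "xai_examples")
ai_family <- c("ai_screen", "ai_recommendation", xai_rois)
conventional_rois <- c("chart", "mannequin", "monitor")
rating_of <- c(
  xai_qdiff = "rating_qdiff", xai_mortality = "rating_mortality",
  xai_features = "rating_features", xai_examples = "rating_examples"
)

# t-test that degrades to a not-computable row instead of erroring
safe_t_row <- function(x, y, ...) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(tibble::tibble(
      mean_1 = if (length(x)) mean(x) else NA_real_,
      mean_2 = if (length(y)) mean(y) else NA_real_,
      ci_low_1 = NA_real_, ci_high_1 = NA_real_,
      ci_low_2 = NA_real_, ci_high_2 = NA_real_,
      statistic = NA_real_, df = NA_real_, p.value = NA_real_,
      cohens_d = NA_real_, n1 = length(x), n2 = length(y),
      note = "not computable (n < 2 per arm)"
    ))
  }
  td <- tidy(t_test_independent(x, y, ...))
  tibble::tibble(
    mean_1 = td$mean_1, mean_2 = td$mean_2,
    ci_low_1 = td$ci_low_1, ci_high_1 = td$ci_high_1,
    ci_low_2 = td$ci_low_2, ci_high_2 = td$ci_high_2,
    statistic = td$statistic, df = td$df, p.value = td$p.value,
    cohens_d = td$cohens_d, n1 = td$n1, n2 = td$n2,
    note = NA_character_
  )
}

safe_cor_row <- function(x, y, method = "pearson") {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) {
    return(tibble::tibble(
      r = NA_real_, n = sum(ok), p.value = NA_real_,
      note = "not computable (n < 3)"
    ))
  }
  cr <- pearson_correlation(x, y, method = method)
  tibble::tibble(r = cr$r, n = cr$n, p.value = cr$p_value, note = cr$note)
}

# per-trial overall metrics reconstructed from the per-ROI attention rows
trial_overall <- function(attention) {
  att <- dplyr::filter(attention, .data$roi_id %in% major_rois)
  dplyr::summarise(
    dplyr::group_by(att, .data$participant_id, .data$scenario_id, .data$condition),
    total_fixations = sum(.data$n_fixations, na.rm = TRUE),
    total_blink_rate_bpm = {
      cnt <- sum(.data$blink_rate_bpm * .data$gaze_time_ms / 60000, na.rm = TRUE)
      tm <- sum(.data$gaze_time_ms[!is.na(.data$blink_rate_bpm)])
      if (tm > 0) cnt / tm * 60000 else NA_real_
    },
    .groups = "drop"
  )
}

#' Headline comparison tables
#'
#' Emits the study's statistical layer from the per-trial attention,
#' behaviour and trial tables:
#' 1. AI-screen fixation counts, safe vs unsafe (Student's t), at trial level
#'    and on participant means (both levels are reported because pooling
#'    trials across participants assumes their independence);
#' 2. per-explanation-panel fixation counts, safe vs unsafe, with post-hoc
#'    power at the observed effect size;
#' 3. blink rate on conventional clinical ROIs (chart, mannequin, monitor)
#'    vs AI ROIs (AI screen, recommendation and explanation panels);
#' 4. mean fixation duration and blink rate per ROI (mean, SD, SEM);
#' 5. actual vs chance gaze proportion per ROI, with the actual-to-chance
#'    ratio;
#' 6. correlations: blink rate and fixation count vs practice variation (by
#'    drug) and vs influence of AI (by drug and condition); fixations on each
#'    explanation panel vs its usefulness rating (per panel on participant
#'    means, and pooled across panels at trial level).
#'
#' No multiple-testing adjustment is applied; the report footer says so.
#' Comparisons with fewer than 2 observations per arm are marked
#' not-computable rather than dropped. Report generation is deterministic.
#'
#' @param attention Attention rows from [summarize_attention()] for all
#'   trials.
#' @param behaviour Tibble from [behaviour_table()].
#' @param trials Trials tibble.
#' @return An object of class `gaze_report`: a list of tibbles
#'   (`comparisons`, `roi_metrics`, `chance_ratios`, `correlations`) plus a
#'   `footer` string. Write with [write_report()].
#' @export
headline_report <- function(attention, behaviour, trials) {
  att_fix <- function(roi) {
    dplyr::filter(attention, .data$roi_id == roi)
  }
  ai <- att_fix("ai_screen")
  comparisons <- list()

  # (1) AI-screen fixations, safe vs unsafe
  comparisons$ai_trial <- dplyr::bind_cols(
    tibble::tibble(
      comparison = "ai_screen_fixations", level = "trial",
      group_1 = "unsafe", group_2 = "safe"
    ),
    safe_t_row(
      ai$n_fixations[ai$condition == "unsafe"],
      ai$n_fixations[ai$condition == "safe"]
    )
  )
  ai_pm <- dplyr::summarise(
    dplyr::group_by(ai, .data$participant_id, .data$condition),
    n_fixations = mean(.data$n_fixations), .groups = "drop"
  )
  comparisons$ai_participant <- dplyr::bind_cols(
    tibble::tibble(
      comparison = "ai_screen_fixations", level = "participant_mean",
      group_1 = "unsafe", group_2 = "safe"
    ),
    safe_t_row(
      ai_pm$n_fixations[ai_pm$condition == "unsafe"],
      ai_pm$n_fixations[ai_pm$condition == "safe"]
    )
  )

  # (2) per-XAI-panel fixations, safe vs unsafe
  for (roi in xai_rois) {
    d <- att_fix(roi)
    row <- dplyr::bind_cols(
      tibble::tibble(
        comparison = paste0(roi, "_fixations"), level = "trial",
        group_1 = "unsafe", group_2 = "safe"
      ),
      safe_t_row(
        d$n_fixations[d$condition == "unsafe"],
        d$n_fixations[d$condition == "safe"]
      )
    )
    comparisons[[paste0("xai_", roi)]] <- row
  }

  # (3) conventional vs AI ROI blink rate
  br <- dplyr::filter(
    attention, .data$roi_id %in% c(conventional_rois, ai_family),
    !is.na(.data$blink_rate_bpm)
  )
  conv <- br$blink_rate_bpm[br$roi_id %in% conventional_rois]
  aibr <- br$blink_rate_bpm[br$roi_id %in% ai_family]
  comparisons$blink_groups <- dplyr::bind_cols(
    tibble::tibble(
      comparison = "blink_rate_conventional_vs_ai", level = "trial_roi",
      group_1 = "conventional", group_2 = "ai"
    ),
    safe_t_row(conv, aibr)
  )

  comparisons <- dplyr::bind_rows(comparisons)
  # post-hoc power at the observed standardized effect
  comparisons$power <- purrr::pmap_dbl(
    comparisons[c("cohens_d", "n1", "n2")],
    function(cohens_d, n1, n2) {
      if (!is.finite(cohens_d) || n1 < 2 || n2 < 2) {
        return(NA_real_)
      }
      posthoc_power_t(cohens_d, n1, n2)$power
    }
  )

  # (4) per-ROI metric summary
  roi_metrics <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(attention, .data$roi_id != "elsewhere"), .data$roi_id
    ),
    n_trials = dplyr::n(),
    mean_fixation_duration_ms = mean(.data$mean_fixation_duration_ms, na.rm = TRUE),
    sd_fixation_duration_ms = sd(.data$mean_fixation_duration_ms, na.rm = TRUE),
    mean_blink_rate_bpm = mean(.data$blink_rate_bpm, na.rm = TRUE),
    sd_blink_rate_bpm = sd(.data$blink_rate_bpm, na.rm = TRUE),
    mean_fixations = mean(.data$n_fixations, na.rm = TRUE),
    .groups = "drop"
  )
  roi_metrics$sem_fixation_duration_ms <-
    roi_metrics$sd_fixation_duration_ms / sqrt(roi_metrics$n_trials)
  roi_metrics$sem_blink_rate_bpm <-
    roi_metrics$sd_blink_rate_bpm / sqrt(roi_metrics$n_trials)

  # (5) actual vs chance gaze
  chance_ratios <- dplyr::bind_rows(lapply(
    setdiff(unique(attention$roi_id), "elsewhere"),
    function(roi) {
      d <- att_fix(roi)
      tt <- safe_t_row(d$actual_gaze_proportion, d$chance_gaze_proportion)
      tibble::tibble(
        roi_id = roi,
        mean_actual = tt$mean_1, mean_chance = tt$mean_2,
        actual_to_chance_ratio = actual_to_chance_ratio(tt$mean_1, tt$mean_2),
        statistic = tt$statistic, p.value = tt$p.value, note = tt$note
      )
    }
  ))

  # (6) correlations
  overall <- trial_overall(attention)
  beh <- dplyr::left_join(
    behaviour, overall,
    by = c("participant_id", "scenario_id", "condition")
  )
  correlations <- list()
  for (drug in unique(beh$drug)) {
    d <- beh[beh$drug == drug, ]
    for (metric in c("total_blink_rate_bpm", "total_fixations")) {
      correlations[[paste("pv", drug, metric)]] <- dplyr::bind_cols(
        tibble::tibble(
          analysis = "practice_variation", metric = metric,
          drug = drug, condition = "all", panel = NA_character_
        ),
        safe_cor_row(d$practice_variation, d[[metric]])
      )
      for (cond in unique(d$condition)) {
        dc <- d[d$condition == cond, ]
        correlations[[paste("infl", drug, cond, metric)]] <- dplyr::bind_cols(
          tibble::tibble(
            analysis = "influence_of_ai", metric = metric,
            drug = drug, condition = cond, panel = NA_character_
          ),
          safe_cor_row(dc$influence_clamped, dc[[metric]])
        )
      }
    }
  }
  # XAI fixations vs usefulness rating
  ratings <- dplyr::distinct(
    trials, .data$participant_id, .data$scenario_id,
    .data$rating_qdiff, .data$rating_mortality,
    .data$rating_features, .data$rating_examples
  )
  pooled <- list()
  for (roi in xai_rois) {
    d <- dplyr::left_join(
      att_fix(roi), ratings,
      by = c("participant_id", "scenario_id")
    )
    d$rating <- d[[rating_of[[roi]]]]
    pooled[[roi]] <- d[c("participant_id", "n_fixations", "rating")]
    pm <- dplyr::summarise(
      dplyr::group_by(d, .data$participant_id),
      n_fixations = mean(.data$n_fixations),
      rating = mean(.data$rating), .groups = "drop"
    )
    correlations[[paste("rating", roi)]] <- dplyr::bind_cols(
      tibble::tibble(
        analysis = "xai_rating_vs_fixations", metric = "panel_fixations",
        drug = NA_character_, condition = "all", panel = roi
      ),
      safe_cor_row(pm$n_fixations, pm$rating)
    )
  }
  pooled <- dplyr::bind_rows(pooled)
  correlations$rating_pooled <- dplyr::bind_cols(
    tibble::tibble(
      analysis = "xai_rating_vs_fixations", metric = "panel_fixations",
      drug = NA_character_, condition = "all", panel = "all_panels_trial_level"
    ),
    safe_cor_row(pooled$n_fixations, pooled$rating)
  )
  correlations <- dplyr::bind_rows(correlations)

  structure(
    list(
      comparisons = comparisons,
      roi_metrics = roi_metrics,
      chance_ratios = chance_ratios,
      correlations = correlations,
      footer = paste(
        "All tests two-sided; Student's (pooled-variance) t unless noted.",
        "No multiple-testing adjustment has been applied."
      )
    ),
    class = "gaze_report"
  )
}

#' @export
print.gaze_report <- function(x, ...) {
  cat("Gaze analysis report\n====================\n\nComparisons:\n")
  print(x$comparisons, n = nrow(x$comparisons))
  cat("\nActual vs chance gaze:\n")
  print(x$chance_ratios, n = nrow(x$chance_ratios))
  cat("\nPer-ROI metrics:\n")
  print(x$roi_metrics, n = nrow(x$roi_metrics))
  cat("\nCorrelations:\n")
  print(x$correlations, n = nrow(x$correlations))
  cat("\n", x$footer, "\n", sep = "")
  invisible(x)
}

#' Write a report to disk
#'
#' Writes each report table as CSV plus a markdown summary
#' (`report_summary.md`) whose footer records that no multiple-testing
#' adjustment was applied.
#'
#' @param report A `gaze_report` from [headline_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("comparisons", "roi_metrics", "chance_ratios", "correlations")) {
    readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
      progress = FALSE
    )
  }
  md <- c(
    "# Gaze analysis report", "",
    "## Safe vs unsafe comparisons", "",
    knit_table(report$comparisons[c(
      "comparison", "level", "mean_1", "mean_2", "statistic", "p.value", "power", "note"
    )]),
    "", "## Actual vs chance gaze", "",
    knit_table(report$chance_ratios),
    "", "## Correlations", "",
    knit_table(report$correlations),
    "", paste0("_", report$footer, "_"), ""
  )
  writeLines(md, file.path(dir, "report_summary.md"))
  invisible(dir)
}

# minimal markdown table writer
knit_table <- function(df) {
  fmt <- function(v) {
    if (is.numeric(v)) sub("^NA$", "", formatC(v, digits = 4, format = "g")) else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  cells[is.na(cells)] <- ""
  c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  )
}
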
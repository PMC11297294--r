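#' Fixations per trial by safety condition
#'
#' Bar chart (mean and SEM) of per-trial fixation counts on the AI screen and
#' the four explanation panels, split by safe vs unsafe AI recommendation.
#'
#' @param attention Attention rows from [summarize_attention()].
#' @return A ggplot object.
#' @export
plot_fixations_by_condition <- function(attention) {
  rois <- c("ai_screen", xai_rois)
  d <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(attention, .data$roi_id %in% rois),
      .data$roi_id, .data$condition
    ),
    mean = mean(.data$n_fixations, na.rm = TRUE),
    sem = sd(.data$n_fixations, na.rm = TRUE) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  d$roi_id <- factor(d$roi_id, levels = rois)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$roi_id, y = .data$mean, fill = .data$condition
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::labs(
      x = NULL, y = "Fixations per trial", fill = "AI condition",
      title = "Gaze fixations by ROI and AI safety condition"
    ) +
    ggplot2::theme_minimal()
}

#' Per-ROI fixation duration and blink rate
#'
#' Mirrors the two-panel summary of mean fixation duration and blink rate by
#' region of interest (mean and SEM over trials).
#'
#' @param attention Attention rows from [summarize_attention()].
#' @return A ggplot object (facetted).
#' @export
plot_roi_metrics <- function(attention) {
  d <- tidyr::pivot_longer(
    dplyr::filter(attention, .data$roi_id %in% c(major_rois, xai_rois)),
    c("mean_fixation_duration_ms", "blink_rate_bpm"),
    names_to = "metric", values_to = "value"
  )
  d <- dplyr::summarise(
    dplyr::group_by(d, .data$roi_id, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .groups = "drop"
  )
  d$surface <- ifelse(d$roi_id %in% conventional_rois, "clinical", "AI/XAI")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$roi_id, y = .data$mean, fill = .data$surface
  )) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.25
    ) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Surface") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter of an attention metric against a behaviour metric
#'
#' @param joined Analysis table from [join_behaviour_attention()].
#' @param x,y Column names (strings) to plot.
#' @return A ggplot object facetted by drug and condition.
#' @export
plot_behaviour_scatter <- function(joined, x = "influence_clamped",
                                   y = "n_fixations_ai_screen") {
  ggplot2::ggplot(joined, ggplot2::aes(
    x = .data[[x]], y = .data[[y]], colour = .data$seniority
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_grid(drug ~ condition, scales = "free") +
    ggplot2::labs(x = x, y = y, colour = "Seniority") +
    ggplot2::theme_minimal()
}

#' @method autoplot gaze_report
#' @export
autoplot.gaze_report <- function(object, ...) {
  d <- object$comparisons
  d <- d[!is.na(d$statistic), ]
  dd <- tidyr::pivot_longer(
    d[c("comparison", "mean_1", "mean_2")],
    c("mean_1", "mean_2"),
    names_to = "group", values_to = "mean"
  )
  dd$group <- ifelse(dd$group == "mean_1", d$group_1[match(dd$comparison, d$comparison)],
    d$group_2[match(dd$comparison, d$comparison)]
  )
  ggplot2::ggplot(dd, ggplot2::aes(
    x = .data$comparison, y = .data$mean, fill = .data$group
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Group mean", fill = NULL) +
    ggplot2::theme_minimal()
}
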
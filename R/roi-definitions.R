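#' Region-of-interest definitions
#'
#' ROIs form a forest: the AI display screen is a super-set that encloses the
#' AI-recommendation panel and the four explanation (XAI) panels, while the
#' patient mannequin, vital-signs monitor and paper ICU chart stand alone.
#' A definitions table has one row per ROI with its identifier, a display
#' label, and `parent_id` (`NA` for a root).
#'
#' @param roi_id Character vector of unique ROI identifiers.
#' @param label Human-readable labels (defaults to `roi_id`).
#' @param parent_id Identifier of the enclosing ROI, `NA` for roots.
#'
#' @return A tibble of class `roi_definitions` with columns
#'   `roi_id`, `label`, `parent_id`.
#' @examples
#' roi_definitions(
#'   roi_id = c("screen", "panel"),
#'   parent_id = c(NA, "screen")
#' )
#' @export
roi_definitions <- function(roi_id, label = roi_id, parent_id = NA_character_) {
  defs <- tibble::tibble(
    roi_id = as.character(roi_id),
    label = as.character(label),
    parent_id = as.character(rep_len(parent_id, length(roi_id)))
  )
  validate_roi_definitions(defs)
}

validate_roi_definitions <- function(defs) {
  if (!all(c("roi_id", "label", "parent_id") %in% names(defs))) {
    abort("ROI definitions need columns roi_id, label, parent_id.")
  }
  if (anyDuplicated(defs$roi_id)) {
    abort("Duplicate roi_id in ROI definitions.")
  }
  known <- defs$parent_id %in% defs$roi_id | is.na(defs$parent_id)
  if (!all(known)) {
    abort(paste0(
      "Unknown parent_id: ",
      paste(unique(defs$parent_id[!known]), collapse = ", ")
    ))
  }
  # forest check: following parents must terminate (no cycles)
  for (id in defs$roi_id) {
    seen <- character()
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) abort(paste0("Cycle in ROI parent graph at '", cur, "'."))
      seen <- c(seen, cur)
      cur <- defs$parent_id[match(cur, defs$roi_id)]
    }
  }
  defs <- tibble::as_tibble(defs)[, c("roi_id", "label", "parent_id")]
  class(defs) <- c("roi_definitions", class(defs))
  defs
}

#' Default simulation-suite ROI set
#'
#' The four principal regions — patient mannequin, vital-signs monitor, paper
#' ICU data chart and AI display screen — plus the AI-recommendation panel and
#' the four explanation panels (Q-value difference, predicted mortality
#' change, feature importance, influential training examples), all children of
#' the AI screen.
#'
#' @return A `roi_definitions` tibble with nine rows.
#' @examples
#' default_roi_definitions()
#' @export
default_roi_definitions <- function() {
  roi_definitions(
    roi_id = c(
      "mannequin", "monitor", "chart", "ai_screen",
      "ai_recommendation", "xai_qdiff", "xai_mortality",
      "xai_features", "xai_examples"
    ),
    label = c(
      "Patient mannequin", "Vital signs monitor", "ICU data chart",
      "AI display screen", "AI recommendation", "XAI: Q-value difference",
      "XAI: predicted mortality", "XAI: feature importance",
      "XAI: training examples"
    ),
    parent_id = c(rep(NA_character_, 4), rep("ai_screen", 5))
  )
}

#' Read ROI definitions from a YAML or JSON config
#'
#' The file maps each `roi_id` to a `label` and optional `parent_id`, e.g.
#' `ai_screen: {label: AI display screen}` and
#' `xai_qdiff: {label: ..., parent_id: ai_screen}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `roi_definitions` tibble.
#' @export
read_roi_definitions <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  roi_definitions(
    roi_id = names(raw),
    label = purrr::map_chr(raw, function(x) x$label %||% NA_character_),
    parent_id = purrr::map_chr(raw, function(x) x$parent_id %||% NA_character_)
  )
}

#' Write ROI definitions to YAML
#'
#' @param defs A `roi_definitions` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_definitions <- function(defs, path) {
  defs <- validate_roi_definitions(defs)
  lst <- purrr::pmap(defs, function(roi_id, label, parent_id) {
    out <- list(label = label)
    if (!is.na(parent_id)) out$parent_id <- parent_id
    out
  })
  names(lst) <- defs$roi_id
  yaml::write_yaml(lst, path)
  invisible(path)
}

# all ancestors of each roi_id, as a named list (excludes self)
roi_ancestors <- function(defs) {
  parent <- setNames(defs$parent_id, defs$roi_id)
  out <- lapply(defs$roi_id, function(id) {
    anc <- character()
    cur <- parent[[id]]
    while (!is.na(cur)) {
      anc <- c(anc, cur)
      cur <- parent[[cur]]
    }
    anc
  })
  names(out) <- defs$roi_id
  out
}
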
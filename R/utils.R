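#' @importFrom rlang %||%
NULL

# quiet readr csv read with required-column check
read_csv_strict <- function(path, required, what) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0(
      "Malformed ", what, " file '", path, "': missing column",
      if (length(missing) > 1) "s" else "", " ",
      paste(missing, collapse = ", "), "."
    ))
  }
  x
}

#' Quality-control report attached to an ingested table
#'
#' Readers attach a QC report (row counts, flags, notes) to their result;
#' `qc_report()` retrieves it.
#'
#' @param x A table returned by one of the `read_*()` functions or by
#'   [summarize_attention()].
#' @return A list (contents depend on the producing function), or `NULL`.
#' @export
qc_report <- function(x) attr(x, "qc", exact = TRUE)

set_qc <- function(x, qc) {
  attr(x, "qc") <- qc
  x
}

stopifnot_sorted <- function(t, what = "samples") {
  if (is.unsorted(t)) {
    abort(paste0(what, " must be sorted by time; got non-monotone timestamps."))
  }
}
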
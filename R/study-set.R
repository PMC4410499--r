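#' Validate a set of study-level estimates
#'
#' A study set is the input unit of a meta-analysis: one row per study with an
#' estimated effect and its standard error.  `as_study_set()` checks the
#' invariants every downstream computation relies on (at least two studies,
#' finite effects, strictly positive finite standard errors) and returns a
#' tibble with columns `study`, `effect`, `se`.
#'
#' @param data A data frame with numeric columns `effect` and `se`, and
#'   optionally a `study` identifier column.  Extra columns are dropped.
#' @return A tibble with columns `study` (character), `effect`, `se`.
#' @examples
#' as_study_set(data.frame(effect = c(0.2, 0.5, -0.1), se = c(0.1, 0.2, 0.15)))
#' @export
as_study_set <- function(data) {
  if (!is.data.frame(data)) {
    abort_invalid("`data` must be a data frame of study-level estimates.")
  }
  missing_cols <- setdiff(c("effect", "se"), names(data))
  if (length(missing_cols) > 0) {
    abort_invalid(sprintf(
      "`data` must have columns `effect` and `se`; missing: %s.",
      paste0("`", missing_cols, "`", collapse = ", ")
    ))
  }
  effect <- data[["effect"]]
  se <- data[["se"]]
  if (!is.numeric(effect) || !is.numeric(se)) {
    abort_invalid("Columns `effect` and `se` must be numeric.")
  }
  if (nrow(data) < 2L) {
    abort_invalid(sprintf(
      "A meta-analysis needs at least 2 studies; got %d.", nrow(data)
    ))
  }
  bad_effect <- which(!is.finite(effect))
  if (length(bad_effect) > 0) {
    abort_invalid(sprintf(
      "Every effect must be finite; offending row(s): %s.",
      paste(bad_effect, collapse = ", ")
    ))
  }
  bad_se <- which(!is.finite(se) | se <= 0)
  if (length(bad_se) > 0) {
    abort_invalid(sprintf(
      "Every standard error must be finite and > 0; offending row(s): %s.",
      paste(bad_se, collapse = ", ")
    ))
  }
  study <- if ("study" %in% names(data)) {
    as.character(data[["study"]])
  } else {
    paste0("study_", seq_len(nrow(data)))
  }
  tibble(study = study, effect = as.numeric(effect), se = as.numeric(se))
}

#' Read study-level estimates from a CSV file
#'
#' Reads a UTF-8 comma-separated file with a header row containing at least
#' the columns `study`, `effect`, `se` (extra columns are ignored).  Rows with
#' a missing or non-numeric effect or standard error are rejected with a
#' message naming the offending data line(s).
#'
#' @param file Path to the CSV file.
#' @return A validated study-set tibble (see [as_study_set()]).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("study,effect,se", "a,0.1,0.2", "b,0.4,0.25"), path)
#' read_studies(path)
#' @export
read_studies <- function(file) {
  if (!is.character(file) || length(file) != 1L) {
    abort_invalid("`file` must be a single file path.")
  }
  if (!file.exists(file)) {
    abort_invalid(sprintf("File not found: %s", file))
  }
  raw <- readr::read_csv(
    file,
    col_types = readr::cols(.default = readr::col_guess()),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(c("study", "effect", "se"), names(raw))
  if (length(missing_cols) > 0) {
    abort_invalid(sprintf(
      "%s: header must contain `study,effect,se`; missing: %s.",
      file, paste0("`", missing_cols, "`", collapse = ", ")
    ))
  }
  effect <- suppressWarnings(as.numeric(raw[["effect"]]))
  se <- suppressWarnings(as.numeric(raw[["se"]]))
  # +1 for the header row: report physical line numbers in the file
  bad <- which(!is.finite(effect) | !is.finite(se) | se <= 0)
  if (length(bad) > 0) {
    abort_invalid(sprintf(
      "%s: missing or invalid effect/se on line(s) %s.",
      file, paste(bad + 1L, collapse = ", ")
    ))
  }
  as_study_set(tibble(study = raw[["study"]], effect = effect, se = se))
}
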
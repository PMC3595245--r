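#' Validate an assessment table
#'
#' An assessment table holds one row per patient visit: `patient_id`,
#' `visit_index`, `visit_year`, then the 56 binary symptom flags named as in
#' [flag_columns()]. Validation enforces the full schema: every flag column
#' present, every flag 0 or 1 with no missing values (a partially recorded
#' visit is rejected, not zero-filled), unique `(patient_id, visit_index)`
#' pairs and strictly increasing visit indices within a patient.
#'
#' @param table A data frame of assessments.
#' @return The validated table, invisibly, as a tibble with columns in
#'   canonical order.
#' @export
validate_assessments <- function(table) {
  table <- tibble::as_tibble(table)
  required <- c("patient_id", "visit_index", "visit_year", flag_columns())
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    stop("assessment table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in flag_columns()) {
    v <- table[[col]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad) > 0) {
      stop(sprintf("non-binary or missing flag in column '%s', row %d (value: %s)",
                   col, bad[1], as.character(v[bad[1]])), call. = FALSE)
    }
  }
  key <- paste(table$patient_id, table$visit_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (patient_id, visit_index): ",
         gsub("\r", ", visit ", dup), call. = FALSE)
  }
  inc <- table |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = all(diff(.data$visit_index) > 0), .groups = "drop")
  if (!all(inc$ok)) {
    stop("visit_index not strictly increasing for patient(s): ",
         paste(inc$patient_id[!inc$ok], collapse = ", "), call. = FALSE)
  }
  out <- table |>
    dplyr::select("patient_id", "visit_index", "visit_year",
                  dplyr::all_of(flag_columns())) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(flag_columns()), as.integer))
  invisible(out)
}

#' Read an assessment table from CSV
#'
#' Reads a UTF-8 CSV with header `patient_id, visit_index, visit_year` then
#' the 56 flag columns in the canonical `<side>_<site>_<symptom>` naming
#' (any column order is accepted; the returned tibble is in canonical order).
#' Flags must be 0/1; any missing or non-binary cell is an error naming the
#' offending row and column.
#'
#' @param path Path to a CSV file.
#' @param provenance Optional free-text label attached to the result as the
#'   `"provenance"` attribute.
#' @return A validated tibble of assessments.
#' @seealso [write_assessments()], [validate_assessments()]
#' @export
read_assessments <- function(path, provenance = basename(path)) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- validate_assessments(raw)
  attr(out, "provenance") <- provenance
  out
}

#' Write an assessment table to CSV
#'
#' The on-disk format is a lossless round trip of [read_assessments()]:
#' flags are written as integers 0/1, columns in canonical order.
#'
#' @param table A valid assessment table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(table, path) {
  out <- validate_assessments(table)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Canonical modified-Sharp element columns
#'
#' Hand joint destruction is scored per side for two elements (erosion,
#' joint-space narrowing) in three regions: MCP, PIP and wrist (the hand
#' joints other than MCP and PIP). This yields 12 element columns named
#' `<side>_<region>_<element>`, e.g. `r_mcp_erosion`.
#'
#' @return Character vector of the 12 element column names.
#' @export
sharp_elements <- function() {
  grid <- expand.grid(side = c("l", "r"),
                      element = c("erosion", "narrowing"),
                      region = c("mcp", "pip", "wrist"),
                      stringsAsFactors = FALSE)
  paste(grid$side, grid$region, grid$element, sep = "_")
}

#' Default full (maximum) scores for the Sharp elements
#'
#' Full scores normalise summed element scores into destruction rates.
#' MCP and PIP defaults follow the van der Heijde convention (erosion max 5
#' and narrowing max 4 per joint, 5 joints per hand: 25 and 20 per side).
#' The wrist (large and wrist) group full score is fixed at 108 in total,
#' split here as 30 erosion + 24 narrowing per side; the split is
#' configuration, the 108 total is the reference value.
#'
#' @return Named numeric vector over [sharp_elements()].
#' @export
#' @examples
#' fs <- sharp_full_scores()
#' sum(fs[grep("wrist", names(fs))])  # 108
sharp_full_scores <- function() {
  fs <- c(
    l_mcp_erosion = 25, r_mcp_erosion = 25,
    l_mcp_narrowing = 20, r_mcp_narrowing = 20,
    l_pip_erosion = 25, r_pip_erosion = 25,
    l_pip_narrowing = 20, r_pip_narrowing = 20,
    l_wrist_erosion = 30, r_wrist_erosion = 30,
    l_wrist_narrowing = 24, r_wrist_narrowing = 24
  )
  fs[sharp_elements()]
}

#' Validate a Sharp score table
#'
#' One row per patient: `patient_id` then the 12 element columns of
#' [sharp_elements()]. Scores must be nonnegative and no larger than the
#' configured full score for their element.
#'
#' @param table A data frame of Sharp scores.
#' @param full_scores Named vector of element full scores
#'   (default [sharp_full_scores()]).
#' @return The validated tibble, invisibly.
#' @export
validate_sharp <- function(table, full_scores = sharp_full_scores()) {
  table <- tibble::as_tibble(table)
  required <- c("patient_id", sharp_elements())
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    stop("Sharp table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$patient_id)) {
    stop("duplicate patient_id in Sharp table", call. = FALSE)
  }
  for (col in sharp_elements()) {
    v <- table[[col]]
    bad <- which(is.na(v) | v < 0 | v > full_scores[[col]])
    if (length(bad) > 0) {
      stop(sprintf("score out of range [0, %g] in column '%s', row %d (value: %s)",
                   full_scores[[col]], col, bad[1], as.character(v[bad[1]])),
           call. = FALSE)
    }
  }
  invisible(dplyr::select(table, "patient_id", dplyr::all_of(sharp_elements())))
}

#' Read / write a Sharp score table
#'
#' @param path CSV path.
#' @param full_scores Named vector of element full scores used for
#'   validation.
#' @return `read_sharp()`: a validated tibble. `write_sharp()`: `path`,
#'   invisibly.
#' @export
read_sharp <- function(path, full_scores = sharp_full_scores()) {
  validate_sharp(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
                 full_scores)
}

#' @rdname read_sharp
#' @param table A valid Sharp table.
#' @export
write_sharp <- function(table, path, full_scores = sharp_full_scores()) {
  out <- validate_sharp(table, full_scores)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
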
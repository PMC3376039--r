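# CSV dialect is pinned: UTF-8, comma separator, ISO-8601 dates, "."
# decimal. Validation is collected, not first-fail: every violation is
# reported with its row and column in one condition.

validation_stop <- function(violations) {
  msg <- paste0("validation failed (", nrow(violations), " violation(s)):\n",
                paste(sprintf("  row %s, column %s: %s", violations$row,
                              violations$column, violations$message),
                      collapse = "\n"))
  stop(errorCondition(msg, violations = violations,
                      class = c("nephest_validation_error", "error")))
}

add_violation <- function(v, row, column, message) {
  rbind(v, data.frame(row = row, column = column, message = message,
                      stringsAsFactors = FALSE))
}

empty_violations <- function() {
  data.frame(row = integer(), column = character(), message = character(),
             stringsAsFactors = FALSE)
}

check_columns <- function(df, required, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(errorCondition(
      paste0(path, ": missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = c("nephest_validation_error", "error")))
}

parse_iso_dates <- function(x, column, v) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  for (i in bad) v <- add_violation(v, i, column, paste0(
    "malformed date '", x[i], "' (expected YYYY-MM-DD)"))
  list(dates = d, violations = v)
}

check_positive <- function(df, column, v, strict = TRUE) {
  x <- df[[column]]
  bad <- which(is.finite(x) & (if (strict) x <= 0 else x < 0))
  for (i in bad) v <- add_violation(v, i, column, paste0(
    "must be ", if (strict) "> 0" else ">= 0", " (got ", x[i], ")"))
  v
}

#' Read a biopsy sections table
#'
#' Schema: `patient_id`, `section_id`, `cortex_segment_lengths`
#' (semicolon-separated mm, on-slide), `n_glomeruli`,
#' `n_global_sclerosis`, `needle_gauge`, `stain`.
#'
#' @param path CSV file.
#' @return validated data frame with a parsed `segment_lengths_mm`
#'   list-column.
#' @export
read_sections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "section_id", "cortex_segment_lengths",
                      "n_glomeruli", "n_global_sclerosis", "needle_gauge"),
                path)
  v <- empty_violations()
  seg <- lapply(strsplit(as.character(df$cortex_segment_lengths), ";"),
                function(s) suppressWarnings(as.numeric(s)))
  for (i in seq_along(seg)) {
    if (anyNA(seg[[i]]) || any(seg[[i]] < 0))
      v <- add_violation(v, i, "cortex_segment_lengths",
                         "lengths must be numeric and >= 0")
  }
  for (col in c("n_glomeruli", "n_global_sclerosis")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    for (i in bad) v <- add_violation(v, i, col, "must be a count >= 0")
  }
  bad <- which(df$n_global_sclerosis > df$n_glomeruli)
  for (i in bad) v <- add_violation(v, i, "n_global_sclerosis",
                                    "cannot exceed n_glomeruli")
  if (nrow(v)) validation_stop(v)
  df$segment_lengths_mm <- seg
  df
}

#' Assemble biopsy specimens from a sections table
#'
#' @param sections a validated [read_sections()] data frame (or one built
#'   in code with the same columns).
#' @return named list of [biopsy_specimen()], one per patient.
#' @export
specimens_from_sections <- function(sections) {
  ids <- unique(sections$patient_id)
  out <- lapply(ids, function(id) {
    rows <- sections[sections$patient_id == id, , drop = FALSE]
    secs <- lapply(seq_len(nrow(rows)), function(i)
      biopsy_section(rows$segment_lengths_mm[[i]], rows$n_glomeruli[i],
                     rows$n_global_sclerosis[i]))
    biopsy_specimen(secs, rows$needle_gauge[1],
                    stain = rows$stain[1] %||% "PAS")
  })
  names(out) <- ids
  out
}

#' Read a tomographic slice-areas table
#'
#' Schema: `patient_id`, `side`, `slice_index`, `kidney_area_cm2`,
#' `cortex_area_cm2`, `spacing_cm`.
#'
#' @param path CSV file.
#' @return validated data frame.
#' @export
read_volumes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "side", "slice_index",
                      "kidney_area_cm2", "cortex_area_cm2", "spacing_cm"),
                path)
  v <- empty_violations()
  for (col in c("kidney_area_cm2", "cortex_area_cm2")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    for (i in bad) v <- add_violation(v, i, col, "must be >= 0")
  }
  v <- check_positive(df, "spacing_cm", v)
  bad <- which(df$cortex_area_cm2 > df$kidney_area_cm2)
  for (i in bad) v <- add_violation(v, i, "cortex_area_cm2",
                                    "exceeds kidney_area_cm2")
  if (nrow(v)) validation_stop(v)
  df
}

#' Read an enrollment registry table
#'
#' Schema (core registry fields required, extras pass through):
#' `patient_id`, `biopsy_date`, `age`, `sex`, `serum_creatinine`,
#' `birth_weight_g`, plus free columns (ultrasound axes, body weight,
#' diagnosis, ...).
#'
#' @param path CSV file.
#' @return validated data frame with `biopsy_date` as `Date`.
#' @export
read_enrollment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "biopsy_date", "age", "sex",
                      "serum_creatinine", "birth_weight_g"), path)
  v <- empty_violations()
  pd <- parse_iso_dates(df$biopsy_date, "biopsy_date", v)
  v <- pd$violations
  v <- check_positive(df, "age", v)
  v <- check_positive(df, "serum_creatinine", v)
  bad <- which(!df$sex %in% c("male", "female"))
  for (i in bad) v <- add_violation(v, i, "sex",
                                    "must be 'male' or 'female'")
  dup <- which(duplicated(df$patient_id))
  for (i in dup) v <- add_violation(v, i, "patient_id", "duplicate patient")
  if (nrow(v)) validation_stop(v)
  df$biopsy_date <- pd$dates
  df
}

#' Read a follow-up registry table
#'
#' Schema: `patient_id`, `visit_date`, `serum_creatinine`, plus optional
#' `body_weight_kg`, `urinary_protein_gday`, `raas_blocker`, `status`,
#' event columns (`event_type`, `event_date`, adjudication criteria).
#' When the enrollment table is supplied, each visit is compared against
#' its scheduled anniversary of the biopsy: data within three months of
#' the scheduled date is the protocol's tolerance, recorded per row in
#' `within_window` / `months_off_schedule` (off-window rows are kept,
#' flagged).
#'
#' @param path CSV file.
#' @param enrollment optional [read_enrollment()] table for window flags.
#' @return validated data frame, `visit_date` as `Date`.
#' @export
read_followup <- function(path, enrollment = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "visit_date", "serum_creatinine"),
                path)
  v <- empty_violations()
  pd <- parse_iso_dates(df$visit_date, "visit_date", v)
  v <- pd$violations
  v <- check_positive(df, "serum_creatinine", v)
  dup <- which(duplicated(df[, c("patient_id", "visit_date")]))
  for (i in dup) v <- add_violation(v, i, "visit_date",
                                    "duplicate patient visit")
  if ("event_date" %in% names(df)) {
    ed <- parse_iso_dates(df$event_date, "event_date", v)
    v <- ed$violations
  }
  if (nrow(v)) validation_stop(v)
  df$visit_date <- pd$dates
  if ("event_date" %in% names(df))
    df$event_date <- as.Date(as.character(df$event_date),
                             format = "%Y-%m-%d")
  if (!is.null(enrollment)) {
    base <- enrollment$biopsy_date[match(df$patient_id,
                                         enrollment$patient_id)]
    yrs <- years_between(base, df$visit_date)
    yrs[is.na(base)] <- NA
    off <- (yrs - round(yrs)) * 12
    df$months_off_schedule <- round(off, 2)
    df$within_window <- abs(off) <= 3
  }
  df
}

#' Write a registry or measurement table in the pinned CSV dialect
#'
#' @param df data frame (list-columns are re-serialised with semicolons).
#' @param path output CSV path.
#' @export
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ";")
    if (inherits(df[[col]], "Date"))
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
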
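#' @name registry
#' @title Claims registry tables
#'
#' @description
#' The package works on three plain CSV tables mirroring a national
#' e-prescription export:
#'
#' * `prescriptions.csv`: `prescription_id,patient_id,issue_date,atc_code,tablets`
#' * `dispensations.csv`: `prescription_id,patient_id,dispense_date,tablets`
#' * `patients.csv`: `patient_id,sex,birth_year,death_date` (`death_date`
#'   may be empty; `sex` is `F`, `M` or empty for missing)
#'
#' Dates are ISO-8601 (`YYYY-MM-DD`). One prescription line is one issued
#' e-prescription for one product; quantities are tablets. A dispensation
#' references its prescription and may carry fewer tablets (partial fill);
#' a prescription may be filled in several partial events, which downstream
#' supply arithmetic simply sums.
NULL

rxflow_log <- function(data, log) {
  attr(data, "rxflow_log") <- log
  data
}

#' Retrieve the row-level diagnostics attached by a reader
#'
#' @param x A tibble returned by [read_registry()] components.
#' @return A tibble of diagnostics (possibly empty) with columns `table`,
#'   `issue` and `n`.
#' @export
reader_log <- function(x) {
  attr(x, "rxflow_log") %||% tibble(table = character(), issue = character(), n = integer())
}

parse_date_col <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(suppressWarnings(lubridate::ymd(as.character(x))))
}

clean_table <- function(df, table, date_col, require_pos_tablets = TRUE,
                        schema, quiet = FALSE) {
  log <- tibble(table = character(), issue = character(), n = integer())
  extra <- setdiff(names(df), schema)
  if (length(extra)) {
    # schema anomalies always warn; `quiet` only silences row-level notes
    warn(paste0(table, ": ignoring unknown column(s) ",
                paste(extra, collapse = ", ")))
    df <- df[intersect(names(df), schema)]
  }
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    abort(paste0(table, ": missing required column(s) ",
                 paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)[schema]
  if (!is.null(date_col)) {
    df[[date_col]] <- parse_date_col(df[[date_col]])
    bad_date <- is.na(df[[date_col]])
    if (any(bad_date)) {
      log <- add_row(log, table = table, issue = "malformed_date",
                     n = sum(bad_date))
      df <- df[!bad_date, ]
    }
  }
  if (require_pos_tablets && "tablets" %in% schema) {
    df$tablets <- suppressWarnings(as.integer(df$tablets))
    bad_tab <- is.na(df$tablets) | df$tablets < 1L
    if (any(bad_tab)) {
      log <- add_row(log, table = table, issue = "invalid_tablets",
                     n = sum(bad_tab))
      df <- df[!bad_tab, ]
    }
  }
  dup <- duplicated(df)
  if (any(dup)) {
    log <- add_row(log, table = table, issue = "exact_duplicate",
                   n = sum(dup))
    df <- df[!dup, ]
  }
  if (!quiet && nrow(log)) {
    inform(paste0(table, ": dropped ", sum(log$n), " row(s) (",
                  paste(sprintf("%s: %d", log$issue, log$n), collapse = "; "),
                  ")"))
  }
  rxflow_log(df, log)
}

#' Read a claims registry from CSV files
#'
#' Parses and validates the three registry tables (see [registry]). Rows
#' with malformed dates or non-positive tablet counts are rejected and
#' counted; exact duplicate rows are dropped (double exports are common in
#' registry dumps); unknown columns are ignored with a warning. Per-table
#' diagnostics are attached and retrievable with [reader_log()].
#'
#' @param prescriptions_path,dispensations_path,patients_path CSV paths.
#'   `patients_path` may be `NULL` when demographic data are not needed.
#' @param quiet Suppress informational messages about dropped rows.
#' @return A list with tibbles `prescriptions`, `dispensations`, `patients`.
#' @seealso [write_registry()] for the inverse operation.
#' @export
read_registry <- function(prescriptions_path, dispensations_path,
                          patients_path = NULL, quiet = FALSE) {
  rx <- readr::read_csv(prescriptions_path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  rx <- clean_table(rx, "prescriptions", "issue_date",
                    schema = c("prescription_id", "patient_id", "issue_date",
                               "atc_code", "tablets"),
                    quiet = quiet)
  disp <- readr::read_csv(dispensations_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  disp <- clean_table(disp, "dispensations", "dispense_date",
                      schema = c("prescription_id", "patient_id",
                                 "dispense_date", "tablets"),
                      quiet = quiet)
  pat <- NULL
  if (!is.null(patients_path)) {
    pat <- readr::read_csv(patients_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    pat <- clean_table(pat, "patients", NULL, require_pos_tablets = FALSE,
                       schema = c("patient_id", "sex", "birth_year",
                                  "death_date"),
                       quiet = quiet)
    pat$birth_year <- suppressWarnings(as.integer(pat$birth_year))
    pat$death_date <- parse_date_col(pat$death_date)
    pat$sex <- ifelse(is.na(pat$sex) | pat$sex == "", "missing", pat$sex)
  }
  list(prescriptions = rx, dispensations = disp, patients = pat)
}

#' Write a claims registry to CSV files
#'
#' Field-for-field inverse of [read_registry()]: reading the written files
#' back reproduces the records.
#'
#' @param registry A list with `prescriptions`, `dispensations` and
#'   optionally `patients` tibbles.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    prescriptions = file.path(dir, "prescriptions.csv"),
    dispensations = file.path(dir, "dispensations.csv")
  )
  readr::write_csv(registry$prescriptions, paths[["prescriptions"]])
  readr::write_csv(registry$dispensations, paths[["dispensations"]])
  if (!is.null(registry$patients)) {
    paths <- c(paths, patients = file.path(dir, "patients.csv"))
    readr::write_csv(registry$patients, paths[["patients"]])
  }
  invisible(paths)
}

#' ATC codes retained by the statin inclusion filter
#'
#' Plain statins (any code under C10AA, the HMG-CoA reductase inhibitors)
#' plus the fixed combinations of statins with other lipid-modifying agents
#' (C10BA01-C10BA09, C10BA11, C10BA12). Fixed-dose combinations of statins
#' with non-lipid-lowering drugs (C10BX) and other lipid-lowering agents
#' (ezetimibe C10AX09, fibrates C10AB) are excluded.
#'
#' @return A list with `prefix` (character) and `exact` (character vector).
#' @export
statin_atc_codes <- function() {
  list(
    prefix = "C10AA",
    exact = paste0("C10BA", sprintf("%02d", c(1:9, 11, 12)))
  )
}

#' Keep only statin events
#'
#' Filters an event table on its `atc_code` column according to
#' [statin_atc_codes()]. Empty or too-short codes are excluded with a
#' warning. The operation is idempotent and its output is always a subset
#' of its input.
#'
#' @param events A tibble with an `atc_code` column (typically
#'   prescriptions).
#' @return The filtered tibble.
#' @examples
#' ev <- tibble::tibble(atc_code = c("C10AA05", "C10BA02", "C10BX03"))
#' filter_statin_atc(ev)
#' @export
filter_statin_atc <- function(events) {
  codes <- statin_atc_codes()
  atc <- events$atc_code
  bad <- is.na(atc) | nchar(atc) < 5
  if (any(bad)) {
    warn(sprintf("%d event(s) with missing or too-short ATC code excluded",
                 sum(bad)))
  }
  keep <- !bad & (startsWith(atc, codes$prefix) | atc %in% codes$exact)
  events[keep, , drop = FALSE]
}

#' Patients fulfilling the dispensation inclusion criterion
#'
#' A patient enters the analysed cohort by having at least one (statin)
#' dispensation inside the study window; patients who were only prescribed,
#' never dispensed, are excluded.
#'
#' @param dispensations Dispensation events (already statin-filtered).
#' @param window A [study_window()].
#' @return Character vector of included patient ids.
#' @export
include_patients <- function(dispensations, window = study_window()) {
  window <- as_study_window(window)
  dispensations |>
    filter(.data$dispense_date >= window$start,
           .data$dispense_date <= window$end) |>
    distinct(.data$patient_id) |>
    pull(.data$patient_id)
}
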
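#' @title Validated readers and writers for the four linked EHR tables
#'
#' @description The analysis consumes four longitudinal CSV tables keyed by
#' `patient_id`: `patients` (one row per person), `prescriptions` (one row
#' per dated drug issue), `diagnoses` (dated condition events) and `labs`
#' (dated laboratory measurements). [read_ehr_table()] parses a CSV with a
#' declared schema, coerces ISO-8601 dates, validates every categorical
#' column against the closed vocabularies, and reports schema errors by
#' column name and value errors by row index. [write_ehr_table()] is its
#' lossless inverse.
#'
#' Duplicate `(patient_id, issue_date, drug)` prescription rows are kept:
#' re-issues on the same day are legitimate in source data and are collapsed
#' only where an algorithm requires it (supply-episode construction).
#'
#' @name ehr_io
NULL

ehr_schemas <- list(
  patients = list(
    columns = c(
      "patient_id", "sex", "birth_year", "region", "registration_start",
      "registration_end", "death_date", "practice_last_collection"
    ),
    dates = c("registration_start", "registration_end", "death_date", "practice_last_collection"),
    required = c("patient_id", "sex", "birth_year", "region", "registration_start")
  ),
  prescriptions = list(
    columns = c("patient_id", "issue_date", "drug"),
    dates = "issue_date",
    required = c("patient_id", "issue_date", "drug")
  ),
  diagnoses = list(
    columns = c("patient_id", "event_date", "condition", "source"),
    dates = "event_date",
    required = c("patient_id", "event_date", "condition", "source")
  ),
  labs = list(
    columns = c("patient_id", "date", "analyte", "value"),
    dates = "date",
    required = c("patient_id", "date", "analyte", "value")
  )
)

#' @rdname ehr_io
#' @export
ehr_table_kinds <- names(ehr_schemas)

parse_iso_dates <- function(df, cols, kind) {
  for (col in cols) {
    raw <- df[[col]]
    if (inherits(raw, "Date")) next
    raw <- as.character(raw)
    parsed <- as.Date(raw, format = "%Y-%m-%d")
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: column '%s' has unparsable date(s) at row(s) %s (expected ISO-8601)",
        kind, col, paste(head(bad, 5), collapse = ", ")
      ))
    }
    parsed[!is.na(raw) & raw == ""] <- NA
    df[[col]] <- parsed
  }
  df
}

check_enum <- function(values, allowed, kind, col) {
  bad <- which(!is.na(values) & !(values %in% allowed))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: column '%s' has value(s) outside the closed set at row(s) %s: %s",
      kind, col, paste(head(bad, 5), collapse = ", "),
      paste(unique(values[head(bad, 5)]), collapse = ", ")
    ))
  }
  invisible(values)
}

#' Validate an in-memory EHR table against its schema
#'
#' @param df A data frame.
#' @param kind One of `"patients"`, `"prescriptions"`, `"diagnoses"`,
#'   `"labs"`.
#' @return The validated tibble, invisibly coerced (dates as `Date`,
#'   prescriptions gain a derived `drug_class` column).
#' @export
validate_ehr_table <- function(df, kind) {
  kind <- match.arg(kind, ehr_table_kinds)
  schema <- ehr_schemas[[kind]]
  missing_cols <- setdiff(schema$columns, names(df))
  # drug_class is derived, never required on disk
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s: missing column(s): %s", kind, paste(missing_cols, collapse = ", ")
    ))
  }
  df <- as_tibble(df)[, schema$columns]
  df <- parse_iso_dates(df, schema$dates, kind)

  for (col in schema$required) {
    if (anyNA(df[[col]])) {
      bad <- which(is.na(df[[col]]))
      abort(sprintf(
        "%s: required column '%s' is missing at row(s) %s",
        kind, col, paste(head(bad, 5), collapse = ", ")
      ))
    }
  }

  if (kind == "patients") {
    check_enum(df$sex, sex_levels, kind, "sex")
    df$birth_year <- as.integer(df$birth_year)
    end_candidates <- pmin(df$registration_end, df$death_date,
      df$practice_last_collection,
      na.rm = TRUE
    )
    bad <- which(!is.na(end_candidates) & df$registration_start >= end_candidates)
    if (length(bad) > 0) {
      abort(sprintf(
        "patients: registration_start not before end anchors at row(s) %s",
        paste(head(bad, 5), collapse = ", ")
      ))
    }
  } else if (kind == "prescriptions") {
    check_enum(df$drug, antithrombotic_drugs, kind, "drug")
    df$drug_class <- drug_class(df$drug)
  } else if (kind == "diagnoses") {
    check_enum(df$condition, condition_levels, kind, "condition")
    check_enum(df$source, diagnosis_sources, kind, "source")
  } else if (kind == "labs") {
    check_enum(df$analyte, analyte_levels, kind, "analyte")
    df$value <- as.numeric(df$value)
    bad <- which(!(df$value > 0))
    if (length(bad) > 0) {
      abort(sprintf(
        "labs: non-positive value(s) at row(s) %s",
        paste(head(bad, 5), collapse = ", ")
      ))
    }
    inr_bad <- which(df$analyte == "INR" & (df$value <= 0.5 | df$value >= 20))
    if (length(inr_bad) > 0) {
      abort(sprintf(
        "labs: implausible INR outside (0.5, 20) at row(s) %s",
        paste(head(inr_bad, 5), collapse = ", ")
      ))
    }
  }
  df
}

#' Read one EHR table from CSV
#'
#' @param path Path to a CSV file with the exact columns of the declared
#'   schema. Dates must be ISO-8601; empty fields are missing values.
#' @inheritParams validate_ehr_table
#' @return A validated tibble; row order is preserved.
#' @examples
#' dir <- tempdir()
#' rx <- tibble::tibble(
#'   patient_id = "p1",
#'   issue_date = as.Date("2015-03-01"),
#'   drug = "warfarin"
#' )
#' write_ehr_table(rx, file.path(dir, "prescriptions.csv"), "prescriptions")
#' read_ehr_table(file.path(dir, "prescriptions.csv"), "prescriptions")
#' @export
read_ehr_table <- function(path, kind) {
  kind <- match.arg(kind, ehr_table_kinds)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  validate_ehr_table(df, kind)
}

#' Write one EHR table to CSV
#'
#' Dates are written as ISO-8601, missing values as empty fields, and the
#' column order is the schema order, so `read_ehr_table()` recovers the
#' records exactly. The derived `drug_class` column of prescriptions is not
#' written; it is recomputed on read.
#'
#' @param df A validated table (any extra columns are dropped).
#' @param path Output CSV path.
#' @inheritParams validate_ehr_table
#' @return `path`, invisibly.
#' @export
write_ehr_table <- function(df, path, kind) {
  kind <- match.arg(kind, ehr_table_kinds)
  schema <- ehr_schemas[[kind]]
  df <- validate_ehr_table(df, kind)
  out <- df[, schema$columns]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
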
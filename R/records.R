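admin_record_columns <- c(
  "episode_id", "patient_sex", "birth_date", "admission_date",
  "discharge_date", "medication", "route", "dose_qty", "dose_unit",
  "admin_date"
)

#' Read medication administration records
#'
#' Reads a flat delimited file of deidentified inpatient medication
#' administration records (one row per administration event), canonicalizes
#' medication names through the catalog's synonym table and merges route
#' labels. Rows that fail validation (unparseable dates, negative doses,
#' administrations outside the stay, unknown sex) are collected — with their
#' file line numbers — into the `row_errors` attribute rather than silently
#' dropped.
#'
#' Expected columns (CSV, UTF-8, header required, ISO-8601 dates):
#' `episode_id, patient_sex, birth_date, admission_date, discharge_date,
#' medication, route, dose_qty, dose_unit, admin_date`.
#'
#' @param path Path to the CSV file.
#' @param catalog A [med_catalog()]; defaults to an empty catalog (no
#'   canonicalization, no route merging).
#' @return A tibble of valid records with attribute `row_errors`, a tibble
#'   with columns `line` (file line number) and `message`. Retrieve it with
#'   [row_errors()].
#' @export
read_admin_records <- function(path, catalog = med_catalog()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(admin_record_columns, names(raw))
  if (length(missing)) {
    abort(paste0(
      "input is missing required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  raw <- raw[admin_record_columns]
  validate_admin_records(raw, catalog = catalog, line_offset = 1L)
}

#' Validate raw administration records
#'
#' Parses dates and doses, applies the record invariants
#' (`admission <= administration <= discharge`, `birth <= admission`,
#' `dose_qty >= 0`), canonicalizes names and merges routes. Invalid rows go
#' to the `row_errors` attribute.
#'
#' @param data A data frame with the columns listed in
#'   [read_admin_records()] (character or already-typed).
#' @inheritParams read_admin_records
#' @param line_offset Added to row indices when reporting line numbers (1 for
#'   a CSV with a header row).
#' @return A tibble of valid, typed records with attribute `row_errors`.
#' @export
validate_admin_records <- function(data, catalog = med_catalog(),
                                   line_offset = 0L) {
  data <- as_tibble(data)
  n <- nrow(data)
  parse_date <- function(x) as.Date(as.character(x), format = "%Y-%m-%d")
  birth <- parse_date(data$birth_date)
  adm <- parse_date(data$admission_date)
  dis <- parse_date(data$discharge_date)
  given <- parse_date(data$admin_date)
  dose <- suppressWarnings(as.numeric(data$dose_qty))
  sex <- as.character(data$patient_sex)

  problem <- character(n)
  note <- function(bad, msg) {
    bad <- which(bad & problem == "")
    problem[bad] <<- msg
  }
  note(is.na(birth) | is.na(adm) | is.na(dis) | is.na(given),
       "unparseable date (expected ISO-8601)")
  note(is.na(dose), "unparseable dose quantity")
  note(!is.na(dose) & dose < 0, "negative dose quantity")
  note(!is.na(sex) & !sex %in% c("male", "female"),
       "patient_sex must be 'male' or 'female'")
  note(!is.na(birth) & !is.na(adm) & birth > adm,
       "birth_date after admission_date")
  note(!is.na(adm) & !is.na(given) & given < adm,
       "administration before admission")
  note(!is.na(dis) & !is.na(given) & given > dis,
       "administration after discharge")

  bad <- problem != ""
  errors <- tibble(
    line = which(bad) + as.integer(line_offset),
    message = problem[bad]
  )
  out <- tibble(
    episode_id = as.character(data$episode_id)[!bad],
    patient_sex = sex[!bad],
    birth_date = birth[!bad],
    admission_date = adm[!bad],
    discharge_date = dis[!bad],
    medication = canonicalize_medication(
      as.character(data$medication)[!bad], catalog
    ),
    route = merge_route(as.character(data$route)[!bad], catalog),
    dose_qty = dose[!bad],
    dose_unit = as.character(data$dose_unit)[!bad],
    admin_date = given[!bad]
  )
  attr(out, "row_errors") <- errors
  out
}

#' @rdname read_admin_records
#' @param records A tibble returned by [read_admin_records()] or
#'   [validate_admin_records()].
#' @export
row_errors <- function(records) {
  attr(records, "row_errors") %||% tibble(line = integer(), message = character())
}

#' Write administration records as CSV
#'
#' Inverse of [read_admin_records()]: ISO-8601 dates, the documented column
#' order, deterministic output (same records give byte-identical files).
#'
#' @param records A record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_admin_records <- function(records, path) {
  stopifnot(all(admin_record_columns %in% names(records)))
  readr::write_csv(records[admin_record_columns], path, progress = FALSE)
  invisible(path)
}
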
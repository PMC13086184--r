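# Readers and writers for the four input tables.
#
# All files are UTF-8, comma-separated, with a header row; dates are
# ISO-8601. Administration timestamps are truncated to the calendar date on
# read: the unit of analysis throughout is the hospital day.

# Strict ISO date parsing with row-numbered errors. `rows` are file line
# numbers (header = line 1). Accepts a trailing time component ("T.." or
# " ..") which is discarded.
parse_iso_date <- function(x, what, rows, allow_na = FALSE) {
  x <- sub("[T ].*$", "", trimws(as.character(x)))
  empty <- is.na(x) | !nzchar(x)
  shaped <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  x[!shaped] <- NA
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(if (allow_na) !empty & is.na(d) else is.na(d))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: unparseable date '%s' at line %d",
      what, sub("[T ].*$", "", trimws(as.character(x)))[bad[1]], rows[bad[1]]
    ), call. = FALSE)
  }
  d
}

read_input_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s: file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    fileEncoding = "UTF-8", stringsAsFactors = FALSE
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s: missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

validate_atc_rows <- function(codes, what, rows) {
  x <- toupper(gsub("[[:space:]]+", "", as.character(codes)))
  bad <- which(!atc_ok(x))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: invalid ATC code '%s' at line %d",
      what, codes[bad[1]], rows[bad[1]]
    ), call. = FALSE)
  }
  x
}

#' Read drug administration records
#'
#' Expects a CSV with columns `patient_id,date,atc_code` and an optional
#' `drug_label`. Every row is one administration event; duplicated rows are
#' preserved (same-day de-duplication happens downstream, per day). Dates may
#' carry a time component, which is truncated to the calendar date.
#'
#' @param path Path to the administrations CSV.
#' @return A tibble with columns `patient_id`, `date` (Date), `atc_code`
#'   (normalised), `drug_label`.
#' @export
read_administrations <- function(path) {
  df <- read_input_csv(path, c("patient_id", "date", "atc_code"), "administrations")
  rows <- seq_len(nrow(df)) + 1L
  tibble::tibble(
    patient_id = as.character(df$patient_id),
    date = parse_iso_date(df$date, "administrations", rows),
    atc_code = validate_atc_rows(df$atc_code, "administrations", rows),
    drug_label = if ("drug_label" %in% names(df)) {
      lbl <- as.character(df$drug_label)
      ifelse(is.na(lbl) | !nzchar(lbl), NA_character_, lbl)
    } else {
      NA_character_
    }
  )
}

#' Read stay metadata
#'
#' One row per patient (the index stay): `patient_id`, `admission_date`,
#' `discharge_date`, optional `transplant_date`, and `age_years` (age at
#' admission). Errors on duplicated patients, inverted date ranges, or a
#' transplant date outside the stay.
#'
#' @param path Path to the stays CSV.
#' @return A tibble with one validated row per patient.
#' @export
read_stays <- function(path) {
  df <- read_input_csv(
    path, c("patient_id", "admission_date", "discharge_date", "age_years"),
    "stays"
  )
  rows <- seq_len(nrow(df)) + 1L
  out <- tibble::tibble(
    patient_id = as.character(df$patient_id),
    admission_date = parse_iso_date(df$admission_date, "stays", rows),
    discharge_date = parse_iso_date(df$discharge_date, "stays", rows),
    transplant_date = if ("transplant_date" %in% names(df)) {
      parse_iso_date(df$transplant_date, "stays", rows, allow_na = TRUE)
    } else {
      as.Date(rep(NA, nrow(df)))
    },
    age_years = suppressWarnings(as.integer(df$age_years))
  )
  dup <- out$patient_id[duplicated(out$patient_id)]
  if (length(dup) > 0) {
    stop(
      "stays: duplicated patient_id (one index stay per patient): ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  bad_age <- which(is.na(out$age_years) | out$age_years < 0)
  if (length(bad_age) > 0) {
    stop(sprintf(
      "stays: age_years must be a non-negative integer (line %d)", rows[bad_age[1]]
    ), call. = FALSE)
  }
  bad_rng <- which(out$admission_date > out$discharge_date)
  if (length(bad_rng) > 0) {
    stop(sprintf(
      "stays: admission_date after discharge_date at line %d", rows[bad_rng[1]]
    ), call. = FALSE)
  }
  bad_tx <- which(!is.na(out$transplant_date) &
    (out$transplant_date < out$admission_date |
      out$transplant_date > out$discharge_date))
  if (length(bad_tx) > 0) {
    stop(sprintf(
      "stays: transplant_date outside [admission, discharge] at line %d",
      rows[bad_tx[1]]
    ), call. = FALSE)
  }
  out
}

# Severity levels and their grouping. The four knowledge-base levels map
# onto two analysis groups; "minor" is accepted as a synonym of the moderate
# group (some sources label the non-major group that way).
.ddi_levels <- c(
  contraindicated = "major",
  should_be_avoided = "major",
  precaution_of_use = "moderate",
  to_take_into_account = "moderate",
  major = "major",
  moderate = "moderate",
  minor = "moderate"
)

#' Map a DDI severity level to its analysis group
#'
#' `contraindicated` and `should be avoided` map to `major`;
#' `precaution of use` and `to take into account` map to `moderate`.
#' Matching is case-insensitive and tolerant of spaces or hyphens in place
#' of underscores; the group labels themselves (and `minor`, a synonym of
#' `moderate`) are also accepted.
#'
#' @param level Character vector of severity levels.
#' @return Character vector of `"major"` / `"moderate"`.
#' @export
ddi_severity_group <- function(level) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(level))))
  grp <- unname(.ddi_levels[key])
  if (anyNA(grp)) {
    stop(
      "unknown DDI severity level(s): ",
      paste(sprintf("'%s'", unique(level[is.na(grp)])), collapse = ", "),
      "; allowed: ", paste(names(.ddi_levels), collapse = ", "),
      call. = FALSE
    )
  }
  grp
}

#' Read a drug-drug interaction knowledge table
#'
#' Expects columns `term1,term2,level`: two interacting ATC terms (any
#' level, prefixes allowed) and one of the four severity levels
#' (`contraindicated`, `should_be_avoided`, `precaution_of_use`,
#' `to_take_into_account`), which are mapped to the `major` / `moderate`
#' severity groups.
#'
#' @param path Path to the DDI table CSV.
#' @return A tibble with columns `term1`, `term2`, `level`,
#'   `severity_group`.
#' @export
read_ddi_table <- function(path) {
  df <- read_input_csv(path, c("term1", "term2", "level"), "ddi_table")
  rows <- seq_len(nrow(df)) + 1L
  out <- tibble::tibble(
    term1 = validate_atc_rows(df$term1, "ddi_table", rows),
    term2 = validate_atc_rows(df$term2, "ddi_table", rows),
    level = gsub("[ -]+", "_", tolower(trimws(df$level))),
    severity_group = ddi_severity_group(df$level)
  )
  same <- which(out$term1 == out$term2)
  if (length(same) > 0) {
    stop(sprintf(
      "ddi_table: term1 and term2 identical ('%s') at line %d",
      out$term1[same[1]], rows[same[1]]
    ), call. = FALSE)
  }
  out
}

#' Read a potentially-inappropriate-medication list
#'
#' One ATC term per line (any level; prefixes match all descendants).
#' Lines may carry `#` comments; blank lines are ignored. An empty list is
#' an error: screening against an empty reference is never meaningful.
#'
#' @param path Path to the PIM list text file.
#' @return Character vector of validated ATC terms (unique, sorted).
#' @export
read_pim_list <- function(path) {
  if (!file.exists(path)) {
    stop("pim_list: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- trimws(sub("#.*$", "", lines))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) {
    stop("pim_list: no ATC terms found (empty list)", call. = FALSE)
  }
  sort(unique(validate_atc(terms)))
}

#' Write the input tables
#'
#' Writers matching the readers' CSV dialect (UTF-8, comma-separated,
#' ISO-8601 dates), so that a write / read round trip reproduces the same
#' normalised records.
#'
#' @param records,stays,ddi_table Tibbles as returned by the corresponding
#'   readers.
#' @param terms Character vector of PIM terms.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_administrations <- function(records, path) {
  readr::write_csv(records[c("patient_id", "date", "atc_code", "drug_label")], path, na = "")
  invisible(path)
}

#' @rdname write_tables
#' @export
write_stays <- function(stays, path) {
  cols <- c("patient_id", "admission_date", "discharge_date", "transplant_date", "age_years")
  readr::write_csv(stays[cols], path, na = "")
  invisible(path)
}

#' @rdname write_tables
#' @export
write_ddi_table <- function(ddi_table, path) {
  readr::write_csv(ddi_table[c("term1", "term2", "level")], path, na = "")
  invisible(path)
}

#' @rdname write_tables
#' @export
write_pim_list <- function(terms, path) {
  writeLines(terms, path, useBytes = TRUE)
  invisible(path)
}

# Drop administration rows dated outside the patient's stay window, with a
# warning. Warehouse extracts commonly carry boundary artifacts; silently
# keeping them would corrupt the daily matrix, erroring would block whole
# cohorts.
drop_out_of_window <- function(records, stay) {
  inside <- records$date >= stay$admission_date & records$date <= stay$discharge_date
  n_drop <- sum(!inside)
  if (n_drop > 0) {
    warning(sprintf(
      "patient %s: dropped %d administration row(s) outside [%s, %s]",
      stay$patient_id, n_drop,
      format(stay$admission_date), format(stay$discharge_date)
    ), call. = FALSE)
  }
  records[inside, , drop = FALSE]
}
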
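# Daily determinant detection: the per-patient, per-day exposure matrix.

#' Detection thresholds for the prescribing determinants
#'
#' Polypharmacy (PP) is defined as at least `pp` distinct drugs administered
#' on a day, hyperpolypharmacy (HPP) as at least `hpp`; potentially
#' inappropriate medications (PIMs) are screened only for patients aged
#' `pim_age_min` or older at admission.
#'
#' @param pp Daily distinct-drug count at or above which PP fires (default 5).
#' @param hpp Count at or above which HPP fires (default 10); must be
#'   `>= pp`.
#' @param pim_age_min Minimum age in years for PIM screening (default 65).
#' @return A named list of class `cde_thresholds`.
#' @export
exposure_thresholds <- function(pp = 5, hpp = 10, pim_age_min = 65) {
  pp <- as.integer(pp)
  hpp <- as.integer(hpp)
  pim_age_min <- as.integer(pim_age_min)
  if (is.na(pp) || is.na(hpp) || pp < 1 || hpp < pp) {
    stop("thresholds must satisfy 1 <= pp <= hpp", call. = FALSE)
  }
  if (is.na(pim_age_min) || pim_age_min < 0) {
    stop("pim_age_min must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(pp = pp, hpp = hpp, pim_age_min = pim_age_min),
    class = "cde_thresholds"
  )
}

#' Count distinct drugs administered on one day
#'
#' Repeated administrations of the same code on one day count once. On days
#' strictly before the transplant day, antineoplastic conditioning agents
#' (ATC class `exclude_class`, default `L01`) are excluded from the count,
#' so that high-dose conditioning chemotherapy does not inflate the
#' polypharmacy assessment.
#'
#' @param day_codes Character vector of validated ATC codes administered
#'   that day.
#' @param is_pre_transplant Is this day strictly before the transplant day?
#' @param exclude_class ATC term excluded pre-transplant, or `NULL` to
#'   disable the exclusion.
#' @return Integer count of distinct codes.
#' @export
count_distinct_drugs <- function(day_codes, is_pre_transplant = FALSE,
                                 exclude_class = "L01") {
  codes <- unique(day_codes)
  if (isTRUE(is_pre_transplant) && !is.null(exclude_class)) {
    codes <- codes[!atc_matches(codes, exclude_class)]
  }
  length(codes)
}

#' Detect drug-drug interactions on one day
#'
#' An interaction fires when two *distinct* administered codes match the two
#' terms of a knowledge-table entry (in either orientation); a single code
#' cannot supply both partners of a pair. Events are de-duplicated by the
#' canonical (sorted) term pair; if the same pair is listed at several
#' severity levels, the event is `major` if any listing is.
#'
#' @param day_codes Character vector of validated ATC codes administered
#'   that day.
#' @param ddi_table Knowledge table as returned by [read_ddi_table()].
#' @return Tibble with columns `term1`, `term2` (canonically sorted) and
#'   `severity_group`; zero rows when nothing fires.
#' @export
detect_ddis <- function(day_codes, ddi_table) {
  empty <- tibble::tibble(
    term1 = character(), term2 = character(), severity_group = character()
  )
  codes <- unique(day_codes)
  if (length(codes) < 2 || is.null(ddi_table) || nrow(ddi_table) == 0) {
    return(empty)
  }
  fired <- vapply(seq_len(nrow(ddi_table)), function(i) {
    m1 <- codes[atc_matches(codes, ddi_table$term1[i])]
    m2 <- codes[atc_matches(codes, ddi_table$term2[i])]
    # a distinct pair (a, b) exists iff both sides match and the union of
    # matched codes holds at least two codes
    length(m1) > 0 && length(m2) > 0 && length(unique(c(m1, m2))) >= 2
  }, logical(1))
  if (!any(fired)) {
    return(empty)
  }
  hits <- ddi_table[fired, , drop = FALSE]
  t_lo <- pmin(hits$term1, hits$term2)
  t_hi <- pmax(hits$term1, hits$term2)
  key <- paste(t_lo, t_hi, sep = "|")
  agg <- tapply(hits$severity_group == "major", key, any)
  keys <- sort(names(agg))
  parts <- strsplit(keys, "|", fixed = TRUE)
  tibble::tibble(
    term1 = vapply(parts, `[`, character(1), 1),
    term2 = vapply(parts, `[`, character(1), 2),
    severity_group = as.vector(ifelse(agg[keys], "major", "moderate"))
  )
}

#' Detect potentially inappropriate medications on one day
#'
#' Administered codes are cross-referenced against an ATC-based PIM list;
#' any listed term matched by at least one administered code (prefix
#' semantics) is returned. Screening applies only to patients aged
#' `thresholds$pim_age_min` or older: for younger patients the result is
#' `NULL` (not applicable), which is distinct from an empty match set.
#'
#' @param day_codes Character vector of validated ATC codes.
#' @param pim_list Character vector of ATC terms ([read_pim_list()]).
#' @param age_years Patient age at admission.
#' @param thresholds [exposure_thresholds()].
#' @return Character vector of matched PIM terms (possibly empty), or
#'   `NULL` when the patient is below the screening age.
#' @export
detect_pims <- function(day_codes, pim_list, age_years,
                        thresholds = exposure_thresholds()) {
  if (age_years < thresholds$pim_age_min) {
    return(NULL)
  }
  codes <- unique(day_codes)
  hit <- vapply(pim_list, function(term) any(atc_matches(codes, term)), logical(1))
  unname(pim_list[hit])
}

#' Build the daily exposure matrix for one patient
#'
#' Produces exactly one row per calendar day of the stay (admission and
#' discharge days included). Days with no administration rows have a zero
#' drug count, no flags, and empty event sets. Days strictly before the
#' transplant date (when one is recorded) are treated as pre-transplant for
#' the conditioning-chemotherapy exclusion; the transplant day itself is
#' not excluded.
#'
#' @param records Administration records for this patient
#'   ([read_administrations()] rows); rows dated outside the stay are
#'   dropped with a warning.
#' @param stay One-row stay tibble ([read_stays()]).
#' @param ddi_table Optional DDI knowledge table; `NULL` skips DDI
#'   detection (zero events everywhere).
#' @param pim_list Optional PIM term vector; `NULL` skips PIM screening
#'   entirely (`pim_applicable` is `NA`).
#' @param thresholds [exposure_thresholds()].
#' @param count_atc_level Optional ATC level (1--5) at which distinct drugs
#'   are counted for PP/HPP; `NULL` (default) counts codes as given.
#' @return Tibble with one row per day: `patient_id`, `day_index`, `date`,
#'   `n_distinct_drugs`, `pp`, `hpp`, the list-columns `atc_codes`,
#'   `ddi_events`, `pims`, the event counts `n_ddis`, `n_ddis_major`,
#'   `n_ddis_moderate`, `n_pims`, plus `pim_applicable` and `age_years`.
#'   `n_pims` is `NA` when PIM screening does not apply.
#' @export
build_daily_exposure <- function(records, stay, ddi_table = NULL,
                                 pim_list = NULL,
                                 thresholds = exposure_thresholds(),
                                 count_atc_level = NULL) {
  if (is.null(stay) || nrow(stay) != 1) {
    stop("build_daily_exposure: exactly one stay record required", call. = FALSE)
  }
  records <- records[records$patient_id == stay$patient_id, , drop = FALSE]
  records <- drop_out_of_window(records, stay)

  dates <- seq(stay$admission_date, stay$discharge_date, by = "day")
  los <- length(dates)
  codes_by_day <- split(records$atc_code, factor(as.character(records$date),
    levels = as.character(dates)
  ))
  has_tx <- !is.na(stay$transplant_date)
  pim_applicable <- if (is.null(pim_list)) {
    NA
  } else {
    stay$age_years >= thresholds$pim_age_min
  }

  one_day <- function(i) {
    codes <- unique(codes_by_day[[i]])
    pre_tx <- has_tx && dates[i] < stay$transplant_date
    count_codes <- if (is.null(count_atc_level)) {
      codes
    } else {
      unique(atc_truncate(codes, count_atc_level))
    }
    n <- count_distinct_drugs(count_codes, is_pre_transplant = pre_tx)
    events <- if (is.null(ddi_table)) {
      detect_ddis(character(), NULL)
    } else {
      detect_ddis(codes, ddi_table)
    }
    pims <- if (is.null(pim_list)) {
      NULL
    } else {
      detect_pims(codes, pim_list, stay$age_years, thresholds)
    }
    list(codes = codes, n = n, events = events, pims = pims)
  }
  days <- lapply(seq_len(los), one_day)

  n_distinct <- vapply(days, function(d) d$n, integer(1))
  n_ddis <- vapply(days, function(d) nrow(d$events), integer(1))
  n_major <- vapply(days, function(d) sum(d$events$severity_group == "major"), integer(1))
  tibble::tibble(
    patient_id = stay$patient_id,
    day_index = seq_len(los),
    date = dates,
    n_distinct_drugs = n_distinct,
    pp = n_distinct >= thresholds$pp,
    hpp = n_distinct >= thresholds$hpp,
    atc_codes = lapply(days, function(d) d$codes),
    ddi_events = lapply(days, function(d) d$events),
    n_ddis = n_ddis,
    n_ddis_major = n_major,
    n_ddis_moderate = n_ddis - n_major,
    pims = lapply(days, function(d) d$pims),
    n_pims = if (isTRUE(pim_applicable)) {
      vapply(days, function(d) length(d$pims), integer(1))
    } else {
      NA_integer_
    },
    pim_applicable = pim_applicable,
    age_years = stay$age_years
  )
}

#' Build the daily exposure matrix for a cohort
#'
#' Applies [build_daily_exposure()] to every patient in `stays`, in
#' `stays` order, and binds the results.
#'
#' @inheritParams build_daily_exposure
#' @param stays Stay tibble, one row per patient.
#' @return Row-bound daily exposure tibble for all patients.
#' @export
build_daily_matrix <- function(records, stays, ddi_table = NULL,
                               pim_list = NULL,
                               thresholds = exposure_thresholds(),
                               count_atc_level = NULL) {
  if (nrow(stays) == 0) {
    stop("build_daily_matrix: empty cohort", call. = FALSE)
  }
  dplyr::bind_rows(lapply(seq_len(nrow(stays)), function(i) {
    build_daily_exposure(
      records, stays[i, , drop = FALSE], ddi_table, pim_list,
      thresholds, count_atc_level
    )
  }))
}

#' Flatten a daily exposure matrix for CSV output
#'
#' @param daily Daily exposure tibble ([build_daily_matrix()]).
#' @return Tibble with scalar columns only: `patient_id`, `day_index`,
#'   `date`, `n_distinct_drugs`, `pp`, `hpp`, `n_ddis`, `n_ddis_major`,
#'   `n_ddis_moderate`, `n_pims` (`NA` when PIM screening does not apply).
#' @export
as_daily_exposure_table <- function(daily) {
  daily[c(
    "patient_id", "day_index", "date", "n_distinct_drugs", "pp", "hpp",
    "n_ddis", "n_ddis_major", "n_ddis_moderate", "n_pims"
  )]
}
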
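# Synthetic cohort generation.
#
# The generator emulates the structure of an autologous stem-cell-transplant
# stay: a low drug count at admission, a mid-stay peak during the aplastic
# phase that crosses the hyperpolypharmacy threshold, a taper toward
# discharge, interaction-prone co-prescriptions near the peak, conditioning
# chemotherapy (ATC class L01) before the transplant day, and chronic
# inappropriate medications in older patients. Codes are syntactically valid
# ATC but need not be pharmacologically accurate.

# General palette: ~50 level-5 codes across classes A, B, C, J, L, N.
# Deliberately excludes L01 (planted separately pre-transplant) and every
# family on the packaged PIM list, so a planted chronic PIM is the only PIM
# a synthetic patient receives.
.atc_palette <- c(
  "A02BC05", "A02BC01", "A02BA02", "A03FA01", "A04AA01", "A06AD11",
  "A07AA09", "A10BA02", "A11CC05", "A12BA01",
  "B01AB01", "B01AB05", "B01AC06", "B02BA01", "B03BA01", "B03BB01",
  "B05BA03", "B05BB01",
  "C01BD01", "C01DA02", "C03CA01", "C03CA02", "C03DA01", "C07AB02",
  "C07AB03", "C08DB01", "C09AA05", "C10AA01",
  "J01CR02", "J01DD04", "J01DH02", "J01FA09", "J01XE01", "J02AC01",
  "J04AB02", "J05AB01", "J05AF06", "J06BA02",
  "L02AE02", "L03AA02", "L04AA06", "L04AB02", "L04AD01",
  "N02AA01", "N02BA01", "N02BE01", "N02CC01", "N03AX14", "N05AD01",
  "N05AH03", "N06AB06", "N07CA01"
)

# Interacting pairs planted near the peak; none of these codes matches the
# packaged PIM list.
.planted_ddi_pairs <- list(
  c("A02BC05", "C03CA01"),
  c("B01AC06", "N02BA01")
)

.planted_pim_code <- "C01AA05" # chronic cardiac glycoside, on the PIM list
.planted_l01_code <- "L01XA01" # conditioning chemotherapy, pre-transplant

#' Packaged toy knowledge tables
#'
#' Small stand-ins for a drug-interaction knowledge base and an ATC-based
#' PIM reference list, sized for testing and simulation: the interaction
#' table spans all four severity levels and mixes ATC term levels 2 through
#' 5 (so prefix matching is exercised); the PIM list holds eight term
#' families typical of geriatric screening lists.
#'
#' @return List with elements `ddi` (tibble: `term1`, `term2`, `level`,
#'   `severity_group`) and `pim` (character vector of ATC terms).
#' @export
toy_knowledge_tables <- function() {
  ddi <- tibble::tibble(
    term1 = c(
      "A02BC", "B01AC06", "C03C", "J01FA09", "N06AB", "L04AD01",
      "C07AB", "N05BA", "A10BA02", "J01XE01", "C09AA", "J05"
    ),
    term2 = c(
      "C03CA", "N02BA01", "C03DA01", "C01BD01", "N06AA", "J02AC01",
      "C08DB01", "N02AA01", "C03CA01", "B03BB01", "C03DA01", "L04AD01"
    ),
    level = c(
      "precaution_of_use", "should_be_avoided", "contraindicated",
      "contraindicated", "should_be_avoided", "precaution_of_use",
      "to_take_into_account", "to_take_into_account", "precaution_of_use",
      "to_take_into_account", "should_be_avoided", "precaution_of_use"
    )
  )
  ddi$term1 <- validate_atc(ddi$term1)
  ddi$term2 <- validate_atc(ddi$term2)
  ddi$severity_group <- ddi_severity_group(ddi$level)
  pim <- validate_atc(c(
    "N05BA", "N05CD", "N05CF", "N06AA", "R06AD", "A03BA01",
    "C01AA05", "M01AB05"
  ))
  list(ddi = ddi, pim = sort(pim))
}

#' Synthetic cohort configuration
#'
#' Parameters of the generator. Defaults reflect the transplant-stay use
#' case: stays of 14--52 days, ages 21--70, an expected distinct-drug count
#' rising piecewise-linearly from about 3 at admission to a peak of about
#' 13 (above the hyperpolypharmacy threshold) and tapering to about 5 at
#' discharge, frequent interacting co-prescriptions near the peak, and a
#' high rate of chronic inappropriate medication among patients aged 65 or
#' older.
#'
#' @param n_patients Number of patients (0 allowed: empty cohort).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param los_min,los_max Length-of-stay range in days.
#' @param age_min,age_max Age range at admission, years.
#' @param admission_mean_drugs,peak_mean_drugs,discharge_mean_drugs
#'   Expected distinct-drug counts at the three anchor points of the daily
#'   profile.
#' @param peak_position_frac Position of the peak within the stay (0, 1).
#' @param ddi_pair_rate Daily probability, near the peak, of planting one
#'   known interacting pair.
#' @param pim_rate_elderly Probability that a patient aged 65+ carries a
#'   chronic PIM administered every day.
#' @param transplant_day_frac Transplant day as a fraction of the stay;
#'   days before it receive conditioning chemotherapy (ATC L01).
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed,
                          los_min = 14, los_max = 52,
                          age_min = 21, age_max = 70,
                          admission_mean_drugs = 3,
                          peak_mean_drugs = 13,
                          discharge_mean_drugs = 5,
                          peak_position_frac = 0.4,
                          ddi_pair_rate = 0.6,
                          pim_rate_elderly = 0.8,
                          transplant_day_frac = 0.2) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    los_min = as.integer(los_min), los_max = as.integer(los_max),
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    admission_mean_drugs = admission_mean_drugs,
    peak_mean_drugs = peak_mean_drugs,
    discharge_mean_drugs = discharge_mean_drugs,
    peak_position_frac = peak_position_frac,
    ddi_pair_rate = ddi_pair_rate,
    pim_rate_elderly = pim_rate_elderly,
    transplant_day_frac = transplant_day_frac
  )
  stopifnot(
    !is.na(cfg$n_patients), cfg$n_patients >= 0,
    !is.na(cfg$seed),
    cfg$los_min >= 1, cfg$los_min <= cfg$los_max,
    cfg$age_min >= 0, cfg$age_min <= cfg$age_max,
    cfg$admission_mean_drugs >= 0, cfg$peak_mean_drugs >= 0,
    cfg$discharge_mean_drugs >= 0,
    cfg$peak_position_frac > 0, cfg$peak_position_frac < 1,
    cfg$ddi_pair_rate >= 0, cfg$ddi_pair_rate <= 1,
    cfg$pim_rate_elderly >= 0, cfg$pim_rate_elderly <= 1,
    cfg$transplant_day_frac > 0, cfg$transplant_day_frac < 1
  )
  structure(cfg, class = "cohort_config")
}

# Brute-force per-day truth: recounts the determinants from the emitted
# codes with plain loops, independently of the vectorised detection path.
truth_for_day <- function(codes, pre_tx, age, kb, pim_terms, pim_applicable) {
  codes <- unique(codes)
  counted <- codes
  if (pre_tx) {
    counted <- counted[!startsWith(counted, "L01")]
  }
  pairs <- character(0)
  is_major <- logical(0)
  for (i in seq_len(nrow(kb))) {
    found <- FALSE
    for (a in codes) {
      for (b in codes) {
        if (a != b && startsWith(a, kb$term1[i]) && startsWith(b, kb$term2[i])) {
          found <- TRUE
        }
      }
    }
    if (found) {
      key <- paste(sort(c(kb$term1[i], kb$term2[i])), collapse = "|")
      j <- match(key, pairs)
      if (is.na(j)) {
        pairs <- c(pairs, key)
        is_major <- c(is_major, kb$severity_group[i] == "major")
      } else {
        is_major[j] <- is_major[j] || kb$severity_group[i] == "major"
      }
    }
  }
  n_pims <- if (!pim_applicable) {
    NA_integer_
  } else {
    sum(vapply(pim_terms, function(t) any(startsWith(codes, t)), logical(1)))
  }
  list(
    n_distinct = length(counted),
    n_ddis = length(pairs),
    n_ddis_major = sum(is_major),
    n_pims = n_pims
  )
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under [cohort_config()]: per patient, a uniform length of
#' stay and age, a piecewise-linear admission-to-peak-to-discharge expected
#' drug count with Poisson dispersion, codes sampled from a built-in ATC
#' palette, conditioning chemotherapy on pre-transplant days, a planted
#' interacting pair on peak-phase days with probability `ddi_pair_rate`,
#' and (for eligible older patients) a chronic PIM administered every day.
#' Each patient draws from a substream keyed by the seed and the patient
#' index, so cohorts are reproducible and stable under reordering.
#'
#' The returned `truth` table is an independent brute-force recount of the
#' daily determinants from the emitted records, for use as a planted-truth
#' oracle against the detection pipeline.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `administrations`, `stays`,
#'   `truth` (per patient-day: `n_distinct`, `pp`, `hpp`, `n_ddis`,
#'   `n_ddis_major`, `n_ddis_moderate`, `n_pims`, plus planting flags),
#'   `ddi_table`, `pim_list`, `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("generate_cohort: config must be a cohort_config", call. = FALSE)
  }
  kb <- toy_knowledge_tables()
  thr <- exposure_thresholds()
  base_date <- as.Date("2021-03-01")

  admin <- list()
  stays <- list()
  truth <- list()
  for (i in seq_len(config$n_patients)) {
    set.seed(((config$seed %% 2147483L) * 977L + i) %% 2147483647L)
    pid <- sprintf("P%04d", i)
    los <- sample(config$los_min:config$los_max, 1)
    age <- sample(config$age_min:config$age_max, 1)
    admission <- base_date + (i - 1L)
    discharge <- admission + (los - 1L)
    tx_day <- max(2L, floor(config$transplant_day_frac * los))
    tx_date <- admission + (tx_day - 1L)
    peak_day <- max(2L, min(los - 1L, round(config$peak_position_frac * los)))

    has_pim <- age >= thr$pim_age_min &&
      stats::runif(1) < config$pim_rate_elderly
    pim_applicable <- age >= thr$pim_age_min

    lambda <- numeric(los)
    for (d in seq_len(los)) {
      lambda[d] <- if (d <= peak_day) {
        config$admission_mean_drugs +
          (config$peak_mean_drugs - config$admission_mean_drugs) *
            (d - 1) / max(1, peak_day - 1)
      } else {
        config$peak_mean_drugs +
          (config$discharge_mean_drugs - config$peak_mean_drugs) *
            (d - peak_day) / max(1, los - peak_day)
      }
    }
    near_peak <- lambda >= config$admission_mean_drugs +
      0.7 * (config$peak_mean_drugs - config$admission_mean_drugs)

    day_rows <- vector("list", los)
    day_truth <- vector("list", los)
    for (d in seq_len(los)) {
      n_base <- stats::rpois(1, lambda[d])
      codes <- sample(.atc_palette, min(n_base, length(.atc_palette)))
      pre_tx <- d < tx_day
      if (pre_tx) {
        codes <- c(codes, .planted_l01_code)
      }
      planted_ddi <- near_peak[d] && stats::runif(1) < config$ddi_pair_rate
      if (planted_ddi) {
        pair <- .planted_ddi_pairs[[sample.int(length(.planted_ddi_pairs), 1)]]
        codes <- c(codes, pair)
      }
      if (has_pim) {
        codes <- c(codes, .planted_pim_code)
      }
      codes <- unique(codes)
      day_rows[[d]] <- tibble::tibble(
        patient_id = pid,
        date = admission + (d - 1L),
        atc_code = codes,
        drug_label = NA_character_
      )
      tr <- truth_for_day(codes, pre_tx, age, kb$ddi, kb$pim, pim_applicable)
      day_truth[[d]] <- tibble::tibble(
        patient_id = pid,
        day_index = d,
        date = admission + (d - 1L),
        n_distinct = tr$n_distinct,
        pp = tr$n_distinct >= thr$pp,
        hpp = tr$n_distinct >= thr$hpp,
        n_ddis = tr$n_ddis,
        n_ddis_major = tr$n_ddis_major,
        n_ddis_moderate = tr$n_ddis - tr$n_ddis_major,
        n_pims = tr$n_pims,
        planted_ddi = planted_ddi,
        planted_pim = has_pim
      )
    }
    admin[[i]] <- dplyr::bind_rows(day_rows)
    truth[[i]] <- dplyr::bind_rows(day_truth)
    stays[[i]] <- tibble::tibble(
      patient_id = pid,
      admission_date = admission,
      discharge_date = discharge,
      transplant_date = tx_date,
      age_years = as.integer(age)
    )
  }
  structure(
    list(
      administrations = dplyr::bind_rows(admin),
      stays = dplyr::bind_rows(stays),
      truth = dplyr::bind_rows(truth),
      ddi_table = kb$ddi,
      pim_list = kb$pim,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' Deterministic single-patient worked-example fixture
#'
#' A 34-day stay with a hand-fixed daily distinct-drug profile: exactly 5
#' drugs on day 1; at least 5 on days 1--6, 10--25, and 27--28; at least 10
#' on days 15--21 only; fewer than 5 on all other days; exactly 1 drug on
#' day 34. Run through the pipeline it yields 24 days of cumulative
#' polypharmacy exposure, 7 days of hyperpolypharmacy exposure, and a
#' `1→0` polypharmacy trajectory. No randomness is involved.
#'
#' @return List of class `synthetic_cohort` (with an extra
#'   `daily_drug_counts` element giving the planted per-day counts):
#'   `administrations`, `stays`, `ddi_table`, `pim_list`.
#' @export
figure1_fixture <- function() {
  counts <- c(
    5, 6, 7, 8, 7, 6, # days 1-6   (PP)
    4, 3, 4, # days 7-9
    6, 7, 8, 9, 8, # days 10-14 (PP)
    11, 12, 13, 12, 11, 10, 10, # days 15-21 (PP + HPP)
    9, 8, 7, 6, # days 22-25 (PP)
    4, # day 26
    5, 6, # days 27-28 (PP)
    4, 3, 2, 2, 2, # days 29-33
    1 # day 34
  )
  stopifnot(length(counts) == 34)
  admission <- as.Date("2021-01-01")
  kb <- toy_knowledge_tables()
  rows <- lapply(seq_along(counts), function(d) {
    tibble::tibble(
      patient_id = "F001",
      date = admission + (d - 1L),
      atc_code = .atc_palette[seq_len(counts[d])],
      drug_label = NA_character_
    )
  })
  stays <- tibble::tibble(
    patient_id = "F001",
    admission_date = admission,
    discharge_date = admission + 33L,
    transplant_date = as.Date(NA),
    age_years = 58L
  )
  structure(
    list(
      administrations = dplyr::bind_rows(rows),
      stays = stays,
      truth = NULL,
      ddi_table = kb$ddi,
      pim_list = kb$pim,
      config = NULL,
      daily_drug_counts = counts
    ),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to a directory
#'
#' Emits the same four files the readers consume (`administrations.csv`,
#' `stays.csv`, `ddi_table.csv`, `pim_list.txt`) plus, when present, the
#' generator's planted truth as `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_administrations(cohort$administrations, file.path(dir, "administrations.csv"))
  write_stays(cohort$stays, file.path(dir, "stays.csv"))
  write_ddi_table(cohort$ddi_table, file.path(dir, "ddi_table.csv"))
  write_pim_list(cohort$pim_list, file.path(dir, "pim_list.txt"))
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    truth$date <- format(truth$date)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  invisible(dir)
}
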
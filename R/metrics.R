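# Cumulative and conventional exposure metrics.
#
# CDE (cumulative drug exposure): for PP/HPP, the number of stay days on
# which the flag is raised; for DDIs and PIMs, occurrence-days -- each
# distinct same-day event contributes separately, so four distinct
# interactions on one day count as four. CDED divides CDE by the length of
# stay (both boundary days counted), giving an intensity-adjusted measure.

#' Determinant labels
#'
#' The six determinants the metrics are computed for: polypharmacy,
#' hyperpolypharmacy, drug-drug interactions (all, major-only,
#' moderate-only), and potentially inappropriate medications.
#' @return Character vector of determinant labels.
#' @export
determinant_labels <- function() {
  c("PP", "HPP", "DDI", "DDI_major", "DDI_moderate", "PIM")
}

# Per-day event count for a determinant on a single patient's daily matrix.
daily_counts <- function(daily, determinant) {
  switch(determinant,
    PP = ,
    HPP = daily$n_distinct_drugs,
    DDI = daily$n_ddis,
    DDI_major = daily$n_ddis_major,
    DDI_moderate = daily$n_ddis_moderate,
    PIM = daily$n_pims
  )
}

# Per-day presence for a determinant.
daily_presence <- function(daily, determinant) {
  switch(determinant,
    PP = daily$pp,
    HPP = daily$hpp,
    DDI = daily$n_ddis > 0,
    DDI_major = daily$n_ddis_major > 0,
    DDI_moderate = daily$n_ddis_moderate > 0,
    PIM = daily$n_pims > 0
  )
}

#' Cumulative drug exposure for one patient
#'
#' For PP/HPP the number of exposure days; for the DDI determinants and
#' PIM, the sum over days of distinct same-day events (occurrence-days).
#' PIM exposure for a patient below the screening age is `NA` (not
#' applicable), never zero.
#'
#' @param daily Daily exposure matrix for a single patient.
#' @param determinant One of [determinant_labels()].
#' @return A single number (days or occurrence-days), or `NA` when the
#'   determinant does not apply to the patient.
#' @export
compute_cde <- function(daily, determinant) {
  determinant <- match.arg(determinant, determinant_labels())
  if (nrow(daily) == 0) {
    stop("compute_cde: empty daily matrix", call. = FALSE)
  }
  if (determinant == "PIM" && !isTRUE(daily$pim_applicable[1])) {
    return(NA_real_)
  }
  if (determinant %in% c("PP", "HPP")) {
    return(as.numeric(sum(daily_presence(daily, determinant))))
  }
  as.numeric(sum(daily_counts(daily, determinant)))
}

#' Cumulative drug exposure density
#'
#' CDE normalised by the length of stay in days. For PP/HPP this is the
#' fraction of stay days exposed (in `[0, 1]`); for DDIs/PIMs it is a mean
#' number of events per day and may exceed 1.
#'
#' @param cde CDE value ([compute_cde()]); `NA` propagates.
#' @param los_days Length of stay in days (`>= 1`).
#' @return `cde / los_days`.
#' @export
compute_cded <- function(cde, los_days) {
  if (any(is.na(los_days)) || any(los_days < 1)) {
    stop("compute_cded: los_days must be >= 1", call. = FALSE)
  }
  cde / los_days
}

#' Conventional point-in-time metrics for one patient
#'
#' Presence and event count of a determinant on the first (admission) and
#' last (discharge) calendar day of the stay, plus whether the determinant
#' was ever present. Counts are the daily distinct-drug count for PP/HPP
#' and the number of same-day events for DDIs/PIMs. For a single-day stay,
#' admission and discharge coincide.
#'
#' @inheritParams compute_cde
#' @return Named list: `present_admission`, `present_discharge`,
#'   `count_admission`, `count_discharge`, `present_any_day`. All `NA` for
#'   a non-applicable PIM.
#' @export
conventional_metrics <- function(daily, determinant) {
  determinant <- match.arg(determinant, determinant_labels())
  if (nrow(daily) == 0) {
    stop("conventional_metrics: empty daily matrix", call. = FALSE)
  }
  if (determinant == "PIM" && !isTRUE(daily$pim_applicable[1])) {
    return(list(
      present_admission = NA, present_discharge = NA,
      count_admission = NA_integer_, count_discharge = NA_integer_,
      present_any_day = NA
    ))
  }
  pres <- daily_presence(daily, determinant)
  cnt <- daily_counts(daily, determinant)
  first <- 1L
  last <- nrow(daily)
  list(
    present_admission = pres[first],
    present_discharge = pres[last],
    count_admission = as.integer(cnt[first]),
    count_discharge = as.integer(cnt[last]),
    present_any_day = any(pres)
  )
}

#' Admission-to-discharge trajectory label
#'
#' Classifies a patient by determinant presence at admission and discharge:
#' `0`→`0` (never), `0`→`1` (acquired), `1`→`0` (resolved),
#' `1`→`1` (sustained).
#'
#' @param present_admission,present_discharge Logical scalars.
#' @return One of `"0→0"`, `"0→1"`, `"1→0"`, `"1→1"`;
#'   `NA` if either input is `NA`.
#' @export
classify_trajectory <- function(present_admission, present_discharge) {
  if (is.na(present_admission) || is.na(present_discharge)) {
    return(NA_character_)
  }
  paste0(
    as.integer(present_admission), "→", as.integer(present_discharge)
  )
}

#' Per-patient determinant metrics
#'
#' Combines CDE, CDED, the conventional point-in-time metrics, and the
#' trajectory label for every determinant, over all patients in a daily
#' exposure matrix. PIM rows are emitted only when PIM screening was
#' requested; for patients below the screening age they carry
#' `applicable = FALSE` and `NA` values.
#'
#' @param daily Daily exposure matrix ([build_daily_matrix()]).
#' @return Long tibble with one row per patient and determinant:
#'   `patient_id`, `determinant`, `cde`, `cded`, `los_days`,
#'   `present_admission`, `present_discharge`, `count_admission`,
#'   `count_discharge`, `present_any_day`, `trajectory`, `applicable`.
#' @export
compute_determinant_metrics <- function(daily) {
  pim_requested <- !all(is.na(daily$pim_applicable))
  dets <- determinant_labels()
  if (!pim_requested) {
    dets <- setdiff(dets, "PIM")
  }
  per_patient <- function(d) {
    los <- nrow(d)
    rows <- lapply(dets, function(det) {
      cde <- compute_cde(d, det)
      conv <- conventional_metrics(d, det)
      tibble::tibble(
        patient_id = d$patient_id[1],
        determinant = det,
        cde = cde,
        cded = cde / los,
        los_days = los,
        present_admission = conv$present_admission,
        present_discharge = conv$present_discharge,
        count_admission = conv$count_admission,
        count_discharge = conv$count_discharge,
        present_any_day = conv$present_any_day,
        trajectory = classify_trajectory(
          conv$present_admission, conv$present_discharge
        ),
        applicable = !(det == "PIM" && !isTRUE(d$pim_applicable[1]))
      )
    })
    dplyr::bind_rows(rows)
  }
  out <- daily |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_split() |>
    lapply(per_patient) |>
    dplyr::bind_rows()
  out$determinant <- factor(out$determinant, levels = determinant_labels())
  dplyr::arrange(out, .data$patient_id, .data$determinant) |>
    dplyr::mutate(determinant = as.character(.data$determinant))
}

#' Cohort summary of conventional and cumulative metrics
#'
#' Summarises a cohort the way exposure studies tabulate it: per
#' determinant, the prevalence of exposed patients over the stay (at least
#' one occurrence on any day), at admission, and at discharge, with
#' explicit numerators and denominators; mean event counts per day (pooled
#' over all patient-days for the stay column, averaged over patients at
#' admission and discharge); and mean CDE and CDED. PIM rows use the
#' screening-eligible subgroup as denominator.
#'
#' @param metrics Metrics tibble ([compute_determinant_metrics()]).
#' @param daily Matching daily exposure matrix.
#' @return List of class `cde_cohort_summary` with elements `n_patients`,
#'   `n_pim_applicable`, `prevalence`, `administrations_per_day`,
#'   `cde_mean`, `cded_mean`.
#' @export
cohort_summary <- function(metrics, daily) {
  if (nrow(metrics) == 0) {
    stop("cohort_summary: no metrics", call. = FALSE)
  }
  n_patients <- dplyr::n_distinct(metrics$patient_id)
  pim_ids <- unique(metrics$patient_id[metrics$determinant == "PIM" & metrics$applicable])
  dets <- intersect(determinant_labels(), unique(metrics$determinant))

  prevalence <- dplyr::bind_rows(lapply(dets, function(det) {
    m <- metrics[metrics$determinant == det & metrics$applicable, , drop = FALSE]
    denom <- nrow(m)
    num <- c(
      sum(m$present_any_day), sum(m$present_admission),
      sum(m$present_discharge)
    )
    tibble::tibble(
      determinant = det,
      timepoint = c("stay", "admission", "discharge"),
      n = num,
      denominator = denom,
      pct = if (denom > 0) 100 * num / denom else NA_real_
    )
  }))

  # Pooled stay-level mean: total events over total patient-days. PIM rows
  # pool over screening-eligible patients only.
  pooled <- function(det) {
    d <- daily
    if (det == "PIM") {
      d <- d[d$patient_id %in% pim_ids, , drop = FALSE]
    }
    if (nrow(d) == 0) {
      return(NA_real_)
    }
    sum(daily_counts(d, det)) / nrow(d)
  }
  tp_mean <- function(det, col) {
    m <- metrics[metrics$determinant == det & metrics$applicable, , drop = FALSE]
    if (nrow(m) == 0) NA_real_ else mean(m[[col]])
  }
  adm_dets <- c(drugs = "PP", ddi = "DDI", ddi_major = "DDI_major",
                ddi_moderate = "DDI_moderate", pim = "PIM")
  adm_dets <- adm_dets[adm_dets %in% dets]
  administrations_per_day <- tibble::tibble(
    quantity = names(adm_dets),
    stay_mean = unname(vapply(adm_dets, pooled, numeric(1))),
    admission_mean = unname(vapply(adm_dets, tp_mean, numeric(1), col = "count_admission")),
    discharge_mean = unname(vapply(adm_dets, tp_mean, numeric(1), col = "count_discharge"))
  )

  cde_mean <- tibble::tibble(
    determinant = dets,
    mean = unname(vapply(dets, tp_mean, numeric(1), col = "cde")),
    n = unname(vapply(dets, function(det) {
      sum(metrics$determinant == det & metrics$applicable)
    }, numeric(1)))
  )
  cded_mean <- cde_mean
  cded_mean$mean <- unname(vapply(dets, tp_mean, numeric(1), col = "cded"))

  structure(
    list(
      n_patients = n_patients,
      n_pim_applicable = length(pim_ids),
      prevalence = prevalence,
      administrations_per_day = administrations_per_day,
      cde_mean = cde_mean,
      cded_mean = cded_mean
    ),
    class = "cde_cohort_summary"
  )
}

#' @export
print.cde_cohort_summary <- function(x, ...) {
  cat(sprintf(
    "Cohort summary: %d patients (%d PIM-eligible)\n",
    x$n_patients, x$n_pim_applicable
  ))
  cat("\nPrevalence of determinants (% of patients):\n")
  print(as.data.frame(x$prevalence), row.names = FALSE)
  cat("\nMean events per day:\n")
  print(as.data.frame(x$administrations_per_day), row.names = FALSE)
  cat("\nMean CDE (days / occurrence-days):\n")
  print(as.data.frame(x$cde_mean), row.names = FALSE)
  cat("\nMean CDED:\n")
  print(as.data.frame(x$cded_mean), row.names = FALSE)
  invisible(x)
}
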
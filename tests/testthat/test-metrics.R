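# CDE/CDED, conventional metrics, trajectories, and the cohort summary.

fixture_daily <- function() {
  fx <- figure1_fixture()
  build_daily_matrix(fx$administrations, fx$stays, fx$ddi_table, fx$pim_list)
}

test_that("the worked-example stay yields 24 PP days and 7 HPP days of cumulative exposure", {
  daily <- fixture_daily()
  expect_equal(compute_cde(daily, "PP"), 24)
  expect_equal(compute_cde(daily, "HPP"), 7)
  expect_equal(compute_cded(24, 34), 24 / 34)
})

test_that("occurrence-day counting: several distinct same-day events each count", {
  stay <- make_stay(discharge = "2021-01-05")
  kb <- toy_knowledge_tables()
  # day 3 carries four distinct interacting pairs; other days a lone analgesic
  day3 <- c(
    "A02BC05", "C03CA01", # precaution_of_use
    "B01AC06", "N02BA01", # should_be_avoided
    "C03DA01", # + C03CA01 under the C03C prefix rule
    "J01FA09", "C01BD01" # contraindicated
  )
  rec <- make_records(stay, 1:5, list(
    "N02BE01", "N02BE01", day3, "N02BE01", "N02BE01"
  ))
  daily <- build_daily_exposure(rec, stay, kb$ddi)
  expect_equal(daily$n_ddis, c(0, 0, 4, 0, 0))
  expect_equal(compute_cde(daily, "DDI"), 4)
  expect_equal(
    compute_cde(daily, "DDI"),
    compute_cde(daily, "DDI_major") + compute_cde(daily, "DDI_moderate")
  )
})

test_that("compute_cded validates the length of stay and saturates at 1 for full exposure", {
  expect_equal(compute_cded(0, 19), 0)
  expect_equal(compute_cded(19, 19), 1)
  expect_error(compute_cded(5, 0), "los_days")
})

test_that("conventional metrics read the first and last day of the matrix", {
  daily <- fixture_daily()
  conv <- conventional_metrics(daily, "PP")
  expect_true(conv$present_admission) # day 1: 5 drugs
  expect_false(conv$present_discharge) # day 34: 1 drug
  expect_equal(conv$count_admission, 5L)
  expect_equal(conv$count_discharge, 1L)
  expect_true(conv$present_any_day)
  # single-day stay: admission and discharge coincide
  stay1 <- make_stay(discharge = "2021-01-01")
  rec1 <- make_records(stay1, 1, list(c("A02BC05", "N02BE01")))
  d1 <- build_daily_exposure(rec1, stay1)
  c1 <- conventional_metrics(d1, "PP")
  expect_equal(c1$count_admission, c1$count_discharge)
  # empty stay: all absent, zero counts
  d0 <- build_daily_exposure(rec1[0, ], stay1)
  c0 <- conventional_metrics(d0, "PP")
  expect_false(c0$present_admission || c0$present_any_day)
  expect_equal(c0$count_admission, 0L)
})

test_that("trajectory labels cover the four admission/discharge combinations", {
  expect_equal(classify_trajectory(FALSE, FALSE), "0→0")
  expect_equal(classify_trajectory(FALSE, TRUE), "0→1")
  expect_equal(classify_trajectory(TRUE, FALSE), "1→0")
  expect_equal(classify_trajectory(TRUE, TRUE), "1→1")
  expect_true(is.na(classify_trajectory(NA, TRUE)))
  daily <- fixture_daily()
  m <- compute_determinant_metrics(daily)
  expect_equal(m$trajectory[m$determinant == "PP"], "1→0")
})

test_that("metrics invariants hold on a synthetic cohort", {
  co <- generate_cohort(cohort_config(12, 3))
  daily <- build_daily_matrix(co$administrations, co$stays, co$ddi_table, co$pim_list)
  m <- compute_determinant_metrics(daily)
  expect_equal(m$cded, m$cde / m$los_days)
  pp <- m[m$determinant == "PP", ]
  hpp <- m[m$determinant == "HPP", ]
  expect_true(all(pp$cded >= 0 & pp$cded <= 1))
  expect_true(all(hpp$cded >= 0 & hpp$cded <= 1))
  expect_true(all(hpp$cde <= pp$cde))
  ddi <- m[m$determinant == "DDI", ]
  expect_equal(
    ddi$cde,
    m$cde[m$determinant == "DDI_major"] + m$cde[m$determinant == "DDI_moderate"]
  )
  ok <- !is.na(m$cde)
  expect_equal(m$present_any_day[ok], m$cde[ok] > 0)
  # trajectory consistent with presence pair
  expect_equal(
    m$trajectory[ok],
    mapply(classify_trajectory, m$present_admission[ok], m$present_discharge[ok])
  )
  # conventional counts match the day-1 / last-day daily values
  for (pid in unique(daily$patient_id)) {
    d <- daily[daily$patient_id == pid, ]
    mp <- m[m$patient_id == pid & m$determinant == "PP", ]
    expect_equal(mp$count_admission, d$n_distinct_drugs[1])
    expect_equal(mp$count_discharge, d$n_distinct_drugs[nrow(d)])
  }
})

test_that("PIM metrics are missing, not zero, below the screening age", {
  stay <- make_stay(age = 60)
  kb <- toy_knowledge_tables()
  rec <- make_records(stay, 1, list("N05BA01"))
  daily <- build_daily_exposure(rec, stay, kb$ddi, kb$pim)
  expect_true(is.na(compute_cde(daily, "PIM")))
  m <- compute_determinant_metrics(daily)
  pim <- m[m$determinant == "PIM", ]
  expect_false(pim$applicable)
  expect_true(is.na(pim$cde))
  # and PIM rows are absent entirely when screening was never requested
  d2 <- build_daily_exposure(rec, stay, kb$ddi, NULL)
  m2 <- compute_determinant_metrics(d2)
  expect_false("PIM" %in% m2$determinant)
})

test_that("cohort summary prevalences match a brute-force recount", {
  co <- generate_cohort(cohort_config(15, 9))
  daily <- build_daily_matrix(co$administrations, co$stays, co$ddi_table, co$pim_list)
  m <- compute_determinant_metrics(daily)
  s <- cohort_summary(m, daily)
  expect_equal(s$n_patients, 15)

  # independent recount from the generator truth
  tr <- co$truth
  by_pat <- split(tr, tr$patient_id)
  ever_pp <- sum(vapply(by_pat, function(d) any(d$pp), logical(1)))
  adm_pp <- sum(vapply(by_pat, function(d) d$pp[1], logical(1)))
  dis_hpp <- sum(vapply(by_pat, function(d) d$hpp[nrow(d)], logical(1)))
  prev <- s$prevalence
  expect_equal(prev$n[prev$determinant == "PP" & prev$timepoint == "stay"], ever_pp)
  expect_equal(prev$n[prev$determinant == "PP" & prev$timepoint == "admission"], adm_pp)
  expect_equal(prev$n[prev$determinant == "HPP" & prev$timepoint == "discharge"], dis_hpp)
  expect_true(all(prev$n <= prev$denominator))
  # PIM denominator is the screening-eligible subgroup
  n_elder <- sum(co$stays$age_years >= 65)
  expect_equal(unique(prev$denominator[prev$determinant == "PIM"]), n_elder)
  # pooled stay mean = total events / total patient-days
  expect_equal(
    s$administrations_per_day$stay_mean[s$administrations_per_day$quantity == "ddi"],
    sum(tr$n_ddis) / nrow(tr),
    ignore_attr = TRUE
  )
})

test_that("metrics are invariant under permutation of patient processing order", {
  co <- generate_cohort(cohort_config(6, 5))
  daily_fwd <- build_daily_matrix(co$administrations, co$stays, co$ddi_table, co$pim_list)
  stays_rev <- co$stays[rev(seq_len(nrow(co$stays))), ]
  daily_rev <- build_daily_matrix(co$administrations, stays_rev, co$ddi_table, co$pim_list)
  m_fwd <- compute_determinant_metrics(daily_fwd)
  m_rev <- compute_determinant_metrics(daily_rev)
  expect_equal(m_fwd, m_rev)
})
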
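---
title: "Cumulative drug exposure metrics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative drug exposure metrics: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdexposure)
```

## The problem

Point-in-time indicators of drug burden — is a patient polymedicated at
admission? at discharge? — miss everything that happens in between. In
settings with highly dynamic regimens (transplantation wards, intensive
care, oncology), the drug count can triple mid-stay and fall back before
discharge, so two patients identical at both time points can have wildly
different in-hospital exposure. `cdexposure` implements two cumulative
metrics computed from daily medication-administration records:

* **CDE** (cumulative drug exposure): the total number of stay days on
  which a prescribing determinant is present. For determinants that are
  binary per day — polypharmacy (PP) and hyperpolypharmacy (HPP) — CDE is a
  day count bounded by the length of stay. For event-type determinants —
  drug–drug interactions (DDIs) and potentially inappropriate medications
  (PIMs) — each distinct same-day event contributes separately
  (*occurrence-days*): four distinct interactions on one day add four, so
  CDE may exceed the length of stay.
* **CDED** (cumulative drug exposure density): CDE divided by the length
  of stay, an intensity-adjusted measure that removes the mechanical
  correlation between longer stays and larger cumulative counts. For
  PP/HPP it lies in [0, 1]; for DDIs/PIMs it is a mean daily event count.

Length of stay is counted inclusively: `discharge − admission + 1`
calendar days, which is also the number of rows of the daily matrix, so
CDE(PP) ≤ LOS holds by construction.

## Daily determinant detection

The unit of analysis is the calendar day. Administration timestamps are
truncated to dates on read, and repeated administrations of a drug within
one day count once.

* **PP / HPP**: a day has PP when the number of distinct ATC codes
  administered is ≥ 5, HPP when it is ≥ 10 (both thresholds
  configurable, `exposure_thresholds()`). The records' codes are counted
  as given — typically at ATC level 5 (substance). Because "distinct
  drugs" could defensibly be counted at a coarser level, a
  `count_atc_level` roll-up option is exposed; the default (as-given)
  treats distinct substance codes as distinct drugs.
* **Conditioning-chemotherapy exclusion**: when a transplant date is
  recorded, antineoplastic agents (ATC class L01) administered on days
  *strictly before* the transplant day are excluded from the PP/HPP count,
  so that high-dose conditioning protocols do not read as polypharmacy.
  The transplant day itself is not excluded, and the exclusion applies
  only to the distinct-drug count — L01 drugs still participate in DDI and
  PIM detection. With no transplant date the exclusion is inert.
* **DDIs**: a knowledge table lists interacting ATC term pairs at four
  severity levels, grouped as *major* (contraindicated, should be avoided)
  and *moderate* (precaution of use, to take into account). An interaction
  fires on a day when two **distinct** administered codes match the two
  terms (prefix semantics, either orientation); one code never supplies
  both partners. Events are de-duplicated per day by the canonical sorted
  term pair, taking the worst severity when a pair is listed at several
  levels.
* **PIMs**: administered codes are cross-referenced daily against an
  ATC-based reference list, for patients aged ≥ 65 at admission only.
  Below that age the result is *not applicable* — propagated as missing,
  never as zero — so cohort PIM summaries use the eligible subgroup as
  denominator.

Conventional metrics are read off the first and last rows of the daily
matrix: presence (binary) and event count at admission and at discharge,
plus presence on any stay day. Each patient is classified into one of four
trajectories by the admission/discharge presence pair: `0→0`, `0→1`,
`1→0`, `1→1`.

## Comparison statistics

The normality of each metric is screened with the Shapiro–Wilk test at
α = 0.05 (`shapiro_wilk_gate()`); the package's comparison statistics are
non-parametric throughout, matching the heavily skewed distributions these
metrics have in practice. Associations between conventional counts at a
time point and cumulative exposure use the Spearman rank correlation
computed as the Pearson correlation of mid-ranks, with the two-sided
t-approximation `t = rs·sqrt((n−2)/(1−rs²))` on `n − 2` degrees of
freedom; |rs| < 0.3 is flagged as *weak*, the conventional reading that a
single time point does not reflect cumulative burden. An exact permutation
p value is available for n ≤ 8 (40 320 enumerated permutations); full
enumeration grows factorially and adds nothing for a descriptive contrast,
so larger samples use the t-approximation. No multiplicity adjustment is
applied: the correlations are reported as raw descriptive values.

Per-trajectory descriptives (mean, median, quartiles, range) use linear
interpolation between order statistics (base R `quantile` type 7), the
default convention of mainstream statistical environments. The difference
in medians between exposed and unexposed patients (`median_difference()`)
is purely descriptive; no inferential test is attached.

## Factorial analysis of mixed data

To ask whether the cumulative metrics carry information beyond the
conventional ones, the package fits a factorial analysis of mixed data
(FAMD) from scratch (`famd_fit()`):

* quantitative columns are centred and scaled to unit variance with the
  **population (divisor-n)** convention;
* each qualitative column is expanded to level indicators; indicator *k*
  is divided by √p̄ₖ (its level proportion) and centred, so a variable
  with K observed levels carries inertia K − 1;
* the combined matrix is decomposed by SVD; eigenvalues are squared
  singular values divided by n, giving the identities the tests verify:
  total inertia = p_quant + (Σ categories − p_qual), per-dimension
  contributions sum to 100 %, and the variance of row coordinates along a
  dimension equals its eigenvalue.

Variable contributions aggregate category contributions to their parent
variable; cos² is the share of a variable's own inertia carried by a
dimension (for a quantitative variable, its squared correlation with the
component). Signs of singular vectors are arbitrary, so each dimension is
deterministically oriented with its largest-|loading| column positive. The
expected-average contribution threshold, 100 / (number of variables), is
the usual reference line for reading contribution plots; an exact tie is
not flagged.

`build_mixed_table()` fixes the analysis variable list: counts of drugs
and DDIs at admission and discharge plus CDE (or CDED) of PP, HPP, and DDI
as quantitative variables; presence of PP, HPP, DDI at admission and
discharge as qualitative variables. PIMs are always excluded — they apply
only to the ≥ 65 subgroup and would impose structural missingness.
Severity-specific DDI counts are not included by default; the function
operates on the metrics table, so alternative variable sets can be
assembled from it directly. Qualitative columns with a single observed
level (e.g. no patient hyperpolymedicated at admission) are dropped with a
warning; rows with missing values are dropped with a logged count. Three
components are reported by default.

Degenerate inputs are handled explicitly: fewer than 2 rows error;
zero-variance quantitative columns are dropped with a warning; a matrix
rank below the requested number of components returns fewer components
with a warning.

## The synthetic cohort generator

No real patient data ship with the package. `generate_cohort()` draws
cohorts whose *structure* matches what the metrics were designed for — an
autologous stem-cell-transplant-like stay — so that every stage of the
pipeline is exercisable and testable offline:

* length of stay uniform on 14–52 days; age uniform on 21–70 years
  (defaults of `cohort_config()`);
* expected daily distinct-drug count follows a piecewise-linear
  admission → peak → discharge profile (defaults 3 → 13 → 5, peak at 40 %
  of the stay), with Poisson dispersion around the expectation — the
  simplest count-noise model consistent with large day-to-day swings;
  with these defaults stay-level PP is near-universal while admission
  HPP is rare, echoing the qualitative pattern such cohorts show;
* codes are drawn from a built-in palette of ~50 syntactically valid ATC
  codes across classes A, B, C, J, L, N; the palette deliberately excludes
  L01 and every family on the packaged PIM list;
* days before the transplant day (placed at 20 % of the stay) receive a
  conditioning L01 agent, exercising the exclusion path;
* on peak-phase days (expected count within 30 % of the peak), a known
  interacting pair from the packaged toy DDI table is co-administered with
  probability `ddi_pair_rate` (default 0.6);
* patients aged ≥ 65 carry, with probability `pim_rate_elderly`
  (default 0.8), a chronic PIM administered every day — so for those
  patients PIM CDE equals the length of stay exactly, a property the
  tests use as a planted-truth oracle.

Each patient draws from a pseudo-random substream keyed by the seed and
the patient index, so cohorts are byte-reproducible and the first k
patients are unchanged when a cohort grows. The generator also emits a
`truth` table recomputed from the emitted records by plain brute-force
loops, independent of the vectorised detection code — the tests require
exact agreement between the two.

What the generator does **not** emulate: dose and route semantics,
pharmacologically accurate interaction pairs, correlated drug persistence
(each day's palette draw is independent), weekend/ward effects, or any
clinical outcome. Passing tests therefore demonstrate the correctness of
the computation, not the clinical behaviour of the metrics on real
warehouse extracts.

`figure1_fixture()` is a deterministic single-patient worked example: a
34-day stay with exactly 5 distinct drugs on day 1, ≥ 5 on days 1–6,
10–25 and 27–28, ≥ 10 on days 15–21 only, and 1 drug on day 34. Through
the pipeline it gives CDE(PP) = 24 days, CDE(HPP) = 7 days,
CDED(PP) = 24/34, and a `1→0` polypharmacy trajectory.

## Numerical and I/O conventions

* CSV dialect fixed: UTF-8, comma separator, header row, ISO-8601 dates;
  write/read round trips reproduce normalised records exactly, and
  rerunning any pipeline command on the same inputs is byte-identical.
* CDE values are integers by construction; CDED is kept as an exact ratio
  in memory and rendered at 6 decimals in CSV output.
* Administration rows dated outside the patient's stay are dropped with a
  warning (boundary artifacts are common in warehouse extracts); an
  invalid date or ATC code in any input is an error naming the offending
  line.
* ATC terms of any level are accepted in the DDI table and PIM list;
  administration records are usually level-5 codes but coarser codes are
  accepted and treated as distinct drug entities.

Problem sizes in the test suite (cohorts of 25–200 patients, 500-instance
oracle sweeps, 1000-replicate type-I simulation at n = 30) were chosen as
the smallest at which the checked properties are sharp.

## Limitations

The metrics treat every administration row as an actual administration;
prescription-order extracts would need upstream filtering. CDE weights all
exposure days equally — no recency weighting or dose intensity (weighted
cumulative exposure models address that niche and are out of scope). The
trajectory classification uses only the two boundary days. And thresholds
(5, 10, age 65) are conventions, not clinically validated cut-points; they
are parameters, not constants, throughout the package.
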
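Package: cdexposure
Title: Cumulative Drug Exposure Metrics from Hospital Medication
    Administration Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cumulative drug exposure (CDE) and cumulative drug
    exposure density (CDED) for four prescribing determinants --
    polypharmacy, hyperpolypharmacy, drug-drug interactions, and
    potentially inappropriate medications -- from daily in-hospital drug
    administration records coded with the WHO ATC classification.
    Includes readers and writers for the long-format administration,
    stay, interaction-table, and inappropriate-medication-list inputs;
    daily determinant detection; conventional point-in-time metrics and
    admission-to-discharge trajectory groups; comparison statistics
    (Shapiro-Wilk gate, Spearman rank correlations, trajectory
    descriptives, median differences); a factorial analysis of mixed
    data; a synthetic cohort generator emulating stem-cell-transplant
    stays; and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
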
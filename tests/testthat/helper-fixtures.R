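# Shared in-code fixtures: tiny stays, record tables, and CSV writers.

make_stay <- function(patient_id = "P1",
                      admission = "2021-01-01",
                      discharge = "2021-01-10",
                      transplant = NA,
                      age = 58L) {
  tibble::tibble(
    patient_id = patient_id,
    admission_date = as.Date(admission),
    discharge_date = as.Date(discharge),
    transplant_date = as.Date(transplant),
    age_years = as.integer(age)
  )
}

# One administration row per code per day; days is an integer vector of
# day indices (1 = admission), codes_by_day a list parallel to days.
make_records <- function(stay, days, codes_by_day) {
  stopifnot(length(days) == length(codes_by_day))
  dplyr::bind_rows(lapply(seq_along(days), function(i) {
    tibble::tibble(
      patient_id = stay$patient_id,
      date = stay$admission_date + (days[i] - 1L),
      atc_code = codes_by_day[[i]],
      drug_label = NA_character_
    )
  }))
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Brute-force DDI oracle: explicit triple loop over code pairs and table
# rows, independent of detect_ddis().
brute_force_ddis <- function(codes, kb) {
  codes <- unique(codes)
  found <- list()
  for (i in seq_len(nrow(kb))) {
    hit <- FALSE
    for (a in codes) {
      for (b in codes) {
        if (a != b &&
          startsWith(a, kb$term1[i]) && startsWith(b, kb$term2[i])) {
          hit <- TRUE
        }
      }
    }
    if (hit) {
      pair <- sort(c(kb$term1[i], kb$term2[i]))
      key <- paste(pair, collapse = "|")
      major <- kb$severity_group[i] == "major"
      if (is.null(found[[key]])) {
        found[[key]] <- list(pair = pair, major = major)
      } else {
        found[[key]]$major <- found[[key]]$major || major
      }
    }
  }
  if (length(found) == 0) {
    return(tibble::tibble(
      term1 = character(), term2 = character(), severity_group = character()
    ))
  }
  keys <- sort(names(found))
  tibble::tibble(
    term1 = vapply(found[keys], function(f) f$pair[1], character(1), USE.NAMES = FALSE),
    term2 = vapply(found[keys], function(f) f$pair[2], character(1), USE.NAMES = FALSE),
    severity_group = ifelse(
      vapply(found[keys], function(f) f$major, logical(1), USE.NAMES = FALSE),
      "major", "moderate"
    )
  )
}

# Textbook mid-rank Spearman oracle: ranks by counting, Pearson formula by
# explicit sums.
brute_force_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Random small DDI instance for oracle equivalence tests.
random_ddi_instance <- function() {
  letters_pool <- c("A", "B", "C", "J", "L", "N")
  rand_code <- function(n) {
    paste0(
      sample(letters_pool, n, TRUE),
      sprintf("%02d", sample(0:19, n, TRUE)),
      sample(LETTERS[1:4], n, TRUE), sample(LETTERS[1:4], n, TRUE),
      sprintf("%02d", sample(1:9, n, TRUE))
    )
  }
  codes <- unique(rand_code(sample(2:8, 1)))
  n_kb <- sample(1:6, 1)
  truncate_at <- c(1, 3, 4, 5, 7)
  rand_term <- function() {
    code <- rand_code(1)
    substr(code, 1, sample(truncate_at, 1))
  }
  kb <- tibble::tibble(
    term1 = vapply(seq_len(n_kb), function(i) rand_term(), character(1)),
    term2 = vapply(seq_len(n_kb), function(i) rand_term(), character(1)),
    level = sample(
      c("contraindicated", "should_be_avoided", "precaution_of_use", "to_take_into_account"),
      n_kb, TRUE
    )
  )
  kb <- kb[kb$term1 != kb$term2, , drop = FALSE]
  # bias some rows toward firing: rewrite terms as prefixes of actual codes
  if (nrow(kb) > 0 && length(codes) >= 2) {
    for (i in seq_len(nrow(kb))) {
      if (stats::runif(1) < 0.5) {
        ab <- sample(codes, 2)
        kb$term1[i] <- substr(ab[1], 1, sample(truncate_at, 1))
        kb$term2[i] <- substr(ab[2], 1, sample(truncate_at, 1))
      }
    }
    kb <- kb[kb$term1 != kb$term2, , drop = FALSE]
  }
  kb$severity_group <- ddi_severity_group(kb$level)
  list(codes = codes, kb = kb)
}

# Independent FAMD route: model.matrix indicators + eigendecomposition of
# the divisor-n column covariance.
reference_famd_eigen <- function(quanti, quali) {
  n <- nrow(quanti)
  Zq <- apply(as.matrix(quanti), 2, function(v) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  })
  Zlist <- list(Zq)
  for (v in names(quali)) {
    ind <- stats::model.matrix(~ 0 + quali[[v]])
    p <- colMeans(ind)
    Zlist <- c(Zlist, list(sweep(sweep(ind, 2, p), 2, sqrt(p), "/")))
  }
  Z <- do.call(cbind, Zlist)
  ev <- eigen(crossprod(Z) / n, symmetric = TRUE)
  list(
    eigenvalues = ev$values[ev$values > max(ev$values) * 1e-12],
    Z = Z, vectors = ev$vectors
  )
}

# Random mixed table for FAMD oracle tests.
random_mixed_table <- function(n = 25, p_quant = 3, p_qual = 2) {
  quanti <- as.data.frame(matrix(stats::rnorm(n * p_quant), n, p_quant))
  names(quanti) <- paste0("q", seq_len(p_quant))
  quali <- as.data.frame(lapply(seq_len(p_qual), function(j) {
    nlev <- sample(2:3, 1)
    factor(sample(letters[seq_len(nlev)], n, TRUE))
  }))
  names(quali) <- paste0("c", seq_len(p_qual))
  # ensure every level observed at least twice so no degenerate columns
  for (j in seq_along(quali)) {
    quali[[j]] <- droplevels(quali[[j]])
    if (nlevels(quali[[j]]) < 2) {
      quali[[j]] <- factor(rep(c("a", "b"), length.out = n))
    }
  }
  list(quanti = quanti, quali = quali)
}
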
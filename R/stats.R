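# Comparison statistics: normality gate, Spearman rank correlations,
# trajectory descriptives, and median differences.

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and reports whether a normal distribution is
#' tenable at level `alpha`; non-normality gates the downstream analyses
#' onto non-parametric methods. Samples outside the test's supported size
#' range (3--5000) or with zero variance are flagged not testable rather
#' than erroring.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param alpha Significance level (default 0.05).
#' @return List: `testable`, `statistic`, `p_value`, `normal`
#'   (`p_value >= alpha`), `n`.
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 3 || n > 5000 || stats::sd(v) == 0) {
    return(list(
      testable = FALSE, statistic = NA_real_, p_value = NA_real_,
      normal = NA, n = n
    ))
  }
  sw <- stats::shapiro.test(v)
  list(
    testable = TRUE,
    statistic = unname(sw$statistic),
    p_value = sw$p.value,
    normal = sw$p.value >= alpha,
    n = n
  )
}

# All permutations of 1..n as a matrix (n! rows); used by the exact
# Spearman option. Kept small: n <= 8 (40320 rows).
perm_matrix <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    shifted <- sub + (sub >= i)
    cbind(rep(i, nrow(sub)), shifted)
  }))
}

#' Spearman rank correlation
#'
#' Computes the rank correlation as the Pearson correlation of average
#' (mid-) ranks, so ties are handled by the textbook mid-rank convention.
#' The two-sided p value uses the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on `n - 2` degrees of freedom;
#' `|rs| = 1` yields `p = 0`. For very small samples (`n <= 8`) an exact
#' permutation p value can be requested instead.
#'
#' @param x,y Numeric vectors of equal length; pairs with an `NA` are
#'   dropped.
#' @param weak_threshold Absolute correlation below which the association
#'   is flagged weak (default 0.3).
#' @param exact Use the exact permutation null (only honoured for
#'   `n <= 8`; larger samples fall back to the t approximation with a
#'   message).
#' @return List: `defined`, `rs`, `p_value`, `n`, `weak`
#'   (`|rs| < weak_threshold`), `method`. When either vector is constant
#'   in rank the correlation is undefined: `defined = FALSE` and the
#'   estimates are `NA`.
#' @export
spearman_cor <- function(x, y, weak_threshold = 0.3, exact = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  undefined <- list(
    defined = FALSE, rs = NA_real_, p_value = NA_real_, n = n,
    weak = NA, method = NA_character_
  )
  if (n < 3) {
    return(undefined)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(undefined)
  }
  rs <- stats::cor(rx, ry)

  if (exact && n > 8) {
    message("spearman_cor: exact permutation p available for n <= 8; using t approximation")
    exact <- FALSE
  }
  if (exact) {
    perms <- perm_matrix(n)
    rp <- matrix(ry[perms], nrow(perms), n)
    mx <- mean(rx)
    my <- mean(ry)
    num <- rp %*% rx - n * mx * my
    rs_null <- as.vector(num) / ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rs_null) >= abs(rs) - 1e-12)
    method <- "exact_permutation"
  } else if (abs(rs) >= 1 - 1e-12) {
    p <- 0
    method <- "t_approximation"
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t_approximation"
  }
  list(
    defined = TRUE, rs = rs, p_value = p, n = n,
    weak = abs(rs) < weak_threshold, method = method
  )
}

#' Descriptive statistics of CDE/CDED by trajectory group
#'
#' Splits the applicable patients for one determinant by their
#' admission-to-discharge trajectory and summarises the chosen exposure
#' value per group: n, mean, median, quartiles (linear interpolation
#' between order statistics), and range. Empty groups are omitted.
#'
#' @param metrics Metrics tibble ([compute_determinant_metrics()]).
#' @param determinant One of [determinant_labels()].
#' @param value `"cde"` or `"cded"`.
#' @return Tibble with columns `group`, `n`, `mean`, `median`, `q1`, `q3`,
#'   `min`, `max`.
#' @export
trajectory_descriptives <- function(metrics, determinant, value = c("cde", "cded")) {
  determinant <- match.arg(determinant, determinant_labels())
  value <- match.arg(value)
  m <- metrics[metrics$determinant == determinant & metrics$applicable, , drop = FALSE]
  if (nrow(m) == 0) {
    stop("trajectory_descriptives: no applicable patients for ", determinant,
      call. = FALSE
    )
  }
  m |>
    dplyr::group_by(group = .data$trajectory) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      median = stats::median(.data[[value]]),
      q1 = unname(stats::quantile(.data[[value]], 0.25, type = 7)),
      q3 = unname(stats::quantile(.data[[value]], 0.75, type = 7)),
      min = min(.data[[value]]),
      max = max(.data[[value]]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
}

#' Difference in medians between exposed and unexposed patients
#'
#' A descriptive contrast: the median exposure value among patients exposed
#' at a time point minus the median among those unexposed. Not computable
#' when either group is empty.
#'
#' @param values_exposed,values_unexposed Numeric vectors (`NA`s dropped).
#' @return List: `computable`, `d`, `n_exposed`, `n_unexposed`.
#' @export
median_difference <- function(values_exposed, values_unexposed) {
  ve <- values_exposed[!is.na(values_exposed)]
  vu <- values_unexposed[!is.na(values_unexposed)]
  if (length(ve) == 0 || length(vu) == 0) {
    return(list(
      computable = FALSE, d = NA_real_,
      n_exposed = length(ve), n_unexposed = length(vu)
    ))
  }
  list(
    computable = TRUE,
    d = stats::median(ve) - stats::median(vu),
    n_exposed = length(ve),
    n_unexposed = length(vu)
  )
}

#' Cohort correlation table
#'
#' For each determinant, time point (admission, discharge) and exposure
#' metric (CDE, CDED): the Spearman correlation between the conventional
#' event count at the time point and the cumulative value, over applicable
#' patients. Also reports the median difference in the cumulative value
#' between patients exposed and unexposed at the time point.
#'
#' @param metrics Metrics tibble ([compute_determinant_metrics()]).
#' @param determinants Determinants to tabulate (default PP, HPP, DDI,
#'   PIM, matching the usual reporting; severity sub-determinants can be
#'   added).
#' @return Tibble: `determinant`, `timepoint`, `metric`, `rs`, `p_value`,
#'   `n`, `weak`, `median_diff`.
#' @export
cohort_correlations <- function(metrics,
                                determinants = c("PP", "HPP", "DDI", "PIM")) {
  determinants <- intersect(determinants, unique(metrics$determinant))
  grid <- expand.grid(
    determinant = determinants,
    timepoint = c("admission", "discharge"),
    metric = c("cde", "cded"),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    det <- grid$determinant[i]
    tp <- grid$timepoint[i]
    met <- grid$metric[i]
    m <- metrics[metrics$determinant == det & metrics$applicable, , drop = FALSE]
    counts <- m[[paste0("count_", tp)]]
    pres <- m[[paste0("present_", tp)]]
    sp <- spearman_cor(counts, m[[met]])
    md <- median_difference(m[[met]][pres], m[[met]][!pres])
    tibble::tibble(
      determinant = det, timepoint = tp, metric = met,
      rs = sp$rs, p_value = sp$p_value, n = sp$n, weak = sp$weak,
      median_diff = md$d
    )
  })
  dplyr::bind_rows(rows)
}

#' Cohort trajectory descriptives table
#'
#' [trajectory_descriptives()] for every determinant and both exposure
#' metrics, in long form.
#'
#' @inheritParams cohort_correlations
#' @return Tibble: `determinant`, `metric`, `group`, `n`, `mean`,
#'   `median`, `q1`, `q3`, `min`, `max`.
#' @export
cohort_trajectories <- function(metrics,
                                determinants = c("PP", "HPP", "DDI", "PIM")) {
  determinants <- intersect(determinants, unique(metrics$determinant))
  has_rows <- vapply(determinants, function(det) {
    any(metrics$determinant == det & metrics$applicable)
  }, logical(1))
  determinants <- determinants[has_rows]
  rows <- lapply(determinants, function(det) {
    dplyr::bind_rows(lapply(c("cde", "cded"), function(met) {
      d <- trajectory_descriptives(metrics, det, met)
      tibble::tibble(determinant = det, metric = met, d)
    }))
  })
  dplyr::bind_rows(rows)
}
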
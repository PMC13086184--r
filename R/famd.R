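# Factorial analysis of mixed data (FAMD).
#
# Quantitative columns are centred and scaled to unit variance with the
# population (divisor-n) convention; each qualitative column is expanded to
# level indicators, indicator k is divided by sqrt(p_k) (p_k the level
# proportion) and centred. The combined matrix is decomposed by SVD;
# eigenvalues are squared singular values divided by n. Under this weighting
# a qualitative variable with K observed levels carries inertia K - 1, so
# total inertia = p_quant + (total categories - p_qual).

#' Assemble the mixed analysis table for FAMD
#'
#' Builds the patient-level table the factorial analysis runs on:
#' quantitative columns are the conventional counts at admission and
#' discharge (distinct drugs, interactions) and the cumulative exposure of
#' PP, HPP, and DDIs (CDE or CDED, per `mode`); qualitative columns are the
#' presence of PP, HPP, and DDIs at admission and discharge. PIM variables
#' are always excluded: they apply only to the older-age subgroup and would
#' impose structural missingness on the full cohort. Rows with any missing
#' value are dropped (with a message); qualitative columns with a single
#' observed level are dropped with a warning.
#'
#' @param metrics Metrics tibble ([compute_determinant_metrics()]).
#' @param mode `"cde"` or `"cded"`: which cumulative metric enters the
#'   quantitative block.
#' @return List of class `mixed_table`: `quanti` (numeric data frame),
#'   `quali` (data frame of factors), `patient_id`, `mode`.
#' @export
build_mixed_table <- function(metrics, mode = c("cde", "cded")) {
  mode <- match.arg(mode)
  need <- c("PP", "HPP", "DDI")
  missing_det <- setdiff(need, unique(metrics$determinant))
  if (length(missing_det) > 0) {
    stop(
      "build_mixed_table: metrics lack determinant(s): ",
      paste(missing_det, collapse = ", "),
      call. = FALSE
    )
  }
  get <- function(det, col) {
    m <- metrics[metrics$determinant == det, , drop = FALSE]
    m <- m[order(m$patient_id), , drop = FALSE]
    stats::setNames(m[[col]], m$patient_id)
  }
  ids <- sort(unique(metrics$patient_id))
  quanti <- data.frame(
    n_drugs_admission = get("PP", "count_admission")[ids],
    n_drugs_discharge = get("PP", "count_discharge")[ids],
    n_ddis_admission = get("DDI", "count_admission")[ids],
    n_ddis_discharge = get("DDI", "count_discharge")[ids],
    row.names = ids
  )
  for (det in need) {
    quanti[[paste0(mode, "_", tolower(det))]] <- get(det, mode)[ids]
  }
  quali <- data.frame(
    pp_admission = get("PP", "present_admission")[ids],
    pp_discharge = get("PP", "present_discharge")[ids],
    hpp_admission = get("HPP", "present_admission")[ids],
    hpp_discharge = get("HPP", "present_discharge")[ids],
    ddi_admission = get("DDI", "present_admission")[ids],
    ddi_discharge = get("DDI", "present_discharge")[ids],
    row.names = ids
  )
  complete <- stats::complete.cases(quanti) & stats::complete.cases(quali)
  if (any(!complete)) {
    message(sprintf(
      "build_mixed_table: dropped %d row(s) with missing values", sum(!complete)
    ))
  }
  quanti <- quanti[complete, , drop = FALSE]
  quali <- quali[complete, , drop = FALSE]
  if (nrow(quanti) < 2) {
    stop("build_mixed_table: fewer than 2 complete rows", call. = FALSE)
  }
  quali[] <- lapply(quali, function(v) factor(ifelse(v, "yes", "no"), levels = c("no", "yes")))
  single <- vapply(quali, function(f) length(unique(f)) < 2, logical(1))
  if (any(single)) {
    warning(
      "build_mixed_table: dropped single-level qualitative column(s): ",
      paste(names(quali)[single], collapse = ", "),
      call. = FALSE
    )
    quali <- quali[, !single, drop = FALSE]
  }
  quali[] <- lapply(quali, droplevels)
  structure(
    list(
      quanti = quanti, quali = quali,
      patient_id = rownames(quanti), mode = mode
    ),
    class = "mixed_table"
  )
}

#' Fit a factorial analysis of mixed data
#'
#' Joint principal-component decomposition of standardized quantitative
#' variables and weighted indicator-coded qualitative variables (see the
#' file header for the exact weighting). Reports eigenvalues, explained
#' variance, row coordinates, and per-variable contributions (%) and cos2
#' per retained dimension; category-level contributions are aggregated to
#' their parent qualitative variable. Component signs are fixed
#' deterministically: the column with the largest absolute loading on each
#' dimension loads positively.
#'
#' @param table A `mixed_table` ([build_mixed_table()]), or any list with
#'   elements `quanti` (numeric data frame) and `quali` (data frame of
#'   factors; may have zero columns for an all-quantitative analysis).
#' @param n_components Number of dimensions to retain (default 3). If the
#'   matrix rank is lower, fewer are returned with a warning.
#' @return List of class `famd`: `eigenvalues` (all positive ones),
#'   `explained_variance_pct` (sums to 100 over all components),
#'   `cumulative_pct`, `n_components`, `row_coordinates`,
#'   `variable_contributions_pct`, `variable_cos2`, `column_loadings`,
#'   `variables`, `total_inertia`,
#'   `expected_contribution_threshold_pct` (`100 / n_variables`).
#' @export
famd_fit <- function(table, n_components = 3) {
  quanti <- as.data.frame(table$quanti)
  quali <- as.data.frame(table$quali)
  n <- nrow(quanti)
  if (n < 2) {
    stop("famd_fit: at least 2 rows required", call. = FALSE)
  }

  blocks <- list()
  col_var <- numeric(0)
  col_variable <- character(0)
  var_type <- character(0)

  if (ncol(quanti) > 0) {
    X <- as.matrix(quanti)
    ctr <- colMeans(X)
    sdp <- sqrt(colMeans(sweep(X, 2, ctr)^2))
    zero <- sdp == 0
    if (any(zero)) {
      warning(
        "famd_fit: dropped zero-variance quantitative column(s): ",
        paste(colnames(X)[zero], collapse = ", "),
        call. = FALSE
      )
      X <- X[, !zero, drop = FALSE]
      ctr <- ctr[!zero]
      sdp <- sdp[!zero]
    }
    Zq <- sweep(sweep(X, 2, ctr), 2, sdp, "/")
    blocks <- c(blocks, list(Zq))
    col_var <- c(col_var, rep(1, ncol(Zq)))
    col_variable <- c(col_variable, colnames(Zq))
    var_type <- c(var_type, stats::setNames(rep("quantitative", ncol(Zq)), colnames(Zq)))
  }
  if (ncol(quali) > 0) {
    for (v in names(quali)) {
      f <- droplevels(factor(quali[[v]]))
      if (nlevels(f) < 2) {
        stop("famd_fit: qualitative column '", v, "' has a single level", call. = FALSE)
      }
      ind <- stats::model.matrix(~ f - 1)
      colnames(ind) <- paste(v, levels(f), sep = ".")
      p_k <- colMeans(ind)
      Zk <- sweep(sweep(ind, 2, p_k), 2, sqrt(p_k), "/")
      blocks <- c(blocks, list(Zk))
      col_var <- c(col_var, 1 - p_k)
      col_variable <- c(col_variable, rep(v, ncol(ind)))
      var_type[v] <- "qualitative"
    }
  }
  if (length(blocks) == 0) {
    stop("famd_fit: no analysis columns", call. = FALSE)
  }
  Z <- do.call(cbind, blocks)

  sv <- svd(Z / sqrt(n))
  eig <- sv$d^2
  pos <- eig > max(eig) * 1e-12
  eig <- eig[pos]
  V <- sv$v[, pos, drop = FALSE]
  rank <- length(eig)
  ncomp <- min(n_components, rank)
  if (ncomp < n_components) {
    warning(sprintf(
      "famd_fit: rank %d < requested %d components; returning %d",
      rank, n_components, ncomp
    ), call. = FALSE)
  }
  # deterministic sign: largest-|loading| column positive on each dimension
  for (d in seq_len(rank)) {
    j <- which.max(abs(V[, d]))
    if (V[j, d] < 0) V[, d] <- -V[, d]
  }
  rownames(V) <- colnames(Z)

  total_inertia <- sum(col_var)
  explained <- 100 * eig / sum(eig)
  Fmat <- Z %*% V[, seq_len(ncomp), drop = FALSE]
  dimnames(Fmat) <- list(rownames(quanti), paste0("dim", seq_len(ncomp)))

  # column-level contributions and cos2, then aggregation per variable
  ctr_col <- 100 * V[, seq_len(ncomp), drop = FALSE]^2
  cos2_col <- sweep(
    sweep(V[, seq_len(ncomp), drop = FALSE]^2, 2, eig[seq_len(ncomp)], "*"),
    1, col_var, "/"
  )
  variables <- unique(col_variable)
  agg <- function(M) {
    out <- vapply(variables, function(v) {
      colSums(M[col_variable == v, , drop = FALSE])
    }, numeric(ncomp))
    out <- t(matrix(out, nrow = ncomp))
    dimnames(out) <- list(variables, paste0("dim", seq_len(ncomp)))
    out
  }
  contrib <- agg(ctr_col)
  # cos2 of a variable on a dimension: share of the variable's own inertia
  # carried by that dimension (for a quantitative variable this is the
  # squared correlation with the component)
  inertia_by_var <- vapply(variables, function(v) {
    sum(col_var[col_variable == v])
  }, numeric(1))
  cos2 <- agg(sweep(V[, seq_len(ncomp), drop = FALSE]^2, 2, eig[seq_len(ncomp)], "*"))
  cos2 <- sweep(cos2, 1, inertia_by_var, "/")

  structure(
    list(
      eigenvalues = eig,
      explained_variance_pct = explained,
      cumulative_pct = cumsum(explained),
      n_components = ncomp,
      row_coordinates = Fmat,
      variable_contributions_pct = contrib,
      variable_cos2 = cos2,
      column_loadings = V[, seq_len(ncomp), drop = FALSE],
      variables = stats::setNames(var_type[variables], variables),
      total_inertia = total_inertia,
      expected_contribution_threshold_pct = 100 / length(variables)
    ),
    class = "famd"
  )
}

#' @export
print.famd <- function(x, ...) {
  cat(sprintf(
    "FAMD: %d variables, total inertia %.3f, %d component(s) retained\n",
    length(x$variables), x$total_inertia, x$n_components
  ))
  df <- data.frame(
    dimension = seq_along(x$eigenvalues),
    eigenvalue = round(x$eigenvalues, 4),
    explained_pct = round(x$explained_variance_pct, 1),
    cumulative_pct = round(x$cumulative_pct, 1)
  )
  print(utils::head(df, max(x$n_components, 5)), row.names = FALSE)
  invisible(x)
}

#' Variables ranked by contribution to one dimension
#'
#' Sorts variables by their contribution (%) to a dimension and flags those
#' contributing more than the expected average (100 / number of variables),
#' the usual reference line on FAMD contribution plots.
#'
#' @param fit A `famd` object ([famd_fit()]).
#' @param dimension Dimension index (1-based, within the retained
#'   components).
#' @return Tibble: `variable`, `type`, `contribution_pct`, `cos2`,
#'   `above_threshold`, ordered by descending contribution.
#' @export
top_contributors <- function(fit, dimension) {
  if (!inherits(fit, "famd")) {
    stop("top_contributors: not a famd fit", call. = FALSE)
  }
  if (length(dimension) != 1 || dimension < 1 || dimension > fit$n_components) {
    stop(sprintf(
      "top_contributors: dimension must be in 1..%d", fit$n_components
    ), call. = FALSE)
  }
  ctr <- fit$variable_contributions_pct[, dimension]
  out <- tibble::tibble(
    variable = names(ctr),
    type = unname(fit$variables[names(ctr)]),
    contribution_pct = unname(ctr),
    cos2 = unname(fit$variable_cos2[, dimension]),
    # strict comparison with a tie guard so a contribution exactly at the
    # expected average is not flagged by floating-point noise
    above_threshold = unname(ctr) > fit$expected_contribution_threshold_pct * (1 + 1e-9)
  )
  dplyr::arrange(out, dplyr::desc(.data$contribution_pct))
}
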
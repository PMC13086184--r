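# Normality gate, Spearman correlations, trajectory descriptives, median
# differences.

test_that("shapiro_wilk_gate flags untestable inputs and matches the base test", {
  expect_false(shapiro_wilk_gate(rep(3, 10))$testable)
  expect_false(shapiro_wilk_gate(c(1, 2))$testable)
  set.seed(1)
  v <- rnorm(50)
  g <- shapiro_wilk_gate(v)
  sw <- shapiro.test(v)
  expect_equal(g$statistic, unname(sw$statistic))
  expect_equal(g$p_value, sw$p.value)
  expect_equal(g$normal, sw$p.value >= 0.05)
})

test_that("the gate rejects heavily skewed data and holds its type-I error on normal data", {
  set.seed(77)
  # skewed: exponential at n = 200
  rejected <- vapply(1:200, function(i) {
    !shapiro_wilk_gate(rexp(200))$normal
  }, logical(1))
  expect_gt(mean(rejected), 0.99)
  # type I on standard normal at n = 30, 1000 replicates; band = alpha +/- 2 SE
  type1 <- vapply(1:1000, function(i) {
    !shapiro_wilk_gate(rnorm(30))$normal
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(type1) - 0.05), 2 * se)
})

test_that("spearman_cor handles perfect monotone, antitone, and degenerate inputs", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$rs, 1)
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$p_value, 0)
  expect_equal(spearman_cor(1:4, c(8, 6, 4, 2))$rs, -1)
  expect_false(spearman_cor(rep(1, 5), 1:5)$defined)
  expect_false(spearman_cor(1:2, 2:1)$defined)
  # invariance under strictly increasing transforms
  set.seed(8)
  x <- runif(20)
  y <- runif(20)
  base <- spearman_cor(x, y)$rs
  expect_equal(spearman_cor(exp(x), y)$rs, base)
  expect_equal(spearman_cor(x, y^3)$rs, base)
  expect_equal(spearman_cor(x, x)$rs, 1)
})

test_that("tied data match the textbook mid-rank formula and cor.test", {
  # hand-checkable case
  x <- c(1, 2, 2, 3)
  y <- c(1, 3, 2, 4)
  got <- spearman_cor(x, y)
  expect_equal(got$rs, brute_force_spearman(x, y))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$rs, unname(ct$estimate))
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  # randomised property
  set.seed(12)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, TRUE)
    y <- sample(1:5, n, TRUE)
    s <- spearman_cor(x, y)
    if (s$defined) {
      expect_equal(s$rs, brute_force_spearman(x, y))
    }
  }
})

test_that("the weak-correlation flag follows the 0.3 convention", {
  set.seed(3)
  x <- rnorm(100)
  weakish <- spearman_cor(x, rnorm(100))
  expect_true(weakish$weak)
  strong <- spearman_cor(x, x + rnorm(100, sd = 0.1))
  expect_false(strong$weak)
  expect_equal(abs(strong$rs) < 0.3, strong$weak)
})

test_that("exact permutation p agrees with full enumeration and gates on n", {
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  ex <- spearman_cor(x, y, exact = TRUE)
  expect_equal(ex$method, "exact_permutation")
  # independent enumeration of all 120 permutations via expand.grid
  all_p <- {
    idx <- expand.grid(rep(list(1:5), 5))
    idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 5), ]
    rs_obs <- spearman_cor(x, y)$rs
    rs_all <- apply(idx, 1, function(p) {
      suppressWarnings(cor(rank(x), rank(y[unlist(p)])))
    })
    mean(abs(rs_all) >= abs(rs_obs) - 1e-12)
  }
  expect_equal(ex$p_value, all_p)
  expect_message(
    big <- spearman_cor(rnorm(12), rnorm(12), exact = TRUE),
    "n <= 8"
  )
  expect_equal(big$method, "t_approximation")
})

test_that("trajectory descriptives match sort-based order statistics", {
  co <- generate_cohort(cohort_config(20, 21))
  daily <- build_daily_matrix(co$administrations, co$stays, co$ddi_table, co$pim_list)
  m <- compute_determinant_metrics(daily)
  for (det in c("PP", "DDI")) {
    d <- trajectory_descriptives(m, det, "cde")
    expect_true(all(d$min <= d$q1 & d$q1 <= d$median &
      d$median <= d$q3 & d$q3 <= d$max))
    sub <- m[m$determinant == det, ]
    for (g in d$group) {
      v <- sort(sub$cde[sub$trajectory == g])
      expect_equal(d$n[d$group == g], length(v))
      med <- if (length(v) %% 2 == 1) {
        v[(length(v) + 1) / 2]
      } else {
        (v[length(v) / 2] + v[length(v) / 2 + 1]) / 2
      }
      expect_equal(d$median[d$group == g], med)
      expect_equal(d$min[d$group == g], v[1])
      expect_equal(d$max[d$group == g], v[length(v)])
    }
  }
  # degenerate single-patient group: all order statistics collapse
  one <- m[m$determinant == "PP", ][1, ]
  d1 <- trajectory_descriptives(one, "PP", "cde")
  expect_equal(d1$n, 1)
  expect_equal(d1$min, d1$q1)
  expect_equal(d1$q1, d1$median)
  expect_equal(d1$median, d1$q3)
  expect_equal(d1$q3, d1$max)
})

test_that("descriptives are invariant under patient order permutation", {
  co <- generate_cohort(cohort_config(10, 2))
  daily <- build_daily_matrix(co$administrations, co$stays, co$ddi_table, co$pim_list)
  m <- compute_determinant_metrics(daily)
  set.seed(5)
  m_shuffled <- m[sample(nrow(m)), ]
  expect_equal(
    trajectory_descriptives(m, "PP", "cded"),
    trajectory_descriptives(m_shuffled, "PP", "cded")
  )
})

test_that("median_difference computes direct medians and flags empty groups", {
  expect_equal(median_difference(c(10, 20, 30), c(1, 2, 3))$d, 18)
  expect_equal(median_difference(1:5, 1:5)$d, 0)
  expect_false(median_difference(numeric(0), 1:3)$computable)
  set.seed(6)
  v <- rnorm(40)
  grp <- sample(c(TRUE, FALSE), 40, TRUE)
  md <- median_difference(v[grp], v[!grp])
  expect_equal(md$d, median(v[grp]) - median(v[!grp]))
  expect_equal(md$n_exposed, sum(grp))
})

test_that("cohort correlation table restricts PIM rows to eligible patients", {
  co <- generate_cohort(cohort_config(30, 14))
  daily <- build_daily_matrix(co$administrations, co$stays, co$ddi_table, co$pim_list)
  m <- compute_determinant_metrics(daily)
  ct <- cohort_correlations(m)
  expect_setequal(unique(ct$determinant), c("PP", "HPP", "DDI", "PIM"))
  n_elder <- sum(co$stays$age_years >= 65)
  expect_true(all(ct$n[ct$determinant == "PIM"] == n_elder))
  expect_true(all(ct$n[ct$determinant == "PP"] == 30))
  expect_equal(ct$weak, abs(ct$rs) < 0.3)
})
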
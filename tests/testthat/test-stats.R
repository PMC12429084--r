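# Published processing-speed summary: ePVS group 98.7 +/- 12.7 (n = 26),
# no-ePVS group 105.1 +/- 14.5 (n = 34).
psi_present <- list(m = 98.7, s = 12.7, n = 26L)
psi_absent <- list(m = 105.1, s = 14.5, n = 34L)

test_that("pooled t test reproduces the audited group comparison", {
  r <- pooled_t_test(psi_present$m, psi_present$s, psi_present$n,
                     psi_absent$m, psi_absent$s, psi_absent$n)
  expect_equal(r$effect_size, -6.4)
  expect_equal(r$df, 58)
  expect_equal(r$statistic, -1.786, tolerance = 5e-4)
  expect_equal(round(r$p_value, 2), 0.08)

  same <- pooled_t_test(10, 2, 20, 10, 2, 20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(pooled_t_test(1, 0, 20, 2, 1, 20), "sd1")
})

test_that("raw-data overloads agree with the stats-package references", {
  set.seed(5)
  x <- rnorm(18, 1)
  y <- rnorm(25, 0.4, 1.6)
  tp <- pooled_t_test_raw(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(tp$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tp$p_value, ref$p.value, tolerance = 1e-10)
  tw <- welch_t_test_raw(x, y)
  refw <- t.test(x, y)
  expect_equal(tw$statistic, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(tw$df, unname(refw$parameter), tolerance = 1e-10)
})

test_that("Welch test matches its closed form and the pooled limit", {
  r <- welch_t_test(psi_present$m, psi_present$s, psi_present$n,
                    psi_absent$m, psi_absent$s, psi_absent$n)
  expect_equal(r$statistic, -1.818, tolerance = 5e-4)
  expect_equal(welch_t_test(10, 2, 20, 10, 2, 20)$p_value, 1)
  # equal variances and sizes: Welch equals pooled
  a <- welch_t_test(3, 1.5, 30, 2.4, 1.5, 30)
  b <- pooled_t_test(3, 1.5, 30, 2.4, 1.5, 30)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-6)
  expect_equal(a$df, b$df, tolerance = 1e-6)
})

test_that("Mann-Whitney U handles ties, separation and shifts", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  set.seed(12)
  expect_lt(mann_whitney_u(rnorm(200), rnorm(200, 1))$p_value, 0.001)
})

test_that("chi-square on 2x2 tables matches the closed form", {
  tab <- matrix(c(12, 3, 14, 31), 2)     # rows: exposure, cols: group
  r <- chi_square_2x2(tab)
  # closed form n (ad - bc)^2 / (r1 r2 c1 c2)
  oracle <- 60 * (12 * 31 - 14 * 3)^2 / (26 * 34 * 15 * 45)
  expect_equal(r$statistic, oracle, tolerance = 1e-10)
  expect_equal(r$statistic, 10.95, tolerance = 5e-4 / 10.95)
  expect_equal(r$df, 1)

  flat <- matrix(10, 2, 2)
  expect_equal(chi_square_2x2(flat)$statistic, 0)
  expect_equal(chi_square_2x2(flat)$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")

  # Yates correction never increases the statistic
  set.seed(7)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 8) + 1, 2)
    expect_lte(chi_square_2x2(t2, yates = TRUE)$statistic,
               chi_square_2x2(t2)$statistic + 1e-12)
  }
})

test_that("Fisher exact p equals full hypergeometric enumeration", {
  p <- fisher_exact_2x2(matrix(c(8, 1, 18, 33), 2))
  expect_equal(p$p_value, fisher_enum_p(8, 18, 1, 33), tolerance = 1e-7)
  # zero cells are fine
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 6, 3), 2))$p_value,
               fisher_enum_p(0, 6, 5, 3), tolerance = 1e-7)
})

test_that("Pearson correlation matches hand computation and recovers rho", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x)$effect_size, 1)
  expect_equal(pearson_r(x, c(1, 3, 2))$effect_size, 0.5)
  # generating correlation 0.22 at n = 5,000, as in the ePVS-group
  # ALPS ~ processing-speed association
  set.seed(41)
  n <- 5000
  u <- rnorm(n)
  v <- 0.22 * u + sqrt(1 - 0.22^2) * rnorm(n)
  r <- pearson_r(u, v)
  expect_equal(r$effect_size, 0.22, tolerance = 0.03 / 0.22)
  expect_lt(r$p_value, 1e-10)
})

test_that("Cohen's d follows the pooled formula", {
  expect_equal(cohens_d(5, 2, 30, 5, 2, 30)$effect_size, 0)
  expect_equal(cohens_d(0, 1, 50, 1, 1, 50)$effect_size, -1)
  d <- cohens_d(psi_present$m, psi_present$s, psi_present$n,
                psi_absent$m, psi_absent$s, psi_absent$n)
  expect_equal(d$effect_size, -0.465, tolerance = 1e-3 / 0.465)
  expect_true(d$ci_low < d$effect_size && d$effect_size < d$ci_high)
})

test_that("logistic regression matches the saturated-table odds ratio", {
  # null case: perfectly balanced, OR exactly 1
  x <- rep(0:1, each = 100)
  y <- rep(c(0, 1), 100)
  r0 <- logistic_fit(y, data.frame(x = x))
  expect_equal(r0$coefficients$odds_ratio[2], 1, tolerance = 1e-8)
  expect_true(r0$converged)

  # table [[12, 14], [3, 31]]: MLE OR equals the cross-product ratio 8.857
  xt <- rep(c(1, 1, 0, 0), c(12, 14, 3, 31))
  yt <- rep(c(1, 0, 1, 0), c(12, 14, 3, 31))
  rt <- logistic_fit(yt, data.frame(x = xt))
  expect_equal(rt$coefficients$odds_ratio[2], 12 * 31 / (14 * 3),
               tolerance = 1e-6)

  # complete separation is flagged, not silently reported
  sep <- logistic_fit(c(0, 0, 0, 1, 1, 1), data.frame(x = 1:6))
  expect_false(sep$converged)
})

test_that("linear regression is exact on exact data and standardizes correctly", {
  set.seed(3)
  X <- data.frame(a = rnorm(40), b = runif(40))
  beta <- c(2, -1.5)
  y <- 1 + as.matrix(X) %*% beta
  fit <- suppressWarnings(linear_fit(as.numeric(y), X))  # perfect-fit note
  expect_equal(fit$coefficients$estimate, c(1, beta), tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  # single predictor: standardized beta equals the correlation
  x1 <- rnorm(60)
  y1 <- 0.6 * x1 + rnorm(60)
  f1 <- linear_fit(y1, data.frame(x = x1), standardize = TRUE)
  expect_equal(f1$coefficients$std_beta[2], cor(x1, y1), tolerance = 1e-10)
})

test_that("the adjusted ALPS group contrast is well powered at the cohort size", {
  # covariate-adjusted group comparison (age, sex, hypertension) at n = 60:
  # the generating group effect should be detected in nearly every cohort
  ps <- vapply(1:40, function(seed) {
    co <- generate_cohort(cohort_params(seed = seed))
    fit <- linear_fit(co$alps, co[, c("epvs_present", "age", "sex",
                                      "hypertension")])
    fit$coefficients$p_value[fit$coefficients$term == "epvs_present"]
  }, 0)
  expect_gte(mean(ps < 0.05), 0.85)
  expect_lt(median(ps), 0.01)
})

test_that("VIF equals its closed form and is bounded below by 1", {
  # exactly orthogonal predictors
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, -1, -1, 1))
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-10)

  # exact correlation 0.9: VIF = 1 / (1 - 0.81) = 5.263...
  u <- as.numeric(scale(1:20))
  set.seed(6)
  z <- as.numeric(scale(residuals(lm(rnorm(20) ~ u))))
  y <- 0.9 * u + sqrt(1 - 0.81) * z
  v <- vif(cbind(x = u, y = y))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  expect_equal(unname(v[1]), 5.263, tolerance = 1e-4)

  set.seed(10)
  Xr <- matrix(rnorm(200), 50)
  expect_true(all(vif(Xr) >= 1))
  expect_error(vif(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
})
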
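test_that("the bias-corrected interval follows the stated quantile rule", {
  # symmetric case: z0 = 0, BC reduces to the plain percentile interval
  ci <- bc_interval(1:100, 50.5, 0.05)
  expect_equal(as.numeric(ci), c(3.475, 97.525))
  expect_false(attr(ci, "degenerate"))
  expect_equal(as.numeric(ci),
               unname(quantile(1:100, c(0.025, 0.975), type = 7)))

  # asymmetric estimate shifts the percentiles via the bias correction
  set.seed(1)
  boot <- rexp(2000)
  est <- median(boot) * 1.2
  ci2 <- bc_interval(boot, est, 0.05)
  z0 <- qnorm(mean(boot < est))
  probs <- pnorm(c(2 * z0 - qnorm(0.975), 2 * z0 + qnorm(0.975)))
  expect_equal(as.numeric(ci2), unname(quantile(boot, probs, type = 7)))
  expect_lt(ci2[1], ci2[2])

  const <- bc_interval(rep(2.5, 50), 2.5)
  expect_true(attr(const, "degenerate"))
  expect_equal(as.numeric(const), c(2.5, 2.5))
  expect_error(bc_interval(numeric(0), 1), "non-empty")
})

test_that("a null mediator path yields a near-zero indirect effect with a straddling CI", {
  p <- cohort_params(n_subjects = 5000L, path_b = 0,
                     noise_sd_outcome = 0.999, seed = 61L)
  co <- generate_cohort(p)
  m <- mediate(co, mediation_spec(mediator = "alps_std",
                                  outcome = "psi_std", n_boot = 500L,
                                  seed = 5L))
  expect_lt(abs(m$indirect), 0.03)
  expect_lt(m$ci_low, 0)
  expect_gt(m$ci_high, 0)
})

test_that("the OLS decomposition c = c' + a*b holds on every fitted sample", {
  for (seed in c(1L, 9L, 33L, 101L)) {
    co <- generate_cohort(cohort_params(seed = seed))
    m <- mediate(co, mediation_spec(n_boot = 50L, seed = 2L))
    expect_lt(abs(m$c - m$c_prime - m$indirect), 1e-10)
    expect_equal(m$indirect, m$a * m$b)
    expect_lte(m$ci_low, m$ci_high)
  }
})

test_that("the bootstrap is seed-deterministic", {
  co <- generate_cohort(cohort_params(seed = 3L))
  spec <- mediation_spec(n_boot = 400L, seed = 77L)
  m1 <- mediate(co, spec)
  m2 <- mediate(co, spec)
  expect_identical(m1[c("a", "b", "c_prime", "c", "indirect", "ci_low",
                        "ci_high", "boot_mean", "boot_sd")],
                   m2[c("a", "b", "c_prime", "c", "indirect", "ci_low",
                        "ci_high", "boot_mean", "boot_sd")])
  m3 <- mediate(co, mediation_spec(n_boot = 400L, seed = 78L))
  expect_false(identical(m1$ci_low, m3$ci_low))
})

test_that("degenerate designs are rejected with informative errors", {
  co <- generate_cohort(cohort_params(seed = 3L))
  co$epvs_present <- 0L
  expect_error(mediate(co, mediation_spec(n_boot = 10L)), "both levels")
  expect_error(mediate(co[, 1:4], mediation_spec(n_boot = 10L)),
               "lacks columns")
  expect_error(mediate(generate_cohort(cohort_params(n_subjects = 4L)),
                       mediation_spec(n_boot = 10L)),
               "too few")
})

test_that("interval coverage and null exclusion behave as a 95% BC bootstrap should", {
  true_indirect <- -0.2813 * 0.8861
  n_sims <- 400L
  cover <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    co <- generate_cohort(cohort_params(seed = 5000L + i))
    m <- mediate(co, mediation_spec(mediator = "alps_std",
                                    outcome = "psi_std", n_boot = 399L,
                                    seed = i))
    cover[i] <- m$ci_low <= true_indirect && true_indirect <= m$ci_high
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)

  # pure-noise mediator: the CI should rarely exclude zero
  excl <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    co <- generate_cohort(cohort_params(seed = 9000L + i, path_a = 0,
                                        path_b = 0,
                                        covariate_effects = list(
                                          mediator = c(age = 0, sex = 0,
                                                       qrisk3 = 0),
                                          outcome = c(age = 0, sex = 0,
                                                      qrisk3 = 0)),
                                        noise_sd_mediator = 1,
                                        noise_sd_outcome = 1))
    m <- mediate(co, mediation_spec(mediator = "alps_std",
                                    outcome = "psi_std", n_boot = 399L,
                                    seed = i))
    excl[i] <- m$ci_low > 0 || m$ci_high < 0
  }
  expect_lte(mean(excl), 0.09)
})
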
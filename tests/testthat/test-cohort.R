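test_that("an empty cohort still carries the full column dictionary", {
  co <- generate_cohort(cohort_params(n_subjects = 0L))
  expect_equal(nrow(co), 0L)
  expect_true(all(c("id", "age", "sex", "family_history", "hypertension",
                    "smoking", "sbp", "bmi", "qrisk3", "epvs_present",
                    "epvs_count_bg", "epvs_count_cso", "epvs_grade_bg",
                    "epvs_grade_cso", "alps", "alps_std", "psi", "psi_std",
                    "pri", "wmi") %in% names(co)))
})

test_that("generation is seed-deterministic and honours the table invariants", {
  p <- cohort_params(seed = 21L)
  co <- generate_cohort(p)
  expect_identical(co, generate_cohort(p))
  expect_false(identical(co, generate_cohort(cohort_params(seed = 22L))))

  for (seed in c(3L, 14L, 159L)) {
    co <- generate_cohort(cohort_params(seed = seed))
    expect_equal(nrow(co), 60L)
    expect_true(all(co$age >= 25 & co$age <= 65))
    expect_true(all(co$alps > 0))
    expect_true(all(co$qrisk3 >= 0 & co$qrisk3 <= 20))
    # grades always re-derivable from counts under the 0-4 scale
    expect_identical(co$epvs_grade_bg, grade_epvs(co$epvs_count_bg))
    expect_identical(co$epvs_grade_cso, grade_epvs(co$epvs_count_cso))
    # counts are positive exactly in the ePVS group
    expect_true(all((co$epvs_count_bg > 0) == (co$epvs_present == 1)))
  }
})

test_that("group rescaling reproduces the configured ALPS and PSI summaries", {
  co <- generate_cohort(cohort_params(seed = 8L))
  by_grp <- split(co, co$epvs_present)
  expect_equal(mean(by_grp$`0`$alps), 1.80, tolerance = 1e-10)
  expect_equal(sd(by_grp$`0`$alps), 0.15, tolerance = 1e-10)
  expect_equal(mean(by_grp$`1`$alps), 1.55, tolerance = 1e-10)
  expect_equal(sd(by_grp$`1`$alps), 0.30, tolerance = 1e-10)
  expect_equal(mean(by_grp$`1`$psi), 98.7, tolerance = 1e-10)
  expect_equal(mean(by_grp$`0`$psi), 105.1, tolerance = 1e-10)
})

test_that("cohort marginals converge to the configured values at large n", {
  big <- generate_cohort(cohort_params(n_subjects = 50000L, seed = 7L))
  expect_equal(mean(big$epvs_present), 0.433, tolerance = 0.02 / 0.433)
  expect_equal(mean(big$sex == "male"), 0.317, tolerance = 0.02 / 0.317)
  grp <- split(big, big$epvs_present)
  expect_equal(mean(grp$`1`$bmi), 26.4, tolerance = 0.02)
  expect_equal(mean(grp$`0`$sbp), 123.9, tolerance = 0.02)
  fh <- tapply(big$family_history, big$epvs_present, mean)
  expect_equal(unname(fh["1"]), 0.462, tolerance = 0.02 / 0.462)
})

test_that("refitting the structural model recovers the generating paths", {
  # mean over replicate large cohorts; per-replicate Monte-Carlo SD of the
  # exposure path is ~0.013 at n = 50,000
  est <- vapply(1:5, function(i) {
    co <- generate_cohort(cohort_params(n_subjects = 50000L,
                                        seed = 1000L + i))
    m <- mediate(co, mediation_spec(mediator = "alps_std",
                                    outcome = "psi_std", n_boot = 1L,
                                    seed = 1L))
    c(m$a, m$b, m$c_prime)
  }, numeric(3))
  expect_equal(mean(est[1, ]), -0.2813, tolerance = 0.02 / 0.2813)
  expect_equal(mean(est[2, ]), 0.8861, tolerance = 0.02 / 0.8861)
  expect_equal(mean(est[3, ]), 0.0412, tolerance = 0.02 / 0.0412)
})

test_that("parameter validation rejects out-of-range configurations", {
  expect_error(cohort_params(epvs_prevalence = 1.3), "epvs_prevalence")
  expect_error(cohort_params(n_subjects = -1), "n_subjects")
  expect_error(cohort_params(age_range = c(20, 65)), "age_range")
  expect_error(cohort_params(noise_sd_mediator = 0), "noise_sd_mediator")
})

test_that("cohort CSV roundtrips through the documented dictionary", {
  co <- generate_cohort(cohort_params(seed = 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$alps, co$alps, tolerance = 1e-12)
  expect_equal(as.character(back$sex), as.character(co$sex))
  expect_error(read_cohort(withr::local_tempfile(fileext = ".csv")),
               "not found")
})
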
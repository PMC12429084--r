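#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the study conditions of the replication recipe: 60
#' community-dwelling adults aged 25-65 with low-to-moderate QRISK3 risk,
#' enlarged-perivascular-space (ePVS) prevalence 43.3%, the published group
#' means and SDs for demographics, vascular measures, WAIS-IV indices and
#' the ALPS index (1.80 +/- 0.15 without ePVS, 1.55 +/- 0.30 with), and the
#' standardized structural mediation paths ePVS -> ALPS -> processing speed
#' (a = -0.2813, b = +0.8861, c' = 0.0412).
#'
#' The mediator and outcome are generated on a standardized structural
#' scale (residual SDs chosen so both have approximately unit variance) and
#' then affinely mapped, per group, onto the configured ALPS and PSI group
#' means/SDs. Regional ePVS counts come from a shifted negative binomial in
#' the ePVS group (count distributions are not published; these are
#' realistic choices yielding mostly grades 1-3) and are zero otherwise.
#'
#' @param n_subjects Cohort size (>= 0).
#' @param epvs_prevalence Probability of visible ePVS.
#' @param age_mean,age_sd Named per-group (`present`/`absent`) location and
#'   scale of age in years.
#' @param age_range Truncation bounds, within 25-65 years.
#' @param male_fraction Marginal probability of male sex.
#' @param group_means Per-variable list of per-group `c(mean, sd)` for
#'   `sbp` (mmHg), `bmi` (kg/m2), `qrisk3` (percent), `pri`, `wmi`, `psi`
#'   (index points).
#' @param alps_group_means Per-group `c(mean, sd)` of the ALPS index.
#' @param family_history_rate,hypertension_rate Per-group flag rates.
#' @param smoking_probs Marginal category probabilities (normalized).
#' @param epvs_count_mu,epvs_count_size Negative-binomial mean and size of
#'   regional counts (basal ganglia `bg`, centrum semiovale `cso`) in the
#'   ePVS group.
#' @param path_a,path_b,path_cprime Structural coefficients of the
#'   mediation model (standardized scale).
#' @param covariate_effects List with `mediator` and `outcome` coefficient
#'   vectors for z-scored age, male sex and z-scored QRISK3.
#' @param noise_sd_mediator,noise_sd_outcome Structural residual SDs.
#' @param seed Integer seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(
    n_subjects = 60L,
    epvs_prevalence = 0.433,
    age_mean = c(present = 43.12, absent = 36.3),
    age_sd = c(present = 12.2, absent = 10.1),
    age_range = c(25, 65),
    male_fraction = 0.317,
    group_means = list(
      sbp = list(present = c(134.3, 15.8), absent = c(123.9, 13.5)),
      bmi = list(present = c(26.4, 3.6), absent = c(23.2, 4.6)),
      qrisk3 = list(present = c(4.5, 5.9), absent = c(1.3, 1.7)),
      pri = list(present = c(101.7, 12.8), absent = c(102.7, 12.3)),
      wmi = list(present = c(107.4, 18.5), absent = c(108.5, 19.6)),
      psi = list(present = c(98.7, 12.7), absent = c(105.1, 14.5))
    ),
    alps_group_means = list(present = c(1.55, 0.30), absent = c(1.80, 0.15)),
    family_history_rate = c(present = 0.462, absent = 0.088),
    hypertension_rate = c(present = 0.307, absent = 0.029),
    smoking_probs = c(non_smoker = 0.866, ex_smoker = 0.100,
                      light = 0.017, moderate = 0.017, heavy = 0),
    epvs_count_mu = c(bg = 9, cso = 11),
    epvs_count_size = 2,
    path_a = -0.2813,
    path_b = 0.8861,
    path_cprime = 0.0412,
    covariate_effects = list(
      mediator = c(age = -0.25, sex = 0, qrisk3 = 0),
      outcome = c(age = 0, sex = 0, qrisk3 = 0)
    ),
    noise_sd_mediator = 0.945,
    noise_sd_outcome = 0.472,
    seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  assert_prob(epvs_prevalence, "epvs_prevalence")
  assert_prob(male_fraction, "male_fraction")
  if (length(age_range) != 2L || any(!is.finite(age_range)) ||
      age_range[1] < 25 || age_range[2] > 65 ||
      age_range[1] >= age_range[2]) {
    stop("'age_range' must be an ordered interval within [25, 65]")
  }
  for (g in c("present", "absent")) {
    assert_scalar_num(age_sd[[g]], paste0("age_sd$", g), lower = 1e-9)
    for (v in names(group_means)) {
      ms <- group_means[[v]][[g]]
      if (length(ms) != 2L || !all(is.finite(ms)) || ms[2] <= 0) {
        stop(sprintf("group_means$%s$%s must be finite c(mean, sd > 0)",
                     v, g))
      }
    }
    ag <- alps_group_means[[g]]
    if (length(ag) != 2L || !all(is.finite(ag)) || ag[1] <= 0 || ag[2] <= 0) {
      stop("alps_group_means must be positive c(mean, sd) per group")
    }
    assert_prob(family_history_rate[[g]], "family_history_rate")
    assert_prob(hypertension_rate[[g]], "hypertension_rate")
  }
  for (nm in c("path_a", "path_b", "path_cprime")) {
    assert_scalar_num(get(nm), nm)
  }
  assert_scalar_num(noise_sd_mediator, "noise_sd_mediator", lower = 1e-9)
  assert_scalar_num(noise_sd_outcome, "noise_sd_outcome", lower = 1e-9)
  assert_scalar_num(epvs_count_size, "epvs_count_size", lower = 1e-9)
  if (any(smoking_probs < 0) || sum(smoking_probs) <= 0) {
    stop("'smoking_probs' must be non-negative with positive sum")
  }
  smoking_probs <- smoking_probs / sum(smoking_probs)
  seed <- assert_count(seed, "seed")
  structure(
    list(n_subjects = n_subjects, epvs_prevalence = epvs_prevalence,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         male_fraction = male_fraction, group_means = group_means,
         alps_group_means = alps_group_means,
         family_history_rate = family_history_rate,
         hypertension_rate = hypertension_rate,
         smoking_probs = smoking_probs, epvs_count_mu = epvs_count_mu,
         epvs_count_size = epvs_count_size, path_a = path_a,
         path_b = path_b, path_cprime = path_cprime,
         covariate_effects = covariate_effects,
         noise_sd_mediator = noise_sd_mediator,
         noise_sd_outcome = noise_sd_outcome, seed = seed),
    class = "cohort_params")
}

cohort_columns <- function() {
  c("id", "age", "sex", "family_history", "hypertension", "smoking",
    "sbp", "bmi", "qrisk3", "epvs_present", "epvs_count_bg",
    "epvs_count_cso", "epvs_grade_bg", "epvs_grade_cso", "alps",
    "alps_std", "psi", "psi_std", "pri", "wmi")
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject under the generative model of
#' [cohort_params()]: covariates and group flags first, then the
#' standardized mediator (`alps_std`) as
#' `path_a * ePVS + covariate effects + noise` and the standardized outcome
#' (`psi_std`) as `path_b * alps_std + path_cprime * ePVS + covariate
#' effects + noise`. `alps` and `psi` are the per-group affine rescalings of
#' those columns onto the configured group means/SDs, so both the printed
#' group summaries and the structural path coefficients are recoverable
#' from one table. Deterministic given the seed.
#'
#' @param params A [cohort_params()].
#' @return A `data.frame`, one row per subject, with columns `id`, `age`,
#'   `sex`, `family_history`, `hypertension`, `smoking`, `sbp`, `bmi`,
#'   `qrisk3`, `epvs_present`, `epvs_count_bg`, `epvs_count_cso`,
#'   `epvs_grade_bg`, `epvs_grade_cso`, `alps`, `alps_std`, `psi`,
#'   `psi_std`, `pri`, `wmi`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n <- p$n_subjects
  smoking_levels <- names(p$smoking_probs)
  if (n == 0L) {
    out <- data.frame(
      id = character(), age = numeric(), sex = factor(levels = c("male", "female")),
      family_history = integer(), hypertension = integer(),
      smoking = factor(levels = smoking_levels), sbp = numeric(),
      bmi = numeric(), qrisk3 = numeric(), epvs_present = integer(),
      epvs_count_bg = integer(), epvs_count_cso = integer(),
      epvs_grade_bg = integer(), epvs_grade_cso = integer(),
      alps = numeric(), alps_std = numeric(), psi = numeric(),
      psi_std = numeric(), pri = numeric(), wmi = numeric(),
      stringsAsFactors = FALSE)
    return(out)
  }
  set.seed(p$seed)
  epvs <- stats::rbinom(n, 1L, p$epvs_prevalence)
  grp <- ifelse(epvs == 1L, "present", "absent")

  draw_group <- function(mean_by, sd_by, lower = -Inf, upper = Inf) {
    rnorm_trunc(n, mean_by[grp], sd_by[grp], lower, upper)
  }
  age <- draw_group(p$age_mean, p$age_sd, p$age_range[1], p$age_range[2])
  sex <- factor(ifelse(stats::runif(n) < p$male_fraction, "male", "female"),
                levels = c("male", "female"))
  family_history <- stats::rbinom(n, 1L, p$family_history_rate[grp])
  hypertension <- stats::rbinom(n, 1L, p$hypertension_rate[grp])
  smoking <- factor(sample(smoking_levels, n, replace = TRUE,
                           prob = p$smoking_probs), levels = smoking_levels)
  gm <- function(v) list(mean = vapply(p$group_means[[v]], `[`, 0, 1),
                         sd = vapply(p$group_means[[v]], `[`, 0, 2))
  sbp_p <- gm("sbp"); bmi_p <- gm("bmi"); qr_p <- gm("qrisk3")
  sbp <- draw_group(sbp_p$mean, sbp_p$sd, lower = 80)
  bmi <- draw_group(bmi_p$mean, bmi_p$sd, lower = 14)
  # cohort is restricted to low-to-moderate risk, so truncate at the bands
  qrisk3 <- draw_group(qr_p$mean, qr_p$sd, lower = 0, upper = 20)

  count_bg <- count_cso <- integer(n)
  pos <- epvs == 1L
  if (any(pos)) {
    count_bg[pos] <- 1L + stats::rnbinom(sum(pos), size = p$epvs_count_size,
                                         mu = p$epvs_count_mu[["bg"]])
    count_cso[pos] <- 1L + stats::rnbinom(sum(pos), size = p$epvs_count_size,
                                          mu = p$epvs_count_mu[["cso"]])
  }

  safe_z <- function(x) {
    if (n < 2L || stats::sd(x) == 0) rep(0, n) else zscore(x)
  }
  z_age <- safe_z(age)
  z_qr <- safe_z(qrisk3)
  male <- as.numeric(sex == "male")
  cm <- p$covariate_effects$mediator
  cy <- p$covariate_effects$outcome
  alps_std <- p$path_a * epvs + cm[["age"]] * z_age + cm[["sex"]] * male +
    cm[["qrisk3"]] * z_qr + stats::rnorm(n, 0, p$noise_sd_mediator)
  psi_std <- p$path_b * alps_std + p$path_cprime * epvs +
    cy[["age"]] * z_age + cy[["sex"]] * male + cy[["qrisk3"]] * z_qr +
    stats::rnorm(n, 0, p$noise_sd_outcome)

  rescale_by_group <- function(std, means) {
    out <- numeric(n)
    for (g in c("present", "absent")) {
      i <- grp == g
      if (!any(i)) next
      ms <- means[[g]]
      if (sum(i) >= 2L && stats::sd(std[i]) > 0) {
        out[i] <- ms[1] + ms[2] * (std[i] - mean(std[i])) / stats::sd(std[i])
      } else {
        out[i] <- ms[1]
      }
    }
    out
  }
  alps <- pmax(rescale_by_group(alps_std, p$alps_group_means), 0.05)
  psi <- rescale_by_group(psi_std, lapply(p$group_means$psi, identity))
  pri_p <- gm("pri"); wmi_p <- gm("wmi")
  pri <- draw_group(pri_p$mean, pri_p$sd, lower = 40, upper = 160)
  wmi <- draw_group(wmi_p$mean, wmi_p$sd, lower = 40, upper = 160)

  data.frame(
    id = sprintf("S%03d", seq_len(n)), age = age, sex = sex,
    family_history = family_history, hypertension = hypertension,
    smoking = smoking, sbp = sbp, bmi = bmi, qrisk3 = qrisk3,
    epvs_present = epvs, epvs_count_bg = count_bg,
    epvs_count_cso = count_cso, epvs_grade_bg = grade_epvs(count_bg),
    epvs_grade_cso = grade_epvs(count_cso), alps = alps,
    alps_std = alps_std, psi = psi, psi_std = psi_std, pri = pri,
    wmi = wmi, stringsAsFactors = FALSE)
}

#' Read and write cohort tables as CSV
#'
#' Plain-text interchange for [generate_cohort()] output; factor columns
#' are restored on read.
#'
#' @param cohort A cohort `data.frame`.
#' @param path CSV file path.
#' @return `read_cohort` returns the `data.frame`; `write_cohort` the path,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing)) {
    stop("cohort file lacks columns: ", paste(missing, collapse = ", "))
  }
  df$sex <- factor(df$sex, levels = c("male", "female"))
  df$smoking <- factor(df$smoking)
  df
}
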
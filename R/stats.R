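# Group-comparison and association statistics used by the cohort analysis.
# Standard tests are delegated to the stats-package implementations
# (t.test, wilcox.test, chisq.test, fisher.test, cor.test, glm, lm); the
# summary-statistic forms needed to audit printed tables are closed-form.

stat_result <- function(statistic, df, p_value, effect_size = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        method = "") {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value),
                 effect_size = unname(effect_size),
                 ci_low = unname(ci_low), ci_high = unname(ci_high),
                 method = method),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<stat_test_result> %s\n", x$method))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
              format(x$df), x$p_value))
  if (!is.na(x$effect_size)) {
    cat(sprintf("  effect size = %.4g (%.4g to %.4g)\n", x$effect_size,
                x$ci_low, x$ci_high))
  }
  invisible(x)
}

check_summary_args <- function(sd1, n1, sd2, n2) {
  assert_scalar_num(sd1, "sd1", lower = 1e-300)
  assert_scalar_num(sd2, "sd2", lower = 1e-300)
  assert_count(n1, "n1", lower = 2L)
  assert_count(n2, "n2", lower = 2L)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Two-sided independent-samples t test with pooled variance and
#' `df = n1 + n2 - 2`, computable directly from printed group means, SDs
#' and sizes - the form used to audit published group comparisons. The
#' effect size is the raw mean difference with its confidence interval.
#' [pooled_t_test_raw()] is the raw-data overload.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param conf_level Confidence level.
#' @return A `stat_test_result`.
#' @export
#' @examples
#' pooled_t_test(98.7, 12.7, 26, 105.1, 14.5, 34)  # p rounds to 0.08
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2,
                          conf_level = 0.95) {
  check_summary_args(sd1, n1, sd2, n2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean1 - mean2
  tt <- diff / se
  p <- 2 * stats::pt(-abs(tt), df)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  stat_result(tt, df, p, diff, diff - q * se, diff + q * se,
              "pooled-variance two-sample t test")
}

#' @rdname pooled_t_test
#' @param x,y Raw observations per group.
#' @export
pooled_t_test_raw <- function(x, y, conf_level = 0.95) {
  pooled_t_test(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y), conf_level)
}

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance companion to [pooled_t_test()] with Satterthwaite
#' degrees of freedom. [welch_t_test_raw()] is the raw-data overload.
#'
#' @inheritParams pooled_t_test
#' @return A `stat_test_result`.
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2,
                         conf_level = 0.95) {
  check_summary_args(sd1, n1, sd2, n2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  diff <- mean1 - mean2
  tt <- diff / se
  p <- 2 * stats::pt(-abs(tt), df)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  stat_result(tt, df, p, diff, diff - q * se, diff + q * se,
              "Welch two-sample t test")
}

#' @rdname welch_t_test
#' @param x,y Raw observations per group.
#' @export
welch_t_test_raw <- function(x, y, conf_level = 0.95) {
  welch_t_test(mean(x), stats::sd(x), length(x),
               mean(y), stats::sd(y), length(y), conf_level)
}

#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided rank-sum test via the normal approximation with tie
#' correction. The statistic reported is U for the first sample; the effect
#' size is the rank-biserial correlation `1 - 2U/(n1 n2)`.
#'
#' @param x,y Observations per group.
#' @return A `stat_test_result`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  u <- unname(wt$statistic)
  rb <- 1 - 2 * u / (length(x) * length(y))
  stat_result(u, NA_real_, wt$p.value, rb,
              method = "Mann-Whitney U (normal approximation)")
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab)) || any(!is.finite(tab))) {
    stop("need a 2x2 table of non-negative integers")
  }
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' df = 1, with optional Yates continuity correction. The effect size is
#' the phi coefficient signed by the cross-product. Tables with a zero
#' margin are an error (use [fisher_exact_2x2()]).
#'
#' @param tab 2x2 integer table.
#' @param yates Apply the continuity correction?
#' @return A `stat_test_result`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(12, 3, 14, 31), 2))  # chi2 = 10.95
chi_square_2x2 <- function(tab, yates = FALSE) {
  tab <- check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square is undefined for tables with a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  phi <- sign(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) *
    sqrt(unname(ct$statistic) / sum(tab))
  stat_result(ct$statistic, ct$parameter, ct$p.value, phi,
              method = if (yates) "chi-square (Yates-corrected)" else
                "chi-square (uncorrected)")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than
#' the observed table's. Handles zero cells/margins. The effect size slot
#' carries the conditional-MLE odds ratio with its exact interval.
#'
#' @param tab 2x2 integer table.
#' @return A `stat_test_result`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  ft <- stats::fisher.test(tab)
  stat_result(NA_real_, NA_real_, ft$p.value, unname(ft$estimate),
              ft$conf.int[1], ft$conf.int[2], "Fisher exact (two-sided)")
}

#' Pearson correlation with t-based p-value
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df; the interval is the
#' Fisher z transform interval.
#'
#' @param x,y Paired observations.
#' @param conf_level Confidence level.
#' @return A `stat_test_result` with the correlation as effect size.
#' @export
pearson_r <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  stat_result(ct$statistic, ct$parameter, ct$p.value, unname(ct$estimate),
              ct$conf.int[1], ct$conf.int[2], "Pearson correlation")
}

#' Cohen's d from summary statistics
#'
#' Pooled-SD standardized mean difference with the usual normal
#' approximation interval
#' (`se^2 = (n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))`).
#'
#' @inheritParams pooled_t_test
#' @return A `stat_test_result` with d as effect size.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2, conf_level = 0.95) {
  check_summary_args(sd1, n1, sd2, n2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- (mean1 - mean2) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  stat_result(NA_real_, NA_real_, NA_real_, d, d - z * se, d + z * se,
              "Cohen's d (pooled SD)")
}

coerce_design <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(NULL, "x"))
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(names(X) == "")) {
    names(X) <- paste0("x", seq_along(X))
  }
  X
}

is_binary_col <- function(v) all(v %in% c(0, 1))

#' Logistic regression (maximum likelihood, Wald inference)
#'
#' Binomial GLM via iteratively reweighted least squares with Wald
#' standard errors, odds ratios and their confidence intervals. With
#' `per_sd = TRUE` continuous predictors are z-scored on the analysis
#' sample first, so odds ratios are per 1 SD. Complete separation is
#' flagged (`converged = FALSE`) rather than silently reported.
#'
#' @param y Binary response (0/1).
#' @param X Predictor matrix or data frame.
#' @param conf_level Confidence level for the Wald intervals.
#' @param per_sd Z-score continuous (non-binary) predictors first?
#' @return An object of class `regression_result`: a coefficient table
#'   (`term`, `estimate`, `std_error`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, odds-ratio scale for the intervals), plus `converged` and
#'   `n_iter`.
#' @export
logistic_fit <- function(y, X, conf_level = 0.95, per_sd = FALSE) {
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  X <- coerce_design(X)
  if (nrow(X) != length(y)) stop("'y' and 'X' dimensions differ")
  if (per_sd) {
    X[] <- lapply(X, function(v) {
      if (is.numeric(v) && !is_binary_col(v)) zscore(v) else v
    })
  }
  dat <- cbind(data.frame(.y = y), X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
    odds_ratio = exp(sm[, 1]),
    ci_low = exp(sm[, 1] - z * sm[, 2]),
    ci_high = exp(sm[, 1] + z * sm[, 2]),
    p_value = sm[, 4], row.names = NULL)
  structure(list(coefficients = coefs,
                 converged = fit$converged && !separated,
                 n_iter = fit$iter, n = length(y), model = "logistic"),
            class = "regression_result")
}

#' Linear regression with optional standardized coefficients
#'
#' Ordinary least squares; `standardize = TRUE` adds standardized betas
#' (`estimate * sd(x) / sd(y)` for non-intercept terms).
#'
#' @param y Numeric response.
#' @param X Predictor matrix or data frame.
#' @param standardize Add standardized betas?
#' @param conf_level Confidence level.
#' @return A `regression_result` with `coefficients` (`term`, `estimate`,
#'   `std_error`, `ci_low`, `ci_high`, `p_value`, optionally `std_beta`),
#'   `r_squared`, `sigma` and `residuals`.
#' @export
linear_fit <- function(y, X, standardize = FALSE, conf_level = 0.95) {
  X <- coerce_design(X)
  if (nrow(X) != length(y)) stop("'y' and 'X' dimensions differ")
  dat <- cbind(data.frame(.y = y), X)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients
  q <- stats::qt(1 - (1 - conf_level) / 2, fit$df.residual)
  coefs <- data.frame(
    term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
    ci_low = cf[, 1] - q * cf[, 2], ci_high = cf[, 1] + q * cf[, 2],
    p_value = cf[, 4], row.names = NULL)
  if (standardize) {
    sdy <- stats::sd(y)
    mm <- stats::model.matrix(fit)
    sdx <- apply(mm, 2, stats::sd)
    coefs$std_beta <- ifelse(coefs$term == "(Intercept)", NA_real_,
                             coefs$estimate * sdx[coefs$term] / sdy)
  }
  structure(list(coefficients = coefs, converged = TRUE,
                 n_iter = 1L, n = length(y), r_squared = sm$r.squared,
                 sigma = sm$sigma, residuals = stats::residuals(fit),
                 model = "linear"),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s model, n = %d%s\n", x$model, x$n,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor j on
#' the remaining predictors (with intercept). Always >= 1; exactly 1 for
#' mutually orthogonal (uncorrelated) predictors.
#'
#' @param X Numeric predictor matrix or data frame with >= 2 columns.
#' @return Named numeric vector of VIFs.
#' @export
#' @examples
#' vif(cbind(a = rnorm(50), b = rnorm(50)))
vif <- function(X) {
  X <- coerce_design(X)
  X <- as.data.frame(lapply(X, as.numeric))
  if (ncol(X) < 2L) stop("VIF needs at least two predictors")
  if (any(vapply(X, stats::sd, 0) == 0)) stop("constant predictor column")
  out <- vapply(seq_along(X), function(j) {
    r2 <- summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, 0)
  names(out) <- names(X)
  out
}
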
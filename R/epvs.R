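#' Semi-quantitative ePVS grade from a regional count
#'
#' Maps the number of enlarged perivascular spaces counted in a region
#' (basal ganglia or centrum semiovale) to the 0-4 ordinal scale:
#' 0 = none, 1 = 1-10, 2 = 11-20, 3 = 21-40, 4 = 41 or more.
#'
#' @param count Non-negative integer count(s).
#' @return Integer grade(s) 0-4.
#' @export
#' @examples
#' grade_epvs(c(0, 10, 11, 40, 41))
grade_epvs <- function(count) {
  if (!is.numeric(count) || any(is.na(count)) || any(count < 0) ||
      any(count != round(count))) {
    stop("'count' must be non-negative integer(s)")
  }
  br <- c(-1, 0, 10, 20, 40, Inf)
  as.integer(cut(count, breaks = br, labels = FALSE)) - 1L
}

#' QRISK3 risk category
#'
#' Ten-year cardio-cerebrovascular risk bands: low (<= 10%), moderate
#' (10.1-20%), high (>= 20.1%). Scores strictly between the printed band
#' edges (e.g. 10.05) are assigned upward, i.e. the operative rule is
#' `> 10` for moderate and `> 20` for high.
#'
#' @param score Risk score(s) in percent, non-negative.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
#' @examples
#' qrisk_category(c(10, 10.1, 20, 20.1))
qrisk_category <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0)) {
    stop("'score' must be non-negative")
  }
  out <- ifelse(score <= 10, "low", ifelse(score <= 20, "moderate", "high"))
  factor(out, levels = c("low", "moderate", "high"))
}

#' Unweighted Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' raters over a shared category set, with the large-sample
#' (Fleiss-Cohen-Everitt) standard error for the confidence interval and the
#' null-variance z test for `p`. When both raters use a single category in
#' perfect agreement, kappa is defined as 1 with a degenerate interval.
#'
#' @param ratings_a,ratings_b Equal-length categorical vectors (length
#'   >= 2).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `agreement_result`: `kappa`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `n_items`.
#' @export
#' @examples
#' cohens_kappa(rep(0:1, c(25, 25)), rep(c(0, 1, 0, 1), c(20, 5, 10, 15)))
cohens_kappa <- function(ratings_a, ratings_b, conf_level = 0.95) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating sequences must have equal length")
  }
  n <- length(ratings_a)
  if (n < 2L) stop("need at least 2 rated items")
  assert_scalar_num(conf_level, "conf_level", 1e-6, 1 - 1e-6)
  levs <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = levs)
  b <- factor(as.character(ratings_b), levels = levs)
  tab <- table(a, b) / n
  po <- sum(diag(tab))
  pr <- rowSums(tab)
  pc <- colSums(tab)
  pe <- sum(pr * pc)

  if (length(levs) == 1L) {
    # one shared category, necessarily perfect agreement
    res <- list(kappa = 1, se = 0, ci_low = 1, ci_high = 1, p_value = NA_real_,
                n_items = n, degenerate = TRUE)
    return(structure(res, class = "agreement_result"))
  }
  kappa <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt estimated variance (for the CI)
  k <- length(levs)
  termA <- 0
  termB <- 0
  for (i in seq_len(k)) {
    termA <- termA + tab[i, i] *
      ((1 - pe) - (pr[i] + pc[i]) * (1 - po))^2
    for (j in seq_len(k)) {
      if (i != j) termB <- termB + tab[i, j] * (pc[i] + pr[j])^2
    }
  }
  termB <- (1 - po)^2 * termB
  termC <- (po * pe - 2 * pe + po)^2
  var_k <- (termA + termB - termC) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))

  # null-hypothesis variance for the z test of kappa = 0
  var0 <- (pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))

  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se,
                 ci_low = max(-1, kappa - zq * se),
                 ci_high = min(1, kappa + zq * se),
                 p_value = p, n_items = n, degenerate = se == 0),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> kappa = %.3f (95%% CI %.3f to %.3f), n = %d\n",
              x$kappa, x$ci_low, x$ci_high, x$n_items))
  invisible(x)
}
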
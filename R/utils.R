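# Internal validation helpers shared across modules.

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, format(lower),
                 format(upper)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < lower) {
    stop(sprintf("'%s' must be an integer >= %d", name, lower), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) assert_scalar_num(x, name, 0, 1)

# Deterministic fan-out of one user-facing seed into per-stage child seeds.
# Kept strictly below 2^31 - 1 so the result is a valid R integer seed.
child_seed <- function(seed, stage) {
  seed <- assert_count(seed, "seed")
  stage <- assert_count(stage, "stage")
  as.integer((as.double(seed) * 7919 + as.double(stage) * 104729) %%
               (.Machine$integer.max - 1L))
}

# Truncated normal draws by inverse-CDF; used for bounded cohort covariates.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant column",
                                    call. = FALSE)
  (x - mean(x)) / s
}
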
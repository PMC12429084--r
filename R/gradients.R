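#' Deterministic spherical Fibonacci gradient directions
#'
#' Generates `n` near-uniform unit vectors on the sphere via the spherical
#' Fibonacci (golden-angle) lattice. Used as the diffusion-encoding scheme of
#' the synthetic phantoms: the acquisition emulated here used 32 directions at
#' b = 1000 s/mm2, but the direction table itself is vendor-specific and not
#' published, so a reproducible near-uniform scheme is used instead.
#'
#' @param n Number of directions (>= 1).
#' @return An `n x 3` matrix of unit row vectors (x, y, z).
#' @export
#' @examples
#' g <- fibonacci_directions(32)
#' range(sqrt(rowSums(g^2)))
fibonacci_directions <- function(n) {
  n <- assert_count(n, "n", lower = 1L)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i        # golden angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Construct a diffusion gradient scheme
#'
#' Bundles per-volume gradient directions and b-values in the scanner frame
#' (x = right-left, y = anterior-posterior, z = superior-inferior). Directions
#' at non-zero b must have unit norm within 1e-6; b = 0 volumes may carry a
#' zero vector.
#'
#' @param directions Matrix with one row per volume and 3 columns.
#' @param bvalues Numeric vector of b-values (s/mm2), one per volume.
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("'directions' must have 3 columns")
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues)) {
    stop("number of directions and b-values must match")
  }
  if (any(!is.finite(directions)) || any(!is.finite(bvalues)) ||
      any(bvalues < 0)) {
    stop("directions and b-values must be finite; b-values non-negative")
  }
  nrm <- sqrt(rowSums(directions^2))
  dwi <- bvalues > 0
  if (any(abs(nrm[dwi] - 1) > 1e-6)) {
    stop("diffusion-weighted directions must have unit norm (within 1e-6)")
  }
  structure(list(directions = unname(directions), bvalues = bvalues),
            class = "gradient_scheme")
}

#' Default 32-direction b=1000 scheme plus b0 volumes
#'
#' @param n_dir Number of diffusion-weighted directions.
#' @param bvalue Diffusion weighting (s/mm2).
#' @param n_b0 Number of unweighted volumes, prepended.
#' @return A `gradient_scheme` of length `n_b0 + n_dir`.
#' @export
default_scheme <- function(n_dir = 32L, bvalue = 1000, n_b0 = 1L) {
  n_b0 <- assert_count(n_b0, "n_b0", lower = 1L)
  assert_scalar_num(bvalue, "bvalue", lower = 1e-12)
  dirs <- rbind(matrix(0, n_b0, 3), fibonacci_directions(n_dir))
  gradient_scheme(dirs, c(rep(0, n_b0), rep(bvalue, n_dir)))
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d volumes (%d b0, %d diffusion-weighted)\n",
              length(x$bvalues), sum(x$bvalues == 0), sum(x$bvalues > 0)))
  cat("b-values:", paste(unique(x$bvalues), collapse = ", "), "s/mm2\n")
  invisible(x)
}

#' Read/write FSL-dialect gradient tables
#'
#' `bval` is a single whitespace-separated row, `bvec` three rows (x, y, z),
#' one column per volume.
#'
#' @param bval_path,bvec_path File paths.
#' @param scheme A `gradient_scheme`.
#' @return `read_scheme` returns a `gradient_scheme`; `write_scheme` returns
#'   the paths invisibly.
#' @export
read_scheme <- function(bval_path, bvec_path) {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path)
  bvals <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3L) stop("bvec file must have exactly 3 rows")
  if (ncol(bvec) != length(bvals)) {
    stop(sprintf("bvec has %d columns but bval lists %d volumes",
                 ncol(bvec), length(bvals)))
  }
  gradient_scheme(t(bvec), bvals)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  bvec <- t(scheme$directions)
  writeLines(apply(bvec, 1L, function(r)
    paste(formatC(r, format = "fg", digits = 17), collapse = " ")), bvec_path)
  invisible(c(bval = bval_path, bvec = bvec_path))
}
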
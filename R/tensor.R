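#' Construct a per-voxel diffusion tensor field
#'
#' Stores the six unique components of the symmetric tensor in the scanner
#' frame, per voxel, after positive semi-definiteness repair: voxels whose
#' tensor has negative eigenvalues are clamped to the nearest PSD tensor
#' (negative eigenvalues set to zero) and flagged in `clamped`. `fit_ok`
#' marks voxels with a usable fit at all.
#'
#' @param dxx,dxy,dxz,dyy,dyz,dzz Component arrays (mm2/s), identical dims.
#' @param s0 Optional fitted unweighted signal array.
#' @param fit_ok Optional logical array; defaults to all `TRUE`.
#' @param voxel_size Voxel edge in mm, carried for ROI geometry.
#' @return An object of class `tensor_field` with component maps, sorted
#'   eigenvalue maps (`l1 >= l2 >= l3`), and `fit_ok`/`clamped` flags.
#' @export
tensor_field <- function(dxx, dxy, dxz, dyy, dyz, dzz, s0 = NULL,
                         fit_ok = NULL, voxel_size = 2.5) {
  comp <- list(dxx = dxx, dxy = dxy, dxz = dxz,
               dyy = dyy, dyz = dyz, dzz = dzz)
  dims <- dim(as.array(dxx))
  if (is.null(dims)) dims <- length(dxx)
  comp <- lapply(comp, function(x) array(as.numeric(x), dim = dims))
  if (is.null(fit_ok)) fit_ok <- array(TRUE, dim = dims)
  fit_ok <- array(as.logical(fit_ok), dim = dims)
  if (is.null(s0)) s0 <- array(1, dim = dims)

  nvox <- prod(dims)
  l <- matrix(0, nvox, 3)
  clamped <- logical(nvox)
  M <- matrix(0, 3, 3)
  for (v in seq_len(nvox)) {
    if (!fit_ok[v]) next
    M[1, 1] <- comp$dxx[v]; M[2, 2] <- comp$dyy[v]; M[3, 3] <- comp$dzz[v]
    M[1, 2] <- M[2, 1] <- comp$dxy[v]
    M[1, 3] <- M[3, 1] <- comp$dxz[v]
    M[2, 3] <- M[3, 2] <- comp$dyz[v]
    e <- eigen(M, symmetric = TRUE)
    if (e$values[3] < 0) {
      clamped[v] <- TRUE
      lam <- pmax(e$values, 0)
      R <- e$vectors %*% (lam * t(e$vectors))
      comp$dxx[v] <- R[1, 1]; comp$dyy[v] <- R[2, 2]; comp$dzz[v] <- R[3, 3]
      comp$dxy[v] <- R[1, 2]; comp$dxz[v] <- R[1, 3]; comp$dyz[v] <- R[2, 3]
      l[v, ] <- lam
    } else {
      l[v, ] <- e$values
    }
  }
  structure(c(comp, list(
    s0 = array(as.numeric(s0), dim = dims),
    fit_ok = fit_ok,
    clamped = array(clamped, dim = dims),
    eigenvalues = list(l1 = array(l[, 1], dims), l2 = array(l[, 2], dims),
                       l3 = array(l[, 3], dims)),
    dim = dims, voxel_size = voxel_size
  )), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s grid; %d/%d voxels fit, %d clamped\n",
              paste(x$dim, collapse = " x "), sum(x$fit_ok),
              prod(x$dim), sum(x$clamped)))
  invisible(x)
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per-voxel ordinary least squares on `ln(S)` with design rows
#' `(1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz)`,
#' the standard linearized monoexponential tensor model. Exact on noiseless
#' data. Signals at or below zero are clipped to `log_floor * S0` before the
#' logarithm; voxels with no positive signal are flagged `fit_ok = FALSE`.
#' Negative eigenvalues arising under noise are clamped to zero (see
#' [tensor_field()]).
#'
#' @param dwi A [dwi_volume()] whose scheme has at least one b0 and six
#'   diffusion-weighted directions.
#' @param log_floor Relative signal floor applied before the log.
#' @return A [tensor_field()].
#' @export
fit_tensor <- function(dwi, log_floor = 1e-8) {
  stopifnot(inherits(dwi, "dwi_volume"))
  scheme <- dwi$scheme
  b <- scheme$bvalues
  g <- scheme$directions
  if (sum(b == 0) < 1L || sum(b > 0) < 6L) {
    stop("tensor fitting needs >= 1 b0 volume and >= 6 diffusion directions")
  }
  dims <- dim(dwi$signal)[1:3]
  nvox <- prod(dims)
  nvol <- dim(dwi$signal)[4]
  S <- matrix(aperm(dwi$signal, c(4, 1, 2, 3)), nrow = nvol)

  s0_est <- colMeans(S[b == 0, , drop = FALSE])
  ok <- s0_est > 0 & matrixStats_colAnys(S > 0)

  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  floor_mat <- matrix(pmax(s0_est, 1e-300) * log_floor, nvol, nvox,
                      byrow = TRUE)
  logS <- log(pmax(S, floor_mat))
  beta <- qr.coef(qr(X), logS)          # 7 x nvox
  beta[, !ok] <- 0

  tensor_field(
    dxx = array(beta[2, ], dims), dxy = array(beta[5, ], dims),
    dxz = array(beta[6, ], dims), dyy = array(beta[3, ], dims),
    dyz = array(beta[7, ], dims), dzz = array(beta[4, ], dims),
    s0 = array(ifelse(ok, exp(beta[1, ]), 0), dims),
    fit_ok = array(ok, dims),
    voxel_size = voxel_size(dwi)
  )
}

matrixStats_colAnys <- function(m) colSums(m) > 0

#' Axis diffusivities in the scanner frame
#'
#' Returns the diagonal tensor components Dxx, Dyy, Dzz: diffusivity along
#' the right-left, anterior-posterior and superior-inferior axes. These are
#' frame-dependent diagonal elements, deliberately *not* eigenvalues - the
#' perivascular-space index reads diffusion along the scanner x-axis
#' irrespective of the local fiber orientation.
#'
#' @param field A [tensor_field()].
#' @return Named list of three arrays (`dxx`, `dyy`, `dzz`), with the
#'   `fit_ok` map attached as an attribute.
#' @export
axis_diffusivities <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  structure(list(dxx = field$dxx, dyy = field$dyy, dzz = field$dzz),
            fit_ok = field$fit_ok)
}

#' Fractional anisotropy map
#'
#' Normalized eigenvalue dispersion
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, in `[0, 1]`.
#' Zero tensors map to FA 0.
#'
#' @param field A [tensor_field()].
#' @return Array of FA values with the field's dimensions.
#' @export
fractional_anisotropy <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  l1 <- field$eigenvalues$l1
  l2 <- field$eigenvalues$l2
  l3 <- field$eigenvalues$l3
  lbar <- (l1 + l2 + l3) / 3
  num <- (l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5) * sqrt(ifelse(den > 0, num / den, 0))
  array(pmin(pmax(fa, 0), 1), dim = field$dim)
}
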
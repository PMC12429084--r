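#' Construct a diffusion-weighted volume
#'
#' A `dwi_volume` couples a 4-D signal grid (x, y, z, volume) with its
#' gradient scheme and a voxel-to-mm affine. The fourth dimension must match
#' the scheme length and the signal must be non-negative.
#'
#' @param signal 4-D numeric array.
#' @param scheme A [gradient_scheme()].
#' @param voxel_size Isotropic voxel edge in mm (ignored when `affine` given).
#' @param affine Optional 4x4 voxel-to-mm matrix; defaults to a diagonal
#'   scaling by `voxel_size`.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, scheme, voxel_size = 2.5, affine = NULL) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (length(dim(signal)) != 4L) stop("'signal' must be a 4-D array")
  if (dim(signal)[4] != length(scheme$bvalues)) {
    stop(sprintf("signal has %d volumes but the scheme describes %d",
                 dim(signal)[4], length(scheme$bvalues)))
  }
  if (any(signal < 0)) stop("signal must be non-negative")
  if (is.null(affine)) {
    assert_scalar_num(voxel_size, "voxel_size", lower = 1e-12)
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(signal = signal, scheme = scheme, affine = affine),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume> %d x %d x %d grid, %d volumes, voxel %.3g mm\n",
              d[1], d[2], d[3], d[4], voxel_size(x)))
  invisible(x)
}

#' Voxel edge length of a volume (mm)
#' @param dwi A `dwi_volume`.
#' @return Scalar voxel size in mm (from the affine column norms).
#' @export
voxel_size <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  sizes <- sqrt(colSums(dwi$affine[1:3, 1:3]^2))
  mean(sizes)
}

#' Read and write diffusion volumes (NIfTI-1 + bval/bvec)
#'
#' Signal, affine and gradient scheme roundtrip losslessly within float
#' precision. A mismatch between the image's fourth dimension and the gradient
#' table is a format error.
#'
#' @param nifti_path Path to a 4-D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param bval_path,bvec_path FSL-dialect gradient table paths; default to
#'   `nifti_path` with extensions `.bval`/`.bvec`.
#' @param dwi A `dwi_volume` (for `write_dwi`).
#' @return `read_dwi` returns a `dwi_volume`; `write_dwi` the paths,
#'   invisibly.
#' @export
read_dwi <- function(nifti_path, bval_path = NULL, bvec_path = NULL) {
  if (is.null(bval_path)) bval_path <- gradient_sidecar(nifti_path, "bval")
  if (is.null(bvec_path)) bvec_path <- gradient_sidecar(nifti_path, "bvec")
  if (!file.exists(nifti_path)) stop("NIfTI file not found: ", nifti_path)
  img <- RNifti::readNifti(nifti_path)
  scheme <- read_scheme(bval_path, bvec_path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L) stop("expected a 4-D diffusion series")
  if (dim(arr)[4] != length(scheme$bvalues)) {
    stop(sprintf("image has %d volumes but gradient table describes %d",
                 dim(arr)[4], length(scheme$bvalues)))
  }
  dwi_volume(arr, scheme, affine = RNifti::xform(img))
}

#' @rdname read_dwi
#' @export
write_dwi <- function(dwi, nifti_path, bval_path = NULL, bvec_path = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (is.null(bval_path)) bval_path <- gradient_sidecar(nifti_path, "bval")
  if (is.null(bvec_path)) bvec_path <- gradient_sidecar(nifti_path, "bvec")
  arr <- dwi$signal
  attr(arr, "pixdim") <- c(rep(voxel_size(dwi), 3), 1)
  RNifti::writeNifti(RNifti::asNifti(arr), nifti_path)
  write_scheme(dwi$scheme, bval_path, bvec_path)
  invisible(c(nifti = nifti_path, bval = bval_path, bvec = bvec_path))
}

gradient_sidecar <- function(nifti_path, ext) {
  base <- sub("\\.nii(\\.gz)?$", "", nifti_path)
  paste0(base, ".", ext)
}

#' Predict the diffusion signal of a single tensor
#'
#' Noise-free monoexponential signal `S0 * exp(-b g' D g)` for one symmetric
#' tensor under a gradient scheme; used to build phantoms and as the forward
#' model in fitting tests.
#'
#' @param D 3x3 symmetric diffusion tensor (mm2/s).
#' @param scheme A [gradient_scheme()].
#' @param s0 Unweighted signal amplitude.
#' @return Numeric vector, one signal per volume.
#' @export
simulate_signal <- function(D, scheme, s0 = 1000) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  D <- as.matrix(D)
  stopifnot(all(dim(D) == c(3, 3)))
  if (max(abs(D - t(D))) > 1e-12) stop("tensor must be symmetric")
  g <- scheme$directions
  quad <- rowSums((g %*% D) * g)        # g' D g per volume
  s0 * exp(-scheme$bvalues * quad)
}
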
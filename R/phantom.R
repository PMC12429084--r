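#' Solve x-axis diffusivities for a prescribed ALPS index
#'
#' Inverts the index formula
#' `ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)`:
#' given the target index and the two perpendicular diffusivities, returns
#' the pair of x-axis diffusivities, split equally by default, so that the
#' noiseless index equals the target exactly.
#'
#' @param target_alps Desired index (> 0, unitless).
#' @param d_perp_proj Dy in the projection-fiber region (mm2/s, > 0).
#' @param d_perp_assoc Dz in the association-fiber region (mm2/s, > 0).
#' @return Named numeric vector `c(dx_proj, dx_assoc)` in mm2/s.
#' @export
#' @examples
#' solve_axis_diffusivities(1.8, 0.8e-3, 0.7e-3)  # both 1.35e-3
solve_axis_diffusivities <- function(target_alps, d_perp_proj, d_perp_assoc) {
  assert_scalar_num(target_alps, "target_alps", lower = 1e-12)
  assert_scalar_num(d_perp_proj, "d_perp_proj", lower = 1e-300)
  assert_scalar_num(d_perp_assoc, "d_perp_assoc", lower = 1e-300)
  dx <- target_alps * mean(c(d_perp_proj, d_perp_assoc))
  c(dx_proj = dx, dx_assoc = dx)
}

#' Default phantom region map
#'
#' Partitions the grid into three equal slabs along x (projection-,
#' association- and subcortical-fiber regions, in that order), with a
#' one-voxel background border in y and z. The projection region is
#' z-dominant, the association region y-dominant and the subcortical region
#' x-dominant, mirroring the fiber geometry around the lateral-ventricle
#' level where the index is read.
#'
#' @param grid_shape Integer vector of voxels per axis.
#' @return Integer array with labels 0 (background), 1 (projection),
#'   2 (association), 3 (subcortical).
#' @export
default_region_map <- function(grid_shape = c(16L, 16L, 16L)) {
  grid_shape <- vapply(grid_shape, assert_count, integer(1),
                       name = "grid_shape", lower = 6L)
  if (length(grid_shape) != 3L) stop("'grid_shape' must have length 3")
  m <- array(0L, grid_shape)
  cuts <- floor(seq(1, grid_shape[1] + 1, length.out = 4))
  yr <- 2:(grid_shape[2] - 1)
  zr <- 2:(grid_shape[3] - 1)
  m[cuts[1]:(cuts[2] - 1), yr, zr] <- 1L
  m[cuts[2]:(cuts[3] - 1), yr, zr] <- 2L
  m[cuts[3]:(cuts[4] - 1), yr, zr] <- 3L
  m
}

#' Specify a DWI phantom
#'
#' Describes a synthetic tensor field whose region-wise diagonal tensors are
#' solved so that the noiseless ALPS pipeline returns `target_alps` exactly.
#' Regions: projection fibers (dominant diffusivity along z), association
#' fibers (dominant along y), subcortical fibers (dominant along x),
#' isotropic background. The diffusion signal is
#' `S = S0 exp(-b g' D g)`, optionally degraded with Rician noise at a given
#' b0 signal-to-noise ratio.
#'
#' @param grid_shape Voxels per axis.
#' @param voxel_size Isotropic voxel edge (mm); default 2.5 as in the
#'   emulated acquisition.
#' @param target_alps Prescribed index (> 0).
#' @param d_axial Dominant-fiber diffusivity (mm2/s).
#' @param d_perp_proj Perpendicular (y) diffusivity in the projection region.
#' @param d_perp_assoc Perpendicular (z) diffusivity in the association
#'   region.
#' @param d_perp_other Second perpendicular diffusivity of each fiber region
#'   and both minor axes of the subcortical region.
#' @param d_background Isotropic background diffusivity.
#' @param snr_b0 Signal-to-noise ratio on the b0 signal; `Inf` disables
#'   noise.
#' @param s0 Unweighted signal amplitude.
#' @param scheme Gradient scheme, default [default_scheme()].
#' @param region_map Label array from [default_region_map()] or compatible.
#' @param roi_voxel_count Voxels per ROI used downstream (for feasibility
#'   checks).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 16L), voxel_size = 2.5,
                         target_alps = 1.8, d_axial = 1.6e-3,
                         d_perp_proj = 0.8e-3, d_perp_assoc = 0.7e-3,
                         d_perp_other = 0.75e-3, d_background = 0.8e-3,
                         snr_b0 = Inf, s0 = 1000,
                         scheme = default_scheme(),
                         region_map = NULL, roi_voxel_count = 12L,
                         seed = 1L) {
  assert_scalar_num(target_alps, "target_alps", lower = 1e-12)
  assert_scalar_num(voxel_size, "voxel_size", lower = 1e-12)
  for (nm in c("d_axial", "d_perp_proj", "d_perp_assoc", "d_perp_other",
               "d_background")) {
    assert_scalar_num(get(nm), nm, lower = 1e-300)
  }
  assert_scalar_num(snr_b0, "snr_b0", lower = 1e-12, allow_inf = TRUE)
  assert_scalar_num(s0, "s0", lower = 1e-300)
  roi_voxel_count <- assert_count(roi_voxel_count, "roi_voxel_count", 1L)
  seed <- assert_count(seed, "seed")
  if (is.null(region_map)) region_map <- default_region_map(grid_shape)
  if (!all(dim(region_map) == grid_shape)) {
    stop("region map dimensions must equal 'grid_shape'")
  }
  for (lab in 1:3) {
    if (sum(region_map == lab) < roi_voxel_count) {
      stop("each fiber region must contain at least the ROI voxel count")
    }
  }
  dx <- solve_axis_diffusivities(target_alps, d_perp_proj, d_perp_assoc)
  tensors <- list(
    projection   = diag(c(dx[["dx_proj"]], d_perp_proj, d_axial)),
    association  = diag(c(dx[["dx_assoc"]], d_axial, d_perp_assoc)),
    subcortical  = diag(c(d_axial, d_perp_other, d_perp_other)),
    background   = diag(rep(d_background, 3))
  )
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 target_alps = target_alps, tensors = tensors,
                 snr_b0 = snr_b0, s0 = s0, scheme = scheme,
                 region_map = region_map,
                 roi_voxel_count = roi_voxel_count, seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %s grid, voxel %.3g mm, target ALPS ",
                     "%.4g, SNR(b0) %s\n"),
              paste(x$grid_shape, collapse = " x "), x$voxel_size,
              x$target_alps,
              if (is.finite(x$snr_b0)) format(x$snr_b0) else "Inf"))
  invisible(x)
}

#' Generate a diffusion-weighted phantom volume
#'
#' Builds the noiseless signal from the region tensors of a [phantom_spec()]
#' and, at finite `snr_b0`, applies Rician degradation: the magnitude of the
#' signal perturbed by two independent Gaussian channels with
#' `sigma = s0 / snr_b0`. Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return A [dwi_volume()].
#' @export
generate_dwi_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  scheme <- spec$scheme
  nvol <- length(scheme$bvalues)
  dims <- spec$grid_shape
  nvox <- prod(dims)
  S <- matrix(0, nvox, nvol)
  labels <- c(background = 0L, projection = 1L, association = 2L,
              subcortical = 3L)
  for (nm in names(labels)) {
    idx <- which(spec$region_map == labels[[nm]])
    if (!length(idx)) next
    sig <- simulate_signal(spec$tensors[[nm]], scheme, spec$s0)
    S[idx, ] <- matrix(sig, length(idx), nvol, byrow = TRUE)
  }
  if (is.finite(spec$snr_b0)) {
    set.seed(spec$seed)
    sigma <- spec$s0 / spec$snr_b0
    S <- sqrt((S + stats::rnorm(length(S), sd = sigma))^2 +
                stats::rnorm(length(S), sd = sigma)^2)
  }
  dwi_volume(array(S, dim = c(dims, nvol)), scheme,
             voxel_size = spec$voxel_size)
}

#' ROI specifications at the phantom's region centroids
#'
#' Returns one ROI per fiber region, centered on the region's voxel
#' centroid, sized at the spec's ROI voxel count. The generator guarantees
#' the selected voxels fall inside their region.
#'
#' @param spec A [phantom_spec()].
#' @return Named list of [roi_spec()] objects (`projection`, `association`,
#'   `subcortical`).
#' @export
phantom_rois <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- c(projection = 1L, association = 2L, subcortical = 3L)
  out <- lapply(names(labels), function(nm) {
    idx <- which(spec$region_map == labels[[nm]], arr.ind = TRUE)
    ctr <- colMeans(idx)
    roi <- roi_spec(nm, ctr, diameter = 5,
                    target_voxel_count = spec$roi_voxel_count)
    vox <- roi_voxels(roi, spec$grid_shape, spec$voxel_size)
    lab <- spec$region_map[vox]
    if (any(lab != labels[[nm]])) {
      stop("ROI at the ", nm, " centroid extends beyond its region")
    }
    roi
  })
  names(out) <- names(labels)
  out
}
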
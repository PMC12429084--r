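#' Specify a spherical region of interest
#'
#' ROIs are placed at the lateral-ventricle level in projection-,
#' association- and subcortical-fiber areas; at 2.5 mm isotropic resolution a
#' 5 mm sphere covers about 12 voxels, which is the default target count.
#'
#' @param label One of `"projection"`, `"association"`, `"subcortical"`.
#' @param center Voxel coordinates (length 3, 1-based, may be fractional).
#' @param diameter Nominal sphere diameter in mm (> 0).
#' @param target_voxel_count Number of voxels the ROI must contain.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(label, center, diameter = 5, target_voxel_count = 12L) {
  label <- match.arg(label, c("projection", "association", "subcortical"))
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("'center' must be 3 finite voxel coordinates")
  }
  assert_scalar_num(diameter, "diameter", lower = 1e-12)
  target_voxel_count <- assert_count(target_voxel_count,
                                     "target_voxel_count", 1L)
  structure(list(label = label, center = center, diameter = diameter,
                 target_voxel_count = target_voxel_count),
            class = "roi_spec")
}

#' Deterministic ROI voxel selection
#'
#' Selects the `target_voxel_count` voxels nearest the ROI center in
#' millimetre (Euclidean) distance, ties broken by lexicographic voxel
#' index. If any selected voxel of the unbounded lattice falls outside the
#' grid the ROI is out of bounds and an error is raised.
#'
#' @param roi A [roi_spec()].
#' @param grid_shape Integer vector of voxels per axis.
#' @param voxel_size Isotropic voxel edge (mm).
#' @return Integer matrix, one row per voxel, columns x/y/z (1-based).
#' @export
roi_voxels <- function(roi, grid_shape, voxel_size = 2.5) {
  stopifnot(inherits(roi, "roi_spec"))
  grid_shape <- as.integer(grid_shape)
  ctr <- roi$center
  if (any(ctr < 1) || any(ctr > grid_shape)) {
    stop("ROI center lies outside the volume")
  }
  k <- roi$target_voxel_count
  half <- max(ceiling(roi$diameter / voxel_size), ceiling(k^(1 / 3))) + 1L
  rng <- lapply(1:3, function(i) {
    seq(floor(ctr[i]) - half, ceiling(ctr[i]) + half)
  })
  cand <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  d2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2 +
    (cand[, 3] - ctr[3])^2
  ord <- order(d2, cand[, 1], cand[, 2], cand[, 3])
  sel <- cand[ord[seq_len(k)], , drop = FALSE]
  inside <- sel >= 1 & sel <= matrix(grid_shape, nrow(sel), 3, byrow = TRUE)
  if (!all(inside)) stop("ROI extends outside the volume")
  storage.mode(sel) <- "integer"
  dimnames(sel) <- list(NULL, c("x", "y", "z"))
  sel
}

#' Mean of a scalar map over ROI voxels
#'
#' Arithmetic mean over the voxels whose tensor fit succeeded. All-bad ROIs
#' are an error rather than a silent NaN.
#'
#' @param map 3-D numeric array (e.g. an axis-diffusivity map).
#' @param voxels Integer matrix of voxel coordinates, as from
#'   [roi_voxels()].
#' @param fit_ok Optional logical array marking usable voxels.
#' @return Scalar mean.
#' @export
roi_mean <- function(map, voxels, fit_ok = NULL) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) == 0L) stop("empty ROI")
  vals <- map[voxels]
  if (!is.null(fit_ok)) {
    keep <- fit_ok[voxels]
    if (!any(keep)) stop("all ROI voxels are flagged as failed fits")
    vals <- vals[keep]
  }
  mean(vals)
}

#' The DTI-ALPS index
#'
#' `ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)`: x-axis
#' (perivascular) diffusivity in the projection- and association-fiber ROIs
#' over the diffusivity perpendicular to the dominant fibers in the same
#' ROIs. Unitless and invariant to rescaling all four diffusivities.
#'
#' @param dx_proj,dy_proj Dx and Dy means in the projection ROI (mm2/s).
#' @param dx_assoc,dz_assoc Dx and Dz means in the association ROI (mm2/s).
#' @return Scalar index.
#' @export
#' @examples
#' alps_index(1.35e-3, 0.8e-3, 1.35e-3, 0.7e-3)  # 1.8
alps_index <- function(dx_proj, dy_proj, dx_assoc, dz_assoc) {
  for (nm in c("dx_proj", "dy_proj", "dx_assoc", "dz_assoc")) {
    assert_scalar_num(get(nm), nm)
  }
  den <- mean(c(dy_proj, dz_assoc))
  if (den <= 0) stop("perpendicular diffusivity mean must be positive")
  mean(c(dx_proj, dx_assoc)) / den
}

#' End-to-end per-subject ALPS computation
#'
#' Composes tensor fitting, axis-diffusivity extraction, ROI aggregation and
#' the index formula. The subcortical ROI, when supplied, is measured and
#' reported but does not enter the index.
#'
#' @param dwi A [dwi_volume()].
#' @param rois List of [roi_spec()] objects including at least one
#'   `projection` and one `association` ROI.
#' @return An object of class `alps_result` with fields `dx_proj`,
#'   `dy_proj`, `dx_assoc`, `dz_assoc` (mm2/s), `alps_index`, and per-ROI
#'   `voxel_counts`.
#' @export
compute_subject_alps <- function(dwi, rois) {
  stopifnot(inherits(dwi, "dwi_volume"))
  labels <- vapply(rois, function(r) r$label, character(1))
  if (!("projection" %in% labels) || !("association" %in% labels)) {
    stop("ROIs must include a projection and an association region")
  }
  field <- fit_tensor(dwi)
  maps <- axis_diffusivities(field)
  dims <- dim(dwi$signal)[1:3]
  vs <- voxel_size(dwi)

  pick <- function(lab) rois[[which(labels == lab)[1]]]
  vox <- lapply(labels, function(lab) {
    roi_voxels(pick(lab), dims, vs)
  })
  names(vox) <- labels

  proj <- vox[["projection"]]
  assoc <- vox[["association"]]
  dx_proj <- roi_mean(maps$dxx, proj, field$fit_ok)
  dy_proj <- roi_mean(maps$dyy, proj, field$fit_ok)
  dx_assoc <- roi_mean(maps$dxx, assoc, field$fit_ok)
  dz_assoc <- roi_mean(maps$dzz, assoc, field$fit_ok)

  structure(list(
    dx_proj = dx_proj, dy_proj = dy_proj,
    dx_assoc = dx_assoc, dz_assoc = dz_assoc,
    alps_index = alps_index(dx_proj, dy_proj, dx_assoc, dz_assoc),
    voxel_counts = vapply(vox, nrow, integer(1))
  ), class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> ALPS index %.4f\n", x$alps_index))
  cat(sprintf("  Dx-proj %.4g  Dy-proj %.4g  Dx-assoc %.4g  Dz-assoc %.4g (mm2/s)\n",
              x$dx_proj, x$dy_proj, x$dx_assoc, x$dz_assoc))
  invisible(x)
}
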
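#' Ellipsoid volume of interest
#'
#' Parametric stand-in for a manually drawn 3-D ellipsoid VOI enclosing
#' the primary lesion. Coordinates are in mm, in the grid frame where the
#' first voxel's center sits at (0, 0, 0) and voxel `(i, j, k)` (1-based)
#' has center `((i-1)*dx, (j-1)*dy, (k-1)*dz)`.
#'
#' @param center_mm Numeric triple, ellipsoid center (mm).
#' @param radii_mm Numeric triple of semi-axes (mm), strictly positive.
#' @return Object of class `ellipsoid_voi`.
#' @export
ellipsoid_voi <- function(center_mm, radii_mm) {
  center_mm <- as.numeric(center_mm); radii_mm <- as.numeric(radii_mm)
  if (length(center_mm) != 3L || length(radii_mm) != 3L)
    stop("center and radii must be length-3")
  if (any(!is.finite(c(center_mm, radii_mm))) || any(radii_mm <= 0))
    stop("radii must be strictly positive and finite")
  structure(list(center = center_mm, radii = radii_mm),
            class = "ellipsoid_voi")
}

#' Rasterize an ellipsoid VOI on a grid
#'
#' A voxel belongs to the VOI iff its center satisfies
#' `sum(((x - c) / r)^2) <= 1` (voxel-center test; no partial-volume
#' weighting).
#'
#' @param voi An [ellipsoid_voi()].
#' @param grid An [image_volume()] supplying shape and spacing.
#' @return [binary_mask()]; errors if no voxel center falls inside.
#' @export
voi_mask <- function(voi, grid) {
  stopifnot(inherits(voi, "ellipsoid_voi"), inherits(grid, "image_volume"))
  d <- dim(grid$values); sp <- grid$spacing
  q <- lapply(1:3, function(ax)
    (((seq_len(d[ax]) - 1) * sp[ax] - voi$center[ax]) / voi$radii[ax])^2)
  s <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+")
  sel <- s <= 1
  if (!any(sel)) stop("ellipsoid VOI does not intersect the grid")
  binary_mask(sel, sp)
}

#' Maximum SUV within a mask
#'
#' @param pet PET [image_volume()].
#' @param mask Nonempty [binary_mask()] on the same grid (typically a VOI
#'   rasterization).
#' @return Maximum SUV over the mask voxels.
#' @export
suv_max <- function(pet, mask) {
  stopifnot(inherits(pet, "image_volume"), inherits(mask, "binary_mask"))
  check_paired_grid(pet, mask)
  if (!any(mask$values)) stop("mask is empty")
  max(pet$values[mask$values])
}

#' Segment the metabolic tumor volume
#'
#' Voxels of the VOI with SUV strictly greater than `fraction * SUVmax`
#' (default 40% isocontour). The threshold is strict, so the maximum voxel
#' itself is always included and the result is nonempty whenever SUVmax is
#' positive.
#'
#' @param pet PET [image_volume()].
#' @param voi_mask Nonempty [binary_mask()] of the VOI.
#' @param fraction Threshold fraction of SUVmax, in (0, 1). Default 0.40.
#' @return [binary_mask()] of the MTV region.
#' @export
segment_mtv <- function(pet, voi_mask, fraction = 0.40) {
  stopifnot(inherits(voi_mask, "binary_mask"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  smax <- suv_max(pet, voi_mask)
  if (smax <= 0) stop("SUVmax within the VOI is not positive")
  sel <- voi_mask$values & (pet$values > fraction * smax)
  binary_mask(sel, pet$spacing)
}

#' Tumor metabolic parameters for one lesion VOI
#'
#' Computes SUVmax over the VOI, the MTV as the volume of the
#' `> fraction * SUVmax` subregion, the mean SUV of that subregion, and
#' TLG = MTV x mean SUV. When an interference mask is supplied (e.g. a
#' hot bladder overlapping the VOI), the PET data inside it is cleared
#' first and all metrics are computed on the cleared volume.
#'
#' @param pet PET [image_volume()].
#' @param voi [ellipsoid_voi()] for the primary lesion.
#' @param fraction MTV threshold fraction, default 0.40.
#' @param interference Optional [binary_mask()] to clear before measuring
#'   (see [clear_interference()]).
#' @return Object of class `tumor_metrics`: `suvmax`, `mtv_cm3`, `tlg`,
#'   `mtv_mean_suv`, `threshold_fraction`.
#' @export
tumor_metrics <- function(pet, voi, fraction = 0.40, interference = NULL) {
  if (!is.null(interference)) pet <- clear_interference(pet, interference)
  vm <- voi_mask(voi, pet)
  smax <- suv_max(pet, vm)
  mm <- segment_mtv(pet, vm, fraction)
  n <- sum(mm$values)
  mean_suv <- mean(pet$values[mm$values])
  mtv <- n * voxel_cm3(pet$spacing)
  structure(
    list(suvmax = smax, mtv_cm3 = mtv, tlg = mtv * mean_suv,
         mtv_mean_suv = mean_suv, threshold_fraction = fraction),
    class = "tumor_metrics")
}

#' @export
print.tumor_metrics <- function(x, ...) {
  cat(sprintf(
    "<tumor_metrics> SUVmax %.2f | MTV %.2f cm3 (>%.0f%% SUVmax) | TLG %.1f | MTV mean SUV %.2f\n",
    x$suvmax, x$mtv_cm3, 100 * x$threshold_fraction, x$tlg, x$mtv_mean_suv))
  invisible(x)
}

#' Clear interfering high-uptake structures from PET
#'
#' Returns a copy of the PET volume with values inside the interference
#' mask set to 0 and every other voxel unchanged. Used to remove e.g.
#' urinary activity before measuring lesion parameters.
#'
#' @param pet PET [image_volume()].
#' @param interference [binary_mask()] on the same grid.
#' @return A new [image_volume()].
#' @export
clear_interference <- function(pet, interference) {
  stopifnot(inherits(pet, "image_volume"),
            inherits(interference, "binary_mask"))
  check_paired_grid(pet, interference)
  vals <- pet$values
  vals[interference$values] <- 0
  image_volume(vals, pet$spacing, pet$modality)
}

#' Analytic 40%-isocontour volume of a Gaussian lesion
#'
#' For a spherically symmetric lesion profile `peak * exp(-r^2 / (2
#' sigma^2))`, the isocontour at `fraction * peak` is the sphere of radius
#' `sigma * sqrt(2 * log(1 / fraction))`; its volume is the continuous
#' limit of the discretized MTV as spacing tends to zero.
#'
#' @param sigma Gaussian falloff (mm).
#' @param fraction Isocontour fraction, default 0.40.
#' @return Volume in cm3.
#' @export
gaussian_isocontour_cm3 <- function(sigma, fraction = 0.40) {
  r <- sigma * sqrt(2 * log(1 / fraction))
  (4 / 3) * pi * r^3 / 1000
}
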
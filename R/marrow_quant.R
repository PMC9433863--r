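#' Pelvic region of interest
#'
#' An axial slab (inclusive 1-based slice indices) with an optional lateral
#' crop box, standing in for the anatomical bounds used for pelvic bone
#' segmentation (L4-L5 vertebrae down to the ischial tuberosity). The
#' anatomical extent is supplied by the user or the phantom generator;
#' automatic vertebra detection is out of scope.
#'
#' @param z_lo,z_hi First and last axial slice (1-based, inclusive),
#'   `1 <= z_lo <= z_hi`.
#' @param crop Optional list with elements `i = c(lo, hi)`, `j = c(lo, hi)`
#'   restricting the in-plane extent (1-based, inclusive). `NULL` keeps the
#'   whole slice.
#' @return Object of class `pelvic_roi`.
#' @export
pelvic_roi <- function(z_lo, z_hi, crop = NULL) {
  z_lo <- as.integer(z_lo); z_hi <- as.integer(z_hi)
  if (z_lo < 1L || z_hi < z_lo) stop("need 1 <= z_lo <= z_hi")
  if (!is.null(crop)) {
    stopifnot(is.list(crop), all(c("i", "j") %in% names(crop)))
    for (ax in c("i", "j")) {
      r <- as.integer(crop[[ax]])
      if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
        stop("invalid crop range for axis ", ax)
      crop[[ax]] <- r
    }
  }
  structure(list(z_lo = z_lo, z_hi = z_hi, crop = crop),
            class = "pelvic_roi")
}

# logical array marking the ROI on a given grid
roi_array <- function(roi, dims) {
  if (roi$z_hi > dims[3]) stop("ROI slab exceeds grid depth (", dims[3], ")")
  ir <- if (is.null(roi$crop)) c(1L, dims[1]) else roi$crop$i
  jr <- if (is.null(roi$crop)) c(1L, dims[2]) else roi$crop$j
  if (ir[2] > dims[1] || jr[2] > dims[2]) stop("ROI crop exceeds grid extent")
  a <- array(FALSE, dims)
  a[ir[1]:ir[2], jr[1]:jr[2], roi$z_lo:roi$z_hi] <- TRUE
  a
}

#' Segment bone from CT by HU thresholding
#'
#' A voxel is bone iff it lies inside the pelvic ROI and its attenuation is
#' at or above the threshold (default 150 HU, inclusive). No morphological
#' cleanup is applied; corrections are expressed as explicit mask edits
#' ([apply_mask_edits()]).
#'
#' @param ct CT [image_volume()] (HU).
#' @param roi A [pelvic_roi()].
#' @param hu_threshold Bone threshold in HU; voxels with `HU >=
#'   hu_threshold` are kept. Default 150.
#' @return [binary_mask()] of the segmented bone (BM_TOT region). Errors if
#'   no voxel passes, which usually signals wrong units or a wrong ROI.
#' @export
segment_bone <- function(ct, roi, hu_threshold = 150) {
  stopifnot(inherits(ct, "image_volume"), inherits(roi, "pelvic_roi"))
  if (ct$modality != "CT") stop("`ct` must be a CT volume (HU)")
  sel <- roi_array(roi, dim(ct$values)) & (ct$values >= hu_threshold)
  if (!any(sel))
    stop("bone segmentation is empty (no voxel in ROI reaches ",
         hu_threshold, " HU); check units and ROI")
  binary_mask(sel, ct$spacing)
}

#' Apply manual mask corrections
#'
#' Represents the manual correction step of semi-automatic bone
#' segmentation as an ordered edit list. Edits are applied in order; the
#' input mask is not modified.
#'
#' @param mask A [binary_mask()].
#' @param edits Data frame with integer columns `i`, `j`, `k` (1-based
#'   voxel indices) and character column `action` (`"add"` or `"remove"`),
#'   e.g. from [read_mask_edits()]. Zero rows is allowed.
#' @return A new [binary_mask()] with the edits applied.
#' @export
apply_mask_edits <- function(mask, edits) {
  stopifnot(inherits(mask, "binary_mask"), is.data.frame(edits))
  vals <- mask$values
  if (nrow(edits) == 0L) return(binary_mask(vals, mask$spacing))
  stopifnot(all(c("i", "j", "k", "action") %in% names(edits)))
  d <- dim(vals)
  ijk <- cbind(as.integer(edits$i), as.integer(edits$j), as.integer(edits$k))
  if (any(ijk < 1L) || any(ijk[, 1] > d[1] | ijk[, 2] > d[2] | ijk[, 3] > d[3]))
    stop("mask edit index outside the grid")
  act <- as.character(edits$action)
  if (!all(act %in% c("add", "remove"))) stop("action must be add/remove")
  for (r in seq_len(nrow(edits)))
    vals[ijk[r, 1], ijk[r, 2], ijk[r, 3]] <- (act[r] == "add")
  binary_mask(vals, mask$spacing)
}

#' Read mask edits from CSV
#'
#' @param path CSV with columns `i,j,k,action` (1-based indices).
#' @return Data frame suitable for [apply_mask_edits()].
#' @export
read_mask_edits <- function(path) {
  ed <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("i", "j", "k", "action") %in% names(ed)))
  ed
}

#' Active bone marrow metrics from PET over a bone mask
#'
#' Computes the patient's mean bone SUV over the (corrected) bone mask,
#' then counts bone voxels whose SUV is at or above that mean (inclusive).
#' BM_TOT is the bone-mask volume, BM_ACT the volume of the at-or-above-
#' mean subregion, and BM_ACT% their ratio in percent. Volumes are voxel
#' count times voxel volume, reported in cm3. The mean is computed on the
#' final mask, i.e. after any manual corrections.
#'
#' @param pet PET [image_volume()] (SUV) on the same grid as the mask.
#' @param bone_mask Nonempty [binary_mask()] of the segmented bone.
#' @return Object of class `bm_metrics`: `bm_tot_cm3`, `bm_act_cm3`,
#'   `bm_act_pct`, `bone_mean_suv`, and `bm_group` (see
#'   [classify_bm_act_group()]).
#' @export
compute_bm_metrics <- function(pet, bone_mask) {
  stopifnot(inherits(pet, "image_volume"), inherits(bone_mask, "binary_mask"))
  if (pet$modality != "PET") stop("`pet` must be a PET volume (SUV)")
  check_paired_grid(pet, bone_mask)
  n_tot <- sum(bone_mask$values)
  if (n_tot == 0L) stop("bone mask is empty")
  suv <- pet$values[bone_mask$values]
  m <- mean(suv)
  n_act <- sum(suv >= m)
  vc <- voxel_cm3(pet$spacing)
  pct <- 100 * n_act / n_tot
  structure(
    list(bm_tot_cm3 = n_tot * vc, bm_act_cm3 = n_act * vc,
         bm_act_pct = pct, bone_mean_suv = m,
         bm_group = classify_bm_act_group(pct)),
    class = "bm_metrics")
}

#' @export
print.bm_metrics <- function(x, ...) {
  cat(sprintf(
    "<bm_metrics> BM_TOT %.2f cm3 | BM_ACT %.2f cm3 | BM_ACT%% %.1f%% (%s) | mean bone SUV %.3f\n",
    x$bm_tot_cm3, x$bm_act_cm3, x$bm_act_pct, x$bm_group, x$bone_mean_suv))
  invisible(x)
}

#' Group a BM_ACT percentage
#'
#' Grouping used for the cross-tabulation against hematologic toxicity:
#' `<30%`, `30%-40%` (closed on both ends) and `>40%`.
#'
#' @param pct Numeric vector of BM_ACT percentages, each in (0, 100].
#' @return Character vector with values `"LT30"`, `"MID30_40"`, `"GT40"`.
#' @export
classify_bm_act_group <- function(pct) {
  if (any(!is.finite(pct)) || any(pct <= 0) || any(pct > 100))
    stop("BM_ACT% must lie in (0, 100]")
  ifelse(pct < 30, "LT30", ifelse(pct <= 40, "MID30_40", "GT40"))
}

#' Levels of the BM_ACT% grouping, in display order
#' @keywords internal
bm_group_levels <- function() c("LT30", "MID30_40", "GT40")
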
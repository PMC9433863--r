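#' Construct an image volume
#'
#' A 3-D scalar grid with millimetre voxel spacing, the carrier for both CT
#' (Hounsfield units) and PET (standardized uptake values) throughout the
#' pipeline. Units follow the modality: CT volumes are in HU, PET volumes
#' in SUV.
#'
#' @param values 3-D numeric array of voxel values. All values must be
#'   finite.
#' @param spacing Numeric triple of voxel edge lengths in mm, all strictly
#'   positive.
#' @param modality Either `"CT"` or `"PET"`.
#' @return An object of class `image_volume` with fields `values`,
#'   `spacing`, `modality` and `units` (`"HU"` for CT, `"SUV"` for PET).
#' @export
image_volume <- function(values, spacing, modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0L)
    stop(sprintf("volume contains %d non-finite voxel(s)", n_bad))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)")
  structure(
    list(values = values, spacing = spacing, modality = modality,
         units = if (modality == "CT") "HU" else "SUV"),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %s (%s), %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$modality, x$units, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a binary mask
#'
#' A 3-D logical grid annotating a volume on the same grid (same shape and
#' spacing). Used for bone regions, VOI rasterizations, metabolic tumour
#' volumes and interference regions.
#'
#' @param values 3-D logical (or 0/1 numeric) array.
#' @param spacing Numeric triple, mm.
#' @return Object of class `binary_mask` with logical `values` and
#'   `spacing`.
#' @export
binary_mask <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("numeric mask values must be 0/1")
    values <- array(values != 0, dim(values))
  }
  if (!is.logical(values)) stop("mask values must be logical or 0/1")
  if (anyNA(values)) stop("mask contains NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)")
  structure(list(values = values, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d set (%.3g cm3)\n",
              d[1], d[2], d[3], sum(x$values),
              sum(x$values) * prod(x$spacing) / 1000))
  invisible(x)
}

# voxel volume in cm3 (spacing is mm)
voxel_cm3 <- function(spacing) prod(spacing) / 1000

#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI file as an [image_volume()]. Voxel values are taken
#' as stored (no rescaling beyond the NIfTI scl slope/intercept applied by
#' the reader); spacing comes from the header pixdim.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param modality `"CT"` or `"PET"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("expected a 3-D image, got ", length(dim(a)), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(a, sp, modality)
}

#' Write a volume to NIfTI
#'
#' Inverse of [read_volume()]: `read_volume(write_volume(v, p), v$modality)`
#' returns a volume with identical values and spacing.
#'
#' @param v An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "image_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a binary mask as 0/1 NIfTI
#'
#' Masks are stored as 0/1 scalars; on read, any nonzero voxel is treated
#' as set.
#'
#' @param path NIfTI path.
#' @return [binary_mask()] for `read_mask`; `path` invisibly for
#'   `write_mask`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path, "CT")  # modality irrelevant; reuse the reader
  vals <- v$values
  if (!all(vals %in% c(0, 1)))
    stop("mask file contains values other than 0/1: ", path)
  binary_mask(vals != 0, v$spacing)
}

#' @rdname read_mask
#' @param mask A [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$values), dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Enforce the paired-grid contract between CT and PET
#'
#' All CT-mask-on-PET operations assume the two volumes live on the same
#' grid (hardware-aligned PET/CT; no registration or resampling is done
#' here). Shapes must be equal and spacings equal within 1e-6 mm;
#' otherwise an error signals that resampling is required upstream.
#'
#' @param ct,pet [image_volume()]s (or a volume and a [binary_mask()]).
#' @return Invisibly `TRUE` on success; errors otherwise.
#' @export
check_paired_grid <- function(ct, pet) {
  da <- dim(ct$values); db <- dim(pet$values)
  if (!identical(da, db))
    stop(sprintf("grid shape mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  if (any(abs(ct$spacing - pet$spacing) > 1e-6))
    stop(sprintf("voxel spacing mismatch: (%s) vs (%s) mm",
                 paste(signif(ct$spacing, 8), collapse = ", "),
                 paste(signif(pet$spacing, 8), collapse = ", ")))
  invisible(TRUE)
}
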
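#' CT volume container
#'
#' A minimal container for a 3D CT volume: a scalar voxel grid in Hounsfield
#' units (HU) plus the physical voxel spacing in mm. HU values are clamped to
#' the representable CT range \[-1024, 3071\] on construction.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing Numeric length-3, voxel spacing in mm per axis (all > 0).
#' @param scan_id Character scan identifier.
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `scan_id`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), scan_id = "scan") {
  if (length(dim(voxels)) != 3L)
    stopf("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be 3 strictly positive mm values")
  voxels <- pmin(pmax(voxels, -1024), 3071)
  structure(list(voxels = voxels, spacing = spacing,
                 scan_id = as.character(scan_id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s> %s voxels, spacing %s mm, HU range [%d, %d]\n",
              x$scan_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              round(min(x$voxels)), round(max(x$voxels))))
  invisible(x)
}

#' Binary lung-field mask
#'
#' @param mask 3D logical array, same shape as its source volume.
#' @return An object of class `lung_mask` with fields `mask` and
#'   `voxel_count`.
#' @export
lung_mask <- function(mask) {
  if (length(dim(mask)) != 3L)
    stopf("`mask` must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  structure(list(mask = mask, voxel_count = sum(mask)), class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %s voxels, %d in mask (%.1f%%)\n",
              paste(dim(x$mask), collapse = "x"), x$voxel_count,
              100 * x$voxel_count / length(x$mask)))
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' @param a,b `lung_mask` objects (or 3D logical arrays) of identical shape.
#' @return Dice coefficient in \[0, 1\]; 1 for two empty masks.
#' @export
mask_dice <- function(a, b) {
  ma <- if (inherits(a, "lung_mask")) a$mask else a
  mb <- if (inherits(b, "lung_mask")) b$mask else b
  stopifnot(identical(dim(ma), dim(mb)))
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(1)
  2 * sum(ma & mb) / denom
}

#' Read a CT volume from NIfTI
#'
#' Voxel spacing is taken from the NIfTI header; HU values are clamped to
#' \[-1024, 3071\].
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param scan_id Identifier; defaults to the file name without extension.
#' @return A [ct_volume()].
#' @export
read_ct_nifti <- function(path, scan_id = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(scan_id))
    scan_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(array(as.numeric(img), dim(img)[1:3]),
            spacing = RNifti::pixdim(img)[1:3], scan_id = scan_id)
}

#' Write a CT volume (or mask) to NIfTI
#'
#' @param x A [ct_volume()] or [lung_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    arr <- x$voxels
    spacing <- x$spacing
  } else if (inherits(x, "lung_mask")) {
    arr <- array(as.integer(x$mask), dim(x$mask))
    spacing <- c(1, 1, 1)
  } else stopf("`x` must be a ct_volume or lung_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path Path to a NIfTI file containing 0/1 voxels.
#' @return A [lung_mask()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  lung_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]))
}
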
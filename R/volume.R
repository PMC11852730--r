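#' Construct a 3D scalar volume with physical voxel spacing
#'
#' A `volume_image` is the basic image container of the pipeline: a 3D
#' numeric array (an MRI sequence or a filtered derivative) plus its voxel
#' spacing in millimetres. Voxel values must be finite; removed or missing
#' voxels are tracked through the segmentation mask, never as `NA`s in the
#' image.
#'
#' @param voxels 3D numeric array.
#' @param spacing_mm positive numeric triple, voxel edge lengths in mm.
#' @param origin world-space offset of the first voxel centre (mm).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing_mm, origin = c(0, 0, 0)) {
  stop_if_not(is.numeric(voxels) && length(dim(voxels)) == 3L,
              "`voxels` must be a 3D numeric array")
  stop_if_not(all(is.finite(voxels)), "voxel values must all be finite")
  spacing_mm <- as.numeric(spacing_mm)
  stop_if_not(length(spacing_mm) == 3L && all(spacing_mm > 0),
              "`spacing_mm` must be a positive triple")
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' Construct a binary segmentation mask aligned to a volume
#'
#' @param voxels 3D logical (or 0/1 numeric) array.
#' @param spacing_mm voxel spacing in mm, matching the paired image.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(voxels, spacing_mm) {
  stop_if_not(length(dim(voxels)) == 3L, "`voxels` must be a 3D array")
  v <- array(as.logical(voxels), dim = dim(voxels))
  stop_if_not(!anyNA(v), "mask voxels must be TRUE/FALSE")
  spacing_mm <- as.numeric(spacing_mm)
  stop_if_not(length(spacing_mm) == 3L && all(spacing_mm > 0),
              "`spacing_mm` must be a positive triple")
  structure(list(voxels = v, spacing_mm = spacing_mm),
            class = "segmentation_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$voxels), collapse = "x"),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, ", sum(x$voxels), " foreground\n", sep = "")
  invisible(x)
}

mask_count <- function(mask) sum(mask$voxels)

check_aligned <- function(img, mask) {
  stop_if_not(identical(dim(img$voxels), dim(mask$voxels)),
              "image and mask dimensions differ")
  stop_if_not(isTRUE(all.equal(img$spacing_mm, mask$spacing_mm,
                               tolerance = 1e-6)),
              "image and mask spacing differ")
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' Spacing is taken from the NIfTI header. Only 3D, axis-aligned volumes are
#' supported; an affine with shear or rotation is rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image].
#' @export
read_volume <- function(path) {
  stop_if_not(file.exists(path), "file not found: ", path)
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  stop_if_not(length(d) == 3L, "only 3D volumes are supported (got ",
              length(d), "D)")
  xf <- structure(RNifti::xform(nii), class = NULL)
  rot <- xf[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  aligned <- abs(rot) / rep(sp, each = 3)
  stop_if_not(all(abs(aligned[aligned < 0.99]) < 1e-4),
              "affine has shear/rotation; only axis-aligned volumes supported")
  volume_image(array(as.numeric(nii), dim = d), spacing_mm = sp,
               origin = xf[1:3, 4])
}

#' Write a volume (or mask) as NIfTI
#'
#' @param img a [volume_image] or [segmentation_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  if (inherits(img, "segmentation_mask")) {
    arr <- array(as.numeric(img$voxels), dim = dim(img$voxels))
    sp <- img$spacing_mm
    org <- c(0, 0, 0)
  } else {
    arr <- img$voxels
    sp <- img$spacing_mm
    org <- img$origin %||% c(0, 0, 0)
  }
  attr(arr, "pixdim") <- sp
  RNifti::writeNifti(arr, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI segmentation mask
#'
#' Voxels > 0.5 are foreground.
#' @param path path to the mask file.
#' @return A [segmentation_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  segmentation_mask(v$voxels > 0.5, v$spacing_mm)
}
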
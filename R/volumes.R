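# ---- volume containers and NIfTI I/O ----------------------------------------

#' CT intensity volume
#'
#' A 3-D scalar field of intensities (HU or normalized units) on a regular
#' grid with per-axis voxel spacing in mm.
#'
#' @param voxels 3-D numeric array
#' @param spacing numeric length-3, strictly positive, in mm
#' @return object of class `ct_volume`
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' Binary mask volume
#'
#' @param voxels 3-D array containing only 0 and 1
#' @param spacing numeric length-3, strictly positive, in mm
#' @return object of class `mask_volume`
#' @export
mask_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (!all(voxels %in% c(0L, 1L)))
    stop("mask voxels must contain only 0 and 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  v <- array(as.integer(voxels), dim = dim(voxels))
  structure(list(voxels = v, spacing = spacing), class = "mask_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("CT volume %s @ %s mm, range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("Mask volume %s @ %s mm, foreground fraction %.4f\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              mean(x$voxels)))
  invisible(x)
}

.same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}

#' Foreground fraction of a mask
#' @param mask a [mask_volume()] or binary array
#' @return fraction of voxels equal to 1
#' @export
foreground_fraction <- function(mask) {
  v <- if (inherits(mask, "mask_volume")) mask$voxels else mask
  mean(v)
}

#' Write a volume to NIfTI
#'
#' Spacing is stored in the header pixdim; CT volumes are written as float64
#' so intensities round-trip bit-exactly, masks as uint8.
#'
#' @param vol a [ct_volume()] or [mask_volume()]
#' @param path output file, conventionally `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_volume_nifti <- function(vol, path) {
  arr <- vol$voxels
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- vol$spacing
  dt <- if (inherits(vol, "mask_volume")) "uint8" else "double"
  RNifti::writeNifti(im, path, datatype = dt)
  invisible(path)
}

#' Read a NIfTI file as a CT volume
#' @param path NIfTI file
#' @return a [ct_volume()]
#' @export
read_ct_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(im), dim = dim(im)), spacing = RNifti::pixdim(im)[1:3])
}

#' Read a NIfTI file as a binary mask volume
#' @param path NIfTI file
#' @return a [mask_volume()]
#' @export
read_mask_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  mask_volume(array(as.integer(im > 0.5), dim = dim(im)),
              spacing = RNifti::pixdim(im)[1:3])
}
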
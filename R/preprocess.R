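# ---- CT preprocessing -------------------------------------------------------
#
# Chain applied before training/inference: HU windowing (0-400 HU, the liver
# range) -> isotropic 1 mm resampling -> per-volume z-score normalization.
# Liver-ROI construction (box dilation of the liver label by 20 mm per axis)
# and joint flip augmentation live here too.

#' Preprocessing configuration
#'
#' @param hu_window intensity clipping window in HU, default `c(0, 400)`
#' @param target_spacing isotropic resampling target in mm, default 1 mm
#' @param mask_margin liver-ROI dilation margin in mm, default 20
#' @param augmentation_axes axes eligible for random flipping
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(hu_window = c(0, 400),
                              target_spacing = c(1, 1, 1),
                              mask_margin = 20, augmentation_axes = 1:3) {
  if (hu_window[1] >= hu_window[2]) stop("hu_window low must be < high")
  if (any(target_spacing <= 0)) stop("target_spacing must be positive")
  if (mask_margin < 0) stop("mask_margin must be >= 0")
  structure(list(hu_window = as.numeric(hu_window),
                 target_spacing = as.numeric(target_spacing),
                 mask_margin = as.numeric(mask_margin),
                 augmentation_axes = as.integer(augmentation_axes)),
            class = "preprocess_config")
}

#' Clip CT intensities to an HU window
#'
#' Every voxel v is replaced by `min(max(v, low), high)`; the grid is
#' unchanged. Idempotent.
#'
#' @param volume a [ct_volume()] or numeric array
#' @param window length-2 `c(low, high)` in HU
#' @return same kind as the input
#' @export
clip_hu <- function(volume, window = c(0, 400)) {
  if (window[1] >= window[2]) stop("window low must be < high")
  if (inherits(volume, "ct_volume")) {
    volume$voxels <- pmin(pmax(volume$voxels, window[1]), window[2])
    volume
  } else {
    pmin(pmax(volume, window[1]), window[2])
  }
}

#' Normalize a volume to zero mean and unit variance
#'
#' Statistics are computed per volume over all voxels; variance is the
#' population (1/N) variance, so a two-voxel volume \{0, 2\} maps to
#' \{-1, +1\}. Constant volumes are rejected.
#'
#' @param volume a [ct_volume()] or numeric array
#' @return same kind as the input
#' @export
normalize_zscore <- function(volume) {
  arr <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  if (length(arr) <= 1L) stop("normalization requires more than one voxel")
  mu <- mean(arr)
  sd_pop <- sqrt(mean((arr - mu)^2))
  if (sd_pop == 0) stop("cannot normalize a volume with zero variance")
  out <- (arr - mu) / sd_pop
  if (inherits(volume, "ct_volume")) { volume$voxels <- out; volume } else out
}

# positions (1-based fractional input indices) of output voxel centers
.resample_positions <- function(n_in, sp_in, n_out, sp_out) {
  centers <- (seq_len(n_out) - 0.5) * sp_out
  pmin(pmax(centers / sp_in + 0.5, 1), n_in)
}

#' Resample a volume to a target (typically isotropic 1 mm) spacing
#'
#' Output shape is `round(shape * spacing / target_spacing)`. Intensity
#' volumes are interpolated with separable natural cubic splines; mask
#' volumes use nearest-neighbor so they stay binary. Voxel centers are
#' aligned between the grids.
#'
#' @param volume a [ct_volume()] or [mask_volume()]
#' @param target_spacing length-3 target spacing in mm
#' @return resampled volume of the same class
#' @export
resample_isotropic <- function(volume, target_spacing = c(1, 1, 1)) {
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  arr <- volume$voxels
  sp <- volume$spacing
  n_in <- dim(arr)
  n_out <- as.integer(round(n_in * sp / target_spacing))
  n_out <- pmax(n_out, 1L)
  if (inherits(volume, "mask_volume")) {
    idx <- lapply(1:3, function(a) {
      pos <- .resample_positions(n_in[a], sp[a], n_out[a], target_spacing[a])
      pmin(pmax(round(pos), 1L), n_in[a])
    })
    out <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- n_out
    return(mask_volume(out, spacing = target_spacing))
  }
  interp_axis <- function(a, axis) {
    ni <- dim(a)[axis]
    no <- n_out[axis]
    if (ni == no && isTRUE(all.equal(sp[axis], target_spacing[axis])))
      return(a)
    pos <- .resample_positions(ni, sp[axis], no, target_spacing[axis])
    m <- apply(a, setdiff(1:3, axis), function(line) {
      if (ni == 1L) rep(line, no)
      else stats::splinefun(seq_len(ni), line, method = "natural")(pos)
    })
    # apply returns no x (other dims); restore axis order
    dims_rest <- dim(a)[setdiff(1:3, axis)]
    m <- array(m, dim = c(no, dims_rest))
    perm <- order(c(axis, setdiff(1:3, axis)))
    aperm(m, perm)
  }
  out <- interp_axis(interp_axis(interp_axis(arr, 1L), 2L), 3L)
  ct_volume(out, spacing = target_spacing)
}

#' Build a liver region-of-interest mask by box dilation
#'
#' Axis-aligned dilation: the output is 1 at any voxel within `margin_mm`
#' (converted to voxels per axis via the spacing) of a labeled voxel along
#' each axis — a box structuring element of half-width
#' `round(margin_mm / spacing)` per axis.
#'
#' @param liver_label non-empty [mask_volume()]
#' @param margin_mm dilation margin in mm (default 20)
#' @param element `"box"` (default) or `"ball"` structuring element
#' @return dilated [mask_volume()]
#' @export
build_liver_roi <- function(liver_label, margin_mm = 20,
                            element = c("box", "ball")) {
  element <- match.arg(element)
  stopifnot(inherits(liver_label, "mask_volume"))
  if (sum(liver_label$voxels) == 0L) stop("liver label is empty")
  if (margin_mm < 0) stop("margin must be >= 0")
  arr <- liver_label$voxels
  m_vox <- as.integer(round(margin_mm / liver_label$spacing))
  if (element == "box") {
    dilate_axis <- function(a, axis, m) {
      if (m == 0L) return(a)
      out <- a
      n <- dim(a)[axis]
      for (s in seq_len(m)) {
        lo <- seq_len(n - s); hi <- lo + s
        if (axis == 1L) {
          out[hi, , ] <- pmax(out[hi, , ], a[lo, , ])
          out[lo, , ] <- pmax(out[lo, , ], a[hi, , ])
        } else if (axis == 2L) {
          out[, hi, ] <- pmax(out[, hi, ], a[, lo, ])
          out[, lo, ] <- pmax(out[, lo, ], a[, hi, ])
        } else {
          out[, , hi] <- pmax(out[, , hi], a[, , lo])
          out[, , lo] <- pmax(out[, , lo], a[, , hi])
        }
      }
      out
    }
    out <- arr
    for (axis in 1:3) out <- dilate_axis(out, axis, m_vox[axis])
  } else {
    # ellipsoidal (ball in mm) dilation via distance check around foreground
    d <- dim(arr)
    offs <- expand.grid(dx = -m_vox[1]:m_vox[1], dy = -m_vox[2]:m_vox[2],
                        dz = -m_vox[3]:m_vox[3])
    sp <- liver_label$spacing
    offs <- offs[(offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 +
                   (offs$dz * sp[3])^2 <= margin_mm^2, ]
    fg <- which(arr == 1L, arr.ind = TRUE)
    out <- array(0L, dim = d)
    for (i in seq_len(nrow(offs))) {
      x <- fg[, 1] + offs$dx[i]; y <- fg[, 2] + offs$dy[i]
      z <- fg[, 3] + offs$dz[i]
      ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
      out[cbind(x[ok], y[ok], z[ok])] <- 1L
    }
  }
  mask_volume(out, spacing = liver_label$spacing)
}

#' Crop a volume to the bounding box of an ROI
#'
#' Returns the tight bounding box of the ROI applied to the volume together
#' with the 0-based offset of the box, so the crop can be reinserted with
#' [uncrop_volume()].
#'
#' @param volume a [ct_volume()] or [mask_volume()] on the ROI's grid
#' @param roi non-empty [mask_volume()]
#' @return list with `volume` (cropped, same class) and `offset` (0-based)
#' @export
crop_to_roi <- function(volume, roi) {
  stopifnot(inherits(roi, "mask_volume"))
  if (sum(roi$voxels) == 0L) stop("ROI is empty")
  if (!identical(dim(volume$voxels), dim(roi$voxels)))
    stop("volume and ROI are on different grids")
  idx <- which(roi$voxels == 1L, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  cropped <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                           drop = FALSE]
  out <- volume
  out$voxels <- cropped
  list(volume = out, offset = as.integer(lo - 1L))
}

#' Reinsert a cropped volume at its recorded offset
#'
#' @param cropped cropped volume (as returned by [crop_to_roi()])
#' @param offset 0-based offset of the crop
#' @param shape full-grid voxel counts
#' @param fill value for voxels outside the crop
#' @return full-size volume of the same class
#' @export
uncrop_volume <- function(cropped, offset, shape, fill = 0) {
  full <- array(fill, dim = shape)
  d <- dim(cropped$voxels)
  full[offset[1] + seq_len(d[1]), offset[2] + seq_len(d[2]),
       offset[3] + seq_len(d[3])] <- cropped$voxels
  out <- cropped
  out$voxels <- if (inherits(cropped, "mask_volume"))
    array(as.integer(full), dim = shape) else full
  out
}

#' Joint random flip augmentation of an image/label pair
#'
#' The same flip decision (one Bernoulli draw per eligible axis) is applied
#' to both volumes; uses the current RNG stream, so runs are reproducible
#' under `set.seed()`.
#'
#' @param image a [ct_volume()] or array
#' @param label a [mask_volume()] or array on the same grid
#' @param axes axes eligible for flipping
#' @param prob per-axis flip probability
#' @return list `image`, `label`, `flipped` (logical per axis)
#' @export
augment_flip <- function(image, label, axes = 1:3, prob = 0.5) {
  img <- if (inherits(image, "ct_volume")) image$voxels else image
  lab <- if (inherits(label, "mask_volume")) label$voxels else label
  if (!identical(dim(img), dim(lab)))
    stop("image and label are on different grids")
  flipped <- logical(3)
  flipped[axes] <- stats::runif(length(axes)) < prob
  flip_axis <- function(a, axis) {
    n <- dim(a)[axis]
    switch(axis, a[n:1, , , drop = FALSE], a[, n:1, , drop = FALSE],
           a[, , n:1, drop = FALSE])
  }
  for (axis in which(flipped)) {
    img <- flip_axis(img, axis)
    lab <- flip_axis(lab, axis)
  }
  if (inherits(image, "ct_volume")) image$voxels <- img else image <- img
  if (inherits(label, "mask_volume"))
    label$voxels <- array(as.integer(lab), dim = dim(lab))
  else label <- lab
  list(image = image, label = label, flipped = flipped)
}

#' Full preprocessing chain for one image (clip, resample, normalize)
#'
#' @param image a [ct_volume()]
#' @param label optional [mask_volume()] resampled alongside the image
#' @param config a [preprocess_config()]
#' @return list `image` (and `label` if given), grids aligned
#' @export
preprocess_volume <- function(image, label = NULL,
                              config = preprocess_config()) {
  img <- clip_hu(image, config$hu_window)
  img <- resample_isotropic(img, config$target_spacing)
  img <- normalize_zscore(img)
  if (is.null(label)) return(list(image = img))
  lab <- resample_isotropic(label, config$target_spacing)
  if (!identical(dim(lab$voxels), dim(img$voxels)))
    stop("image and label disagree after resampling")
  list(image = img, label = lab)
}
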
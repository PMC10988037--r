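# ---- connected-component post-filtering -------------------------------------
#
# Predicted vessel masks are cleaned by removing connected components whose
# physical volume is smaller than 180 mm^3 ("smaller than" read strictly:
# a component of exactly 180 mm^3 is kept). Default adjacency is
# 26-connectivity: vessels are thin and oblique, and face-connectivity
# fragments them.

#' Label connected components of a binary mask
#'
#' @param mask a [mask_volume()] or binary 3-D array
#' @param connectivity 26 (faces, edges, corners; default) or 6 (faces)
#' @param spacing voxel spacing in mm (taken from the mask volume if present)
#' @return list with `labels` (integer array, 0 = background) and `report`
#'   (data.frame: component, voxels, volume_mm3)
#' @export
label_components <- function(mask, connectivity = 26, spacing = NULL) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  if (inherits(mask, "mask_volume")) {
    spacing <- mask$spacing
    arr <- mask$voxels
  } else {
    arr <- mask
    if (is.null(spacing)) spacing <- c(1, 1, 1)
  }
  labels <- cc_label3d(array(as.integer(arr), dim = dim(arr)),
                       as.integer(dim(arr)), as.integer(connectivity))
  dim(labels) <- dim(arr)
  voxvol <- prod(spacing)
  fg <- labels[labels > 0L]
  counts <- if (length(fg)) tabulate(fg) else integer(0)
  report <- data.frame(component = seq_along(counts), voxels = counts,
                       volume_mm3 = counts * voxvol)
  list(labels = labels, report = report)
}

#' Remove connected components smaller than a volume threshold
#'
#' Component volume is voxel count times the per-voxel volume from the
#' spacing. Components with volume strictly smaller than `min_volume_mm3`
#' are removed; a component of exactly the threshold volume is kept.
#' Idempotent, and never adds foreground voxels.
#'
#' @param mask a [mask_volume()] or binary 3-D array
#' @param min_volume_mm3 volume threshold in mm^3 (default 180); must be > 0,
#'   except that 0 is allowed and returns the input unchanged
#' @param connectivity 26 (default) or 6
#' @param spacing voxel spacing (taken from the mask volume if present)
#' @return list with `mask` (filtered, same kind as input) and `report`
#'   (per-component data.frame with a `kept` flag)
#' @export
filter_small_components <- function(mask, min_volume_mm3 = 180,
                                    connectivity = 26, spacing = NULL) {
  if (min_volume_mm3 < 0) stop("min_volume_mm3 must be non-negative")
  lc <- label_components(mask, connectivity = connectivity, spacing = spacing)
  report <- lc$report
  report$kept <- report$volume_mm3 >= min_volume_mm3
  keep_ids <- report$component[report$kept]
  filtered <- array(as.integer(lc$labels %in% keep_ids & lc$labels > 0L),
                    dim = dim(lc$labels))
  out <- if (inherits(mask, "mask_volume"))
    mask_volume(filtered, spacing = mask$spacing)
  else filtered
  list(mask = out, report = report)
}
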
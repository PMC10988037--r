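# ---- multi-resolution deep supervision --------------------------------------
#
# Three supervised paths: decoder logits at full, 1/2 and 1/4 resolution
# (the 1/8 bottleneck level carries no head). The logit pyramid is fused
# stepwise by trilinear upsampling and element-wise addition; each path is
# additionally trained against a label volume downsampled to its own
# resolution, with unit loss weights:
#   L_total = L_all + sum_{d=1..3} L_d

#' Dimensionality-reduction head (1x1x1 convolution to class logits)
#'
#' @param features decoder feature node or array (nx, ny, nz, C)
#' @param w head weights (1, 1, 1, C, n_classes)
#' @param b head bias (n_classes)
#' @return logits node, spatial shape preserved
#' @export
reduce_head <- function(features, w, b) {
  if (!inherits(w, "ag_node")) w <- ag_constant(w)
  if (!inherits(b, "ag_node")) b <- ag_constant(b)
  op_conv3d(features, w, b)
}

#' Fuse the deep-supervision logit pyramid
#'
#' Upsamples the 1/4-resolution logits to 1/2 resolution (trilinear), merges
#' with the 1/2-resolution logits, upsamples the result to full resolution
#' and merges with the full-resolution logits. The default merge is
#' element-wise addition; `"concat"` concatenates channels and reduces with a
#' learned 1x1x1 convolution (requires `model`).
#'
#' @param paths list with logits `full`, `half`, `quarter` (nodes or arrays)
#' @param merge `"add"` or `"concat"`
#' @param model `vnet3d` model providing the concat-reduction weights
#' @return full-resolution fused logits node
#' @export
fuse_pyramid <- function(paths, merge = c("add", "concat"), model = NULL) {
  merge <- match.arg(merge)
  as_node <- function(x) if (inherits(x, "ag_node")) x else ag_constant(x)
  q <- as_node(paths$quarter); hf <- as_node(paths$half); fl <- as_node(paths$full)
  if (!all(nn_spatial(ag_value(q)) * 2L == nn_spatial(ag_value(hf))) ||
      !all(nn_spatial(ag_value(hf)) * 2L == nn_spatial(ag_value(fl))))
    stop("path resolutions must be full, 1/2 and 1/4 of the image grid")
  merge_fn <- function(a, b, which) {
    if (merge == "add") return(op_add(a, b))
    if (is.null(model)) stop("concat fusion requires the model's 1x1x1 reducers")
    p <- model$params
    op_conv3d(op_concat(a, b), p[[sprintf("fuse.%s.w", which)]],
              p[[sprintf("fuse.%s.b", which)]])
  }
  m <- merge_fn(op_upsample2(q), hf, "half")
  merge_fn(op_upsample2(m), fl, "full")
}

#' Downsample a binary label volume to a supervision resolution
#'
#' Trilinear downsampling of the binary field (for integer factors this is
#' the average of the two central voxels per axis, i.e. the 2x2x2 block mean
#' at factor 2) followed by thresholding at 0.5; ties (exactly 0.5) are
#' assigned to the foreground to protect thin vessels.
#'
#' @param mask binary 3-D array or [mask_volume()]
#' @param factor downsampling factor, 2 or 4
#' @return downsampled binary object of the same kind
#' @export
downsample_labels <- function(mask, factor) {
  if (!factor %in% c(2L, 4L)) stop("factor must be 2 or 4")
  vol <- inherits(mask, "mask_volume")
  arr <- if (vol) mask$voxels else mask
  d <- dim(arr)
  if (any(d %% factor != 0L))
    stop("shape ", paste(d, collapse = "x"), " not divisible by ", factor)
  f <- as.integer(factor)
  lo <- f %/% 2L
  avg_axis <- function(a, axis) {
    n <- dim(a)[axis]
    i0 <- seq(lo, n, by = f)
    i1 <- i0 + 1L
    switch(axis,
           (a[i0, , , drop = FALSE] + a[i1, , , drop = FALSE]) / 2,
           (a[, i0, , drop = FALSE] + a[, i1, , drop = FALSE]) / 2,
           (a[, , i0, drop = FALSE] + a[, , i1, drop = FALSE]) / 2)
  }
  sm <- avg_axis(avg_axis(avg_axis(arr * 1.0, 1L), 2L), 3L)
  out <- array(as.integer(sm >= 0.5), dim = dim(sm))
  if (vol) mask_volume(out, spacing = mask$spacing * f) else out
}

#' Total deep-supervision loss
#'
#' `L_total = L_all + L_full + L_half + L_quarter` with unit weights:
#' the fused prediction against the full-resolution labels plus each
#' supervised path against labels downsampled to its resolution.
#'
#' @param outputs result of [vnet_forward()]
#' @param mask binary ground-truth array or [mask_volume()] on the image grid
#' @param loss_fn differentiable loss closure from [make_loss()]
#' @param paths_enabled set `FALSE` to train on the fused loss alone
#' @return list with `total` (scalar graph node) and `terms` (named numeric
#'   breakdown: all, full, half, quarter)
#' @export
supervision_total_loss <- function(outputs, mask, loss_fn,
                                   paths_enabled = TRUE) {
  g_full <- if (inherits(mask, "mask_volume")) mask$voxels else mask
  for (nm in c("full", "half", "quarter"))
    if (is.null(outputs$paths[[nm]])) stop("missing supervised path: ", nm)
  l_all <- op_seg_loss(outputs$probs, g_full, loss_fn)
  if (!paths_enabled)
    return(list(total = l_all,
                terms = c(all = l_all$value, full = NA, half = NA,
                          quarter = NA)))
  g_half <- downsample_labels(g_full, 2L)
  g_quarter <- downsample_labels(g_full, 4L)
  l_f <- op_seg_loss(op_softmax(outputs$paths$full), g_full, loss_fn)
  l_h <- op_seg_loss(op_softmax(outputs$paths$half), g_half, loss_fn)
  l_q <- op_seg_loss(op_softmax(outputs$paths$quarter), g_quarter, loss_fn)
  total <- op_add(op_add(l_all, l_f), op_add(l_h, l_q))
  list(total = total,
       terms = c(all = l_all$value, full = l_f$value, half = l_h$value,
                 quarter = l_q$value))
}
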
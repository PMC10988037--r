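# ---- overlap metrics --------------------------------------------------------
#
# All four metrics derive from voxel confusion counts:
#   Dice        = 2TP / (2TP + FP + FN)
#   Accuracy    = (TP + TN) / (TP + TN + FP + FN)
#   Sensitivity = TP / (TP + FN)
#   Specificity = TN / (TN + FP)
# A zero denominator yields NA (an explicit "undefined" marker), never 0 and
# never an error; the empty-vs-empty convention is configurable because
# clinical reports differ on it.

#' Voxel confusion counts between predicted and reference masks
#'
#' @param pred predicted [mask_volume()] or binary array
#' @param truth reference [mask_volume()] or binary array, same grid
#' @return object of class `confusion_counts` (list TP, TN, FP, FN)
#' @export
confusion <- function(pred, truth) {
  p <- if (inherits(pred, "mask_volume")) pred$voxels else pred
  g <- if (inherits(truth, "mask_volume")) truth$voxels else truth
  if (!identical(dim(p), dim(g)))
    stop("prediction and truth are on different grids")
  if (!all(p %in% c(0L, 1L)) || !all(g %in% c(0L, 1L)))
    stop("masks must be binary")
  tp <- sum(p == 1L & g == 1L)
  tn <- sum(p == 0L & g == 0L)
  fp <- sum(p == 1L & g == 0L)
  fn <- sum(p == 0L & g == 1L)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

.safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Dice coefficient from confusion counts
#' @param counts a [confusion()] result
#' @return scalar in \[0, 1\], or NA if undefined (no foreground anywhere)
#' @export
dice <- function(counts) .safe_ratio(2 * counts$TP,
                                     2 * counts$TP + counts$FP + counts$FN)

#' Voxel accuracy from confusion counts
#' @inheritParams dice
#' @return scalar in \[0, 1\], or NA for empty input
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  .safe_ratio(counts$TP + counts$TN, tot)
}

#' Sensitivity (recall of the vessel class) from confusion counts
#' @inheritParams dice
#' @return scalar in \[0, 1\], or NA if the truth has no foreground
#' @export
sensitivity <- function(counts) .safe_ratio(counts$TP, counts$TP + counts$FN)

#' Specificity (recall of the background class) from confusion counts
#' @inheritParams dice
#' @return scalar in \[0, 1\], or NA if the truth has no background
#' @export
specificity <- function(counts) .safe_ratio(counts$TN, counts$TN + counts$FP)

#' Dice computed directly as overlap of two masks
#'
#' `2 |P intersect G| / (|P| + |G|)`: an independent route that must agree
#' exactly with [dice()] on confusion counts.
#'
#' @inheritParams confusion
#' @return scalar in \[0, 1\], or NA when both masks are empty
#' @export
dice_overlap_crosscheck <- function(pred, truth) {
  p <- if (inherits(pred, "mask_volume")) pred$voxels else pred
  g <- if (inherits(truth, "mask_volume")) truth$voxels else truth
  if (!identical(dim(p), dim(g)))
    stop("prediction and truth are on different grids")
  den <- sum(p) + sum(g)
  .safe_ratio(2 * sum(p * g), den)
}

#' Full metrics report for one volume
#'
#' @inheritParams confusion
#' @param empty_convention value reported when both masks are empty:
#'   `"undefined"` (NA, default) or `"one"`
#' @return data.frame with dice, accuracy, sensitivity, specificity and the
#'   underlying counts
#' @export
metrics_report <- function(pred, truth,
                           empty_convention = c("undefined", "one")) {
  empty_convention <- match.arg(empty_convention)
  cc <- confusion(pred, truth)
  d <- dice(cc)
  if (is.na(d) && empty_convention == "one") d <- 1
  data.frame(dice = d, accuracy = accuracy(cc),
             sensitivity = sensitivity(cc), specificity = specificity(cc),
             TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN)
}

#' Aggregate per-fold metrics as mean and sample standard deviation
#'
#' @param folds data.frame (or list of data.frames/rows) of per-fold metric
#'   values; needs at least 2 folds
#' @return data.frame with one row per metric: mean and sd (n-1 denominator)
#' @export
aggregate_folds <- function(folds) {
  if (is.list(folds) && !is.data.frame(folds))
    folds <- do.call(rbind, lapply(folds, as.data.frame))
  if (is.null(folds) || nrow(folds) < 2L)
    stop("fold aggregation requires at least 2 folds")
  metric_cols <- intersect(c("dice", "accuracy", "sensitivity", "specificity"),
                           names(folds))
  do.call(rbind, lapply(metric_cols, function(m) {
    v <- folds[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE))
  }))
}
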
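# ---- synthetic vascular phantoms --------------------------------------------
#
# Phantoms emulate the statistical structure of hepatic-vessel CT: a bright
# branching tubular tree occupying ~0.5-2% of the voxels inside a noisy
# parenchyma background, with HU-scaled intensities. The intensity model is
# Gaussian, not CT physics: the phantoms exist to exercise segmentation
# machinery with known ground truth, not to simulate scanners.

#' Phantom generation configuration
#'
#' Defaults generate a 64^3 volume at 1 mm spacing whose vessel tree occupies
#' about 1% of the voxels, with parenchyma at 80 HU, vessels ~100 HU brighter
#' (both inside the 0-400 HU liver window) and 15 HU Gaussian noise.
#'
#' @param shape voxel counts per axis (at least 16 each)
#' @param spacing voxel spacing per axis in mm
#' @param n_branch_levels branching generations (1 = root only)
#' @param root_radius root-segment radius in mm
#' @param radius_taper per-generation radius factor in (0, 1)
#' @param vessel_contrast vessel-minus-background mean intensity (HU)
#' @param background_mean parenchyma mean intensity (HU)
#' @param noise_sigma Gaussian noise standard deviation (HU)
#' @param target_foreground_fraction desired vessel voxel fraction, in (0, 0.05]
#' @param rng_seed integer seed
#' @return a `phantom_config` list
#' @export
phantom_config <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                           n_branch_levels = 4L, root_radius = 3,
                           radius_taper = 0.7, vessel_contrast = 100,
                           background_mean = 80, noise_sigma = 15,
                           target_foreground_fraction = 0.01,
                           rng_seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 16L)) stop("shape must be at least 16 voxels per axis")
  if (root_radius <= 0) stop("root_radius must be positive")
  if (radius_taper <= 0 || radius_taper >= 1)
    stop("radius_taper must lie in (0, 1)")
  if (target_foreground_fraction <= 0 || target_foreground_fraction > 0.05)
    stop("target_foreground_fraction must lie in (0, 0.05]")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (n_branch_levels < 1L) stop("n_branch_levels must be >= 1")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 n_branch_levels = as.integer(n_branch_levels),
                 root_radius = root_radius, radius_taper = radius_taper,
                 vessel_contrast = vessel_contrast,
                 background_mean = background_mean, noise_sigma = noise_sigma,
                 target_foreground_fraction = target_foreground_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

# rotate unit vector `dir` away from itself by `angle`, around a random
# azimuth; returns a unit vector
.perturb_direction <- function(dir, angle, azimuth) {
  # orthonormal basis around dir
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  w <- cos(angle) * dir + sin(angle) * (cos(azimuth) * u + sin(azimuth) * v)
  w / sqrt(sum(w^2))
}

#' Grow a branching vessel tree
#'
#' Binary branching: each segment spawns two children whose directions are
#' the parent direction tilted by a random polar angle (20-45 degrees) at a
#' random azimuth. Radii taper geometrically by `radius_taper` per
#' generation; segment lengths shrink by 0.7 per generation. Child segments
#' start at the parent's endpoint (on its axis); endpoints are clamped to the
#' volume bounds. Deterministic for a fixed `rng_seed`.
#'
#' @param config a [phantom_config()]
#' @return object of class `vessel_tree`: a data.frame of segments with
#'   columns x0..z1 (mm), radius (mm), level, parent
#' @export
grow_vessel_tree <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$rng_seed)
  extent <- config$shape * config$spacing
  clamp <- function(p) pmin(pmax(p, 0.02 * extent), 0.98 * extent)
  root_len <- 0.45 * min(extent)
  dir0 <- .perturb_direction(c(0, 0, 1), stats::runif(1, 0, 0.2),
                             stats::runif(1, 0, 2 * pi))
  start0 <- c(extent[1] * stats::runif(1, 0.4, 0.6),
              extent[2] * stats::runif(1, 0.4, 0.6),
              extent[3] * 0.06)
  rows <- list()
  add_row <- function(p0, p1, radius, level, parent) {
    rows[[length(rows) + 1L]] <<- data.frame(
      x0 = p0[1], y0 = p0[2], z0 = p0[3],
      x1 = p1[1], y1 = p1[2], z1 = p1[3],
      radius = radius, level = level, parent = parent)
  }
  end0 <- clamp(start0 + dir0 * root_len)
  add_row(clamp(start0), end0, config$root_radius, 1L, 0L)
  frontier <- list(list(id = 1L, end = end0,
                        dir = (end0 - clamp(start0)) /
                          sqrt(sum((end0 - clamp(start0))^2)),
                        radius = config$root_radius, len = root_len))
  if (config$n_branch_levels > 1L) {
    for (lev in 2:config$n_branch_levels) {
      nxt <- list()
      for (node in frontier) {
        for (child in 1:2) {
          ang <- stats::runif(1, 20, 45) * pi / 180
          azi <- stats::runif(1, 0, 2 * pi)
          d <- .perturb_direction(node$dir, ang, azi)
          len <- node$len * 0.7
          rad <- node$radius * config$radius_taper
          p1 <- clamp(node$end + d * len)
          add_row(node$end, p1, rad, lev, node$id)
          id <- length(rows)
          seg_vec <- p1 - node$end
          seg_len <- sqrt(sum(seg_vec^2))
          nd <- if (seg_len > 0) seg_vec / seg_len else node$dir
          nxt[[length(nxt) + 1L]] <- list(id = id, end = p1, dir = nd,
                                          radius = rad, len = len)
        }
      }
      frontier <- nxt
    }
  }
  segs <- do.call(rbind, rows)
  structure(list(segments = segs, shape = config$shape,
                 spacing = config$spacing), class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("Vessel tree: %d segments, %d levels, radii %.2f-%.2f mm\n",
              nrow(x$segments), max(x$segments$level),
              min(x$segments$radius), max(x$segments$radius)))
  invisible(x)
}

#' Rasterize a vessel tree onto a voxel grid
#'
#' A voxel is foreground iff the distance from its center (in mm) to the
#' nearest segment axis is at most that segment's radius: segments are
#' capsules (tubes with hemispherical caps). Voxel centers sit at
#' `(index + 0.5) * spacing`.
#'
#' @param tree a `vessel_tree` (or anything with a `segments` data.frame)
#' @param shape voxel counts per axis
#' @param spacing voxel spacing per axis (mm)
#' @return a [mask_volume()]
#' @export
rasterize_tree <- function(tree, shape = tree$shape, spacing = tree$spacing) {
  segs <- tree$segments
  shape <- as.integer(shape)
  if (is.null(segs) || nrow(segs) == 0L) {
    warning("empty vessel tree: returning an all-zero mask")
    return(mask_volume(array(0L, dim = shape), spacing = spacing))
  }
  m <- as.matrix(segs[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius")])
  vox <- cc_rasterize(m, shape, as.numeric(spacing))
  dim(vox) <- shape
  mask_volume(vox, spacing = spacing)
}

#' Render a CT phantom from a vessel mask
#'
#' Background voxels are drawn from Normal(background_mean, noise_sigma) and
#' vessel voxels from Normal(background_mean + vessel_contrast, noise_sigma).
#'
#' @param mask a [mask_volume()]
#' @param config a [phantom_config()] supplying the intensity model
#' @param seed optional seed; if `NULL` the current RNG stream is used
#' @return a [ct_volume()] on the mask's grid
#' @export
render_ct <- function(mask, config, seed = NULL) {
  stopifnot(inherits(mask, "mask_volume"))
  if (config$noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(mask$voxels)
  vox <- config$background_mean + config$vessel_contrast * mask$voxels +
    stats::rnorm(n, 0, config$noise_sigma)
  dim(vox) <- dim(mask$voxels)
  ct_volume(vox, spacing = mask$spacing)
}

#' Generate a dataset of paired phantom CT images and vessel masks
#'
#' Per-volume seeds are derived as `master_seed + volume index`, keeping the
#' dataset reproducible yet the volumes distinct. Each mask's foreground
#' fraction must fall within \[0.25x, 4x\] of the configured target; trees
#' are regrown with perturbed seeds a bounded number of times before failing.
#'
#' @param config a [phantom_config()]
#' @param n_volumes number of phantoms (>= 1)
#' @param master_seed base seed; defaults to `config$rng_seed`
#' @param max_retries regrow attempts per volume
#' @return list of `list(image = ct_volume, label = mask_volume, seed)`
#' @export
make_dataset <- function(config, n_volumes, master_seed = config$rng_seed,
                         max_retries = 20L) {
  if (n_volumes < 1L) stop("n_volumes must be >= 1")
  lo <- 0.25 * config$target_foreground_fraction
  hi <- 4 * config$target_foreground_fraction
  out <- vector("list", n_volumes)
  for (v in seq_len(n_volumes)) {
    seed_v <- master_seed + v
    mask <- NULL
    for (attempt in 0:max_retries) {
      cfg_v <- config
      cfg_v$rng_seed <- as.integer(seed_v + attempt * 10000L)
      tree <- grow_vessel_tree(cfg_v)
      cand <- rasterize_tree(tree, config$shape, config$spacing)
      f <- foreground_fraction(cand)
      if (f >= lo && f <= hi) { mask <- cand; break }
    }
    if (is.null(mask))
      stop("could not reach a foreground fraction in [",
           signif(lo, 3), ", ", signif(hi, 3), "] after ", max_retries,
           " retries for volume ", v)
    image <- render_ct(mask, config, seed = seed_v + 500000L)
    out[[v]] <- list(image = image, label = mask, seed = seed_v)
  }
  out
}

#' Export a phantom dataset as paired NIfTI image/label files
#'
#' @param dataset result of [make_dataset()]
#' @param dir output directory (created if needed)
#' @return data.frame of written image/label paths, invisibly
#' @export
export_dataset_nifti <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset), function(i) {
    img <- file.path(dir, sprintf("phantom_%03d_image.nii.gz", i))
    lab <- file.path(dir, sprintf("phantom_%03d_label.nii.gz", i))
    write_volume_nifti(dataset[[i]]$image, img)
    write_volume_nifti(dataset[[i]]$label, lab)
    data.frame(image = img, label = lab)
  })
  invisible(do.call(rbind, rows))
}
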
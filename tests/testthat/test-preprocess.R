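test_that("HU clipping follows the 0-400 window and is idempotent", {
  v <- ct_volume(array(c(-50, 500, 200, 0, 400, 123.4), dim = c(6, 1, 1)))
  got <- clip_hu(v, c(0, 400))
  expect_equal(as.numeric(got$voxels), c(0, 400, 200, 0, 400, 123.4))
  expect_equal(clip_hu(got, c(0, 400))$voxels, got$voxels)

  inside <- ct_volume(array(runif(27, 10, 390), dim = c(3, 3, 3)))
  expect_equal(clip_hu(inside)$voxels, inside$voxels)
  expect_error(clip_hu(v, c(400, 0)), "low")
})

test_that("z-score normalization yields mean 0 / unit (population) variance", {
  set.seed(1)
  v <- ct_volume(array(rnorm(16^3, 100, 35), dim = c(16, 16, 16)))
  z <- normalize_zscore(v)
  expect_lt(abs(mean(z$voxels)), 1e-6)
  expect_lt(abs(mean(z$voxels^2) - 1), 1e-6)

  # two-voxel case pins down the 1/N variance convention
  two <- normalize_zscore(array(c(0, 2), dim = c(2, 1, 1)))
  expect_equal(as.numeric(two), c(-1, 1))

  # idempotence on already-standardized input
  z2 <- normalize_zscore(z)
  expect_lt(max(abs(z2$voxels - z$voxels)), 1e-6)

  expect_error(normalize_zscore(array(5, dim = c(1, 1, 1))), "one voxel")
  expect_error(normalize_zscore(array(5, dim = c(4, 4, 4))), "zero variance")
})

test_that("isotropic resampling maps shapes by spacing ratio", {
  set.seed(2)
  v <- ct_volume(array(rnorm(64 * 64 * 32), dim = c(64, 64, 32)),
                 spacing = c(1, 1, 2))
  out <- resample_isotropic(v, c(1, 1, 1))
  expect_equal(dim(out$voxels), c(64L, 64L, 64L))
  expect_equal(out$spacing, c(1, 1, 1))

  same <- resample_isotropic(ct_volume(v$voxels, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(dim(same$voxels), dim(v$voxels))
  expect_equal(same$voxels, v$voxels, tolerance = 1e-12)

  m <- mask_volume(array(as.integer(runif(64 * 64 * 32) < 0.3),
                         dim = c(64, 64, 32)), spacing = c(1, 1, 2))
  mo <- resample_isotropic(m, c(1, 1, 1))
  expect_equal(dim(mo$voxels), c(64L, 64L, 64L))
  expect_true(all(mo$voxels %in% c(0L, 1L)))

  zero <- mask_volume(array(0L, dim = c(16, 16, 16)), spacing = c(1.5, 1, 1))
  expect_equal(sum(resample_isotropic(zero, c(0.7, 0.7, 0.7))$voxels), 0)

  expect_error(resample_isotropic(v, c(0, 1, 1)), "positive")
})

test_that("liver ROI construction is a per-axis box dilation", {
  arr <- array(0L, dim = c(64, 64, 64))
  arr[32, 32, 32] <- 1L
  lab <- mask_volume(arr)
  roi <- build_liver_roi(lab, 20)
  expect_equal(sum(roi$voxels), 41^3)
  idx <- which(roi$voxels == 1L, arr.ind = TRUE)
  expect_equal(as.numeric(apply(idx, 2, min)), rep(12, 3))
  expect_equal(as.numeric(apply(idx, 2, max)), rep(52, 3))

  # clipped at borders
  arr2 <- array(0L, dim = c(24, 24, 24)); arr2[2, 2, 2] <- 1L
  roi2 <- build_liver_roi(mask_volume(arr2), 20)
  expect_equal(sum(roi2$voxels), 22^3)

  # spacing converts mm to voxels per axis
  lab3 <- mask_volume(arr, spacing = c(2, 1, 1))
  roi3 <- build_liver_roi(lab3, 20)
  idx3 <- which(roi3$voxels == 1L, arr.ind = TRUE)
  expect_equal(diff(range(idx3[, 1])) + 1, 21) # 10 voxels of 2 mm per side
  expect_equal(diff(range(idx3[, 2])) + 1, 41)

  expect_equal(build_liver_roi(lab, 0)$voxels, lab$voxels)
  expect_true(all(build_liver_roi(lab, 5)$voxels >= lab$voxels))
  expect_error(build_liver_roi(mask_volume(array(0L, dim = c(16, 16, 16)))),
               "empty")
})

test_that("ROI cropping records offsets and round-trips", {
  set.seed(3)
  v <- ct_volume(array(rnorm(64^3), dim = c(64, 64, 64)))
  full <- mask_volume(array(1L, dim = c(64, 64, 64)))
  cr <- crop_to_roi(v, full)
  expect_equal(cr$offset, c(0L, 0L, 0L))
  expect_equal(cr$volume$voxels, v$voxels)

  roi <- array(0L, dim = c(64, 64, 64))
  roi[28:37, 28:37, 28:37] <- 1L
  cr2 <- crop_to_roi(v, mask_volume(roi))
  expect_equal(dim(cr2$volume$voxels), c(10L, 10L, 10L))
  expect_equal(cr2$offset, c(27L, 27L, 27L))

  back <- uncrop_volume(cr2$volume, cr2$offset, c(64, 64, 64))
  expect_identical(back$voxels[28:37, 28:37, 28:37],
                   v$voxels[28:37, 28:37, 28:37])
  expect_error(crop_to_roi(v, mask_volume(array(0L, dim = c(64, 64, 64)))),
               "empty")
})

test_that("flip augmentation is joint, involutive and seeded", {
  set.seed(4)
  img <- array(rnorm(16^3), dim = c(16, 16, 16))
  lab <- array(as.integer(runif(16^3) < 0.1), dim = c(16, 16, 16))

  set.seed(11)
  a <- augment_flip(img, lab)
  set.seed(11)
  b <- augment_flip(img, lab)
  expect_identical(a$flipped, b$flipped)
  expect_identical(a$image, b$image)

  expect_equal(sum(a$label), sum(lab)) # permutation preserves counts
  # label moved with the image: foreground intensities are unchanged
  expect_equal(sort(a$image[a$label == 1]), sort(img[lab == 1]))

  # flipping twice along the same axes restores the original
  set.seed(12); f1 <- augment_flip(img, lab, prob = 1)
  set.seed(13); f2 <- augment_flip(f1$image, f1$label, prob = 1)
  expect_identical(f2$image, img)
  expect_identical(f2$label, lab)
})

test_that("the full preprocessing chain keeps grids aligned and finite", {
  cfg <- tiny_phantom(rng_seed = 21L)
  cfg$spacing <- c(1, 1, 2)
  mask <- rasterize_tree(grow_vessel_tree(cfg), cfg$shape, cfg$spacing)
  ct <- render_ct(mask, cfg, seed = 5)
  pp <- preprocess_volume(ct, mask)
  expect_equal(dim(pp$image$voxels), dim(pp$label$voxels))
  expect_equal(pp$image$spacing, pp$label$spacing)
  expect_equal(dim(pp$image$voxels), c(32L, 32L, 64L))
  expect_true(all(is.finite(pp$image$voxels)))
  expect_true(all(pp$label$voxels %in% c(0L, 1L)))
})
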
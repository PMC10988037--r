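test_that("vessel tree growth is seeded, tapers geometrically, respects bounds", {
  cfg <- phantom_config(rng_seed = 7L)
  t1 <- grow_vessel_tree(cfg)
  t2 <- grow_vessel_tree(cfg)
  expect_identical(t1$segments, t2$segments)

  t3 <- grow_vessel_tree(phantom_config(rng_seed = 8L))
  expect_false(identical(t1$segments, t3$segments))

  single <- grow_vessel_tree(phantom_config(n_branch_levels = 1L))
  expect_equal(nrow(single$segments), 1L)
  expect_equal(single$segments$level, 1L)

  cfg3 <- phantom_config(root_radius = 4, radius_taper = 0.7,
                         n_branch_levels = 3L)
  tree <- grow_vessel_tree(cfg3)
  lev3 <- tree$segments$radius[tree$segments$level == 3L]
  expect_true(length(lev3) > 0)
  expect_equal(lev3, rep(4 * 0.7^2, length(lev3)))

  # child radius never exceeds parent's; endpoints inside the volume
  segs <- tree$segments
  for (i in which(segs$parent > 0)) {
    expect_lte(segs$radius[i], segs$radius[segs$parent[i]])
  }
  extent <- cfg3$shape * cfg3$spacing
  expect_true(all(segs$x0 >= 0 & segs$x1 <= extent[1]))
  expect_true(all(segs$z0 >= 0 & segs$z1 <= extent[3]))
  expect_true(all(segs$radius > 0))
})

test_that("phantom config rejects invalid parameters", {
  expect_error(phantom_config(root_radius = 0), "root_radius")
  expect_error(phantom_config(shape = c(8, 64, 64)), "16")
  expect_error(phantom_config(radius_taper = 1.1), "radius_taper")
  expect_error(phantom_config(target_foreground_fraction = 0.2), "foreground")
})

test_that("rasterization matches the brute-force distance oracle exactly", {
  shape <- c(20L, 18L, 16L)
  set.seed(33)
  tree <- single_tube_tree(c(4, 9, 3), c(16, 9, 13), 2.5, shape)
  tree$segments <- rbind(tree$segments,
                         data.frame(x0 = 10, y0 = 2, z0 = 8, x1 = 12,
                                    y1 = 16, z1 = 8, radius = 1.6,
                                    level = 2L, parent = 1L))
  for (spacing in list(c(1, 1, 1), c(1.3, 0.8, 1.1))) {
    got <- rasterize_tree(tree, shape, spacing)
    want <- rasterize_oracle(tree, shape, spacing)
    expect_identical(got$voxels, want)
  }
})

test_that("empty tree rasterizes to an all-zero mask with a warning", {
  tree <- structure(list(segments = NULL, shape = c(16L, 16L, 16L),
                         spacing = c(1, 1, 1)), class = "vessel_tree")
  expect_warning(m <- rasterize_tree(tree), "empty")
  expect_equal(sum(m$voxels), 0)
})

test_that("tube voxel count tracks the analytic capsule volume", {
  # radius 3 mm, length 40 mm, 1 mm spacing, axis through voxel centers;
  # hemispherical caps add (4/3) pi r^3 to the cylinder volume
  shape <- c(48L, 48L, 48L)
  tree <- single_tube_tree(c(24.5, 24.5, 4), c(24.5, 24.5, 44), 3, shape)
  n <- sum(rasterize_tree(tree)$voxels)
  cyl <- pi * 3^2 * 40
  caps <- 4 / 3 * pi * 3^3
  expect_lt(abs(n - (cyl + caps)) / (cyl + caps), 0.10)

  # doubling the spacing along the tube axis halves the count
  n2 <- sum(rasterize_tree(tree, c(48L, 48L, 24L), c(1, 1, 2))$voxels)
  expect_lt(abs(n2 - n / 2) / (n / 2), 0.1)
})

test_that("foreground fraction is non-decreasing in root radius", {
  fracs <- vapply(c(1.5, 2, 2.5, 3, 3.5), function(r) {
    cfg <- phantom_config(root_radius = r, rng_seed = 42L)
    foreground_fraction(rasterize_tree(grow_vessel_tree(cfg)))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("CT rendering follows the two-Gaussian intensity model", {
  cfg <- tiny_phantom(rng_seed = 3L)
  mask <- rasterize_tree(grow_vessel_tree(cfg))

  noiseless <- render_ct(mask, phantom_config(noise_sigma = 0), seed = 1)
  expect_setequal(unique(as.numeric(noiseless$voxels)),
                  c(80, 180))

  expect_error(render_ct(mask, mod_cfg(cfg, noise_sigma = -1)), "noise_sigma")

  ct <- render_ct(mask, cfg, seed = 10)
  inside <- ct$voxels[mask$voxels == 1]
  outside <- ct$voxels[mask$voxels == 0]
  tol <- 3 * cfg$noise_sigma / sqrt(min(length(inside), length(outside)))
  expect_lt(abs((mean(inside) - mean(outside)) - cfg$vessel_contrast), tol)

  # all-zero mask: nothing near the vessel mean beyond noise expectation
  zero <- mask_volume(array(0L, dim = c(32, 32, 32)))
  bg <- render_ct(zero, cfg, seed = 2)
  expect_lt(max(bg$voxels), cfg$background_mean + cfg$vessel_contrast)
})

test_that("make_dataset is reproducible and honors the foreground band", {
  cfg <- tiny_phantom()
  ds1 <- make_dataset(cfg, 3, master_seed = 50L)
  ds2 <- make_dataset(cfg, 3, master_seed = 50L)
  expect_identical(lapply(ds1, function(d) d$label$voxels),
                   lapply(ds2, function(d) d$label$voxels))
  masks <- lapply(ds1, function(d) d$label$voxels)
  expect_false(identical(masks[[1]], masks[[2]]))

  target <- cfg$target_foreground_fraction
  for (d in ds1) {
    f <- foreground_fraction(d$label)
    expect_gte(f, 0.25 * target)
    expect_lte(f, 4 * target)
  }
  expect_error(make_dataset(cfg, 0), "n_volumes")
})

test_that("phantom volumes round-trip through NIfTI bit-exactly", {
  cfg <- tiny_phantom(rng_seed = 9L)
  mask <- rasterize_tree(grow_vessel_tree(cfg))
  ct <- render_ct(mask, cfg, seed = 4)
  tmp <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ct, tmp)
  back <- read_ct_nifti(tmp)
  expect_identical(back$voxels, ct$voxels)
  expect_equal(back$spacing, ct$spacing)

  ct2 <- ct_volume(ct$voxels, spacing = c(0.75, 0.75, 2.5))
  write_volume_nifti(ct2, tmp)
  expect_equal(read_ct_nifti(tmp)$spacing, c(0.75, 0.75, 2.5))

  tmp2 <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(mask, tmp2)
  mback <- read_mask_nifti(tmp2)
  expect_identical(mback$voxels, mask$voxels)
  unlink(c(tmp, tmp2))
})
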
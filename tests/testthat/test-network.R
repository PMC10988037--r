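test_that("effective kernel size follows kd = k + (k-1)(r-1)", {
  expect_equal(effective_kernel_size(3, 3), 7)
  expect_equal(effective_kernel_size(3, 1), 3)
  expect_equal(effective_kernel_size(3, 5), 11)
  expect_equal(effective_kernel_size(3, 4), 9)
  expect_equal(effective_kernel_size(5, 2), 9)
  expect_error(effective_kernel_size(3, 0), "r must be")
})

test_that("network config enforces the architecture invariants", {
  expect_error(network_config(conv_kernel = 4), "odd")
  expect_error(network_config(pyramid_kernels = c(3, 4, 7)), "odd")
  expect_error(network_config(dilation_rates = c(0, 4, 5)), "dilation")
  cfg <- network_config()
  expect_equal(cfg$n_levels, 4L)
  expect_equal(cfg$dilation_rates, c(3L, 4L, 5L))
  expect_equal(cfg$pyramid_kernels, c(3L, 5L, 7L))
  expect_equal(cfg$dropout_p, 0.5)
})

test_that("the built model matches the published architecture counts", {
  model <- vnet_build(network_config(base_channels = 4L), seed = 1)
  lt <- vnet_layer_table(model)

  dil <- lt[lt$kind == "dilated", ]
  expect_equal(nrow(dil), 3L)
  expect_equal(sort(dil$dilation), c(3L, 4L, 5L))
  expect_true(all(dil$level == 4L))

  expect_equal(sum(lt$kind == "down"), 3L)
  expect_equal(sum(lt$kind == "up"), 3L)

  # channel schedule base*(1,2,4,8) down the encoder
  expect_equal(model$channels, 4L * c(1L, 2L, 4L, 8L))
  downs <- lt[lt$kind == "down", ]
  expect_equal(downs$cin, 4L * c(1L, 2L, 4L))
  expect_equal(downs$cout, 4L * c(2L, 4L, 8L))
  ups <- lt[lt$kind == "up", ]
  expect_equal(sort(ups$cout), 4L * c(1L, 2L, 4L))

  # three supervision heads, none on the deepest (1/8) level
  heads <- lt[lt$kind == "head", ]
  expect_equal(nrow(heads), 3L)
  expect_true(all(heads$level %in% 1:3))
  expect_true(all(heads$kernel == 1L))
})

test_that("model building is deterministic per seed", {
  m1 <- vnet_build(tiny_network(), seed = 5)
  m2 <- vnet_build(tiny_network(), seed = 5)
  expect_equal(vnet_param_count(m1), vnet_param_count(m2))
  expect_identical(lapply(m1$params, function(p) p$value),
                   lapply(m2$params, function(p) p$value))
  m3 <- vnet_build(tiny_network(), seed = 6)
  expect_false(identical(m1$params$in.w$value, m3$params$in.w$value))
})

test_that("removing pyramid blocks changes the parameter count by their total", {
  with_p <- vnet_build(tiny_network(use_pyramid = TRUE), seed = 1)
  without <- vnet_build(tiny_network(use_pyramid = FALSE), seed = 1)
  lt <- vnet_layer_table(with_p)
  pyr <- lt[lt$kind == "pyramid", ]
  # weights + biases (+ PReLU slopes on the three branch convs)
  pyr_params <- sum(pyr$kernel^3 * pyr$cin * pyr$cout) + sum(pyr$cout) +
    sum(pyr$cout[pyr$kernel > 1L])
  expect_equal(vnet_param_count(with_p) - vnet_param_count(without),
               pyr_params)
})

test_that("pyramid block is shape-preserving with an exact residual identity", {
  set.seed(20)
  ve <- asNamespace("vesselvnet")
  C <- 3L
  dims <- c(10L, 8L, 6L)
  x <- array(rnorm(prod(dims) * C), dim = c(dims, C))
  mk_w <- function(k, zero = FALSE) {
    w <- if (zero) array(0, dim = c(k, k, k, C, C))
    else array(rnorm(k^3 * C * C, sd = 0.1), dim = c(k, k, k, C, C))
    w
  }
  weights <- list()
  for (k in c(3, 5, 7)) {
    weights[[paste0("k", k, ".w")]] <- ve$ag_constant(mk_w(k))
    weights[[paste0("k", k, ".b")]] <- ve$ag_constant(numeric(C))
    weights[[paste0("k", k, ".a")]] <- ve$ag_constant(rep(0.25, C))
  }
  weights[["post.w"]] <- ve$ag_constant(array(rnorm(C * C), dim = c(1, 1, 1, C, C)))
  weights[["post.b"]] <- ve$ag_constant(numeric(C))

  out <- pyramid_block_forward(x, weights)
  expect_equal(dim(out$value), dim(x))

  # all branch weights zero + post conv bypassed -> exact identity
  zw <- weights
  for (k in c(3, 5, 7)) zw[[paste0("k", k, ".w")]] <- ve$ag_constant(mk_w(k, TRUE))
  ident <- pyramid_block_forward(x, zw, bypass_post = TRUE)
  expect_identical(ident$value, x)

  # channel mismatch rejected
  bad <- array(rnorm(prod(dims) * 2), dim = c(dims, 2L))
  expect_error(pyramid_block_forward(bad, weights), "channel mismatch")
})

test_that("gradients reach all three pyramid branches", {
  set.seed(21)
  ve <- asNamespace("vesselvnet")
  C <- 2L
  dims <- c(8L, 8L, 8L)
  x <- ve$ag_constant(array(rnorm(prod(dims) * C), dim = c(dims, C)))
  weights <- list()
  for (k in c(3, 5, 7)) {
    weights[[paste0("k", k, ".w")]] <-
      ve$ag_param(array(rnorm(k^3 * C * C, sd = 0.1), dim = c(k, k, k, C, C)))
    weights[[paste0("k", k, ".b")]] <- ve$ag_param(numeric(C))
    weights[[paste0("k", k, ".a")]] <- ve$ag_param(rep(0.25, C))
  }
  weights[["post.w"]] <- ve$ag_param(array(rnorm(C * C), dim = c(1, 1, 1, C, C)))
  weights[["post.b"]] <- ve$ag_param(numeric(C))
  out <- pyramid_block_forward(x, weights)
  ve$ag_backward(ag_sum_node(out))
  for (k in c(3, 5, 7)) {
    g <- weights[[paste0("k", k, ".w")]]$grad
    expect_false(is.null(g))
    expect_gt(max(abs(g)), 0)
  }
})

test_that("forward pass preserves shape and normalizes per voxel", {
  model <- vnet_build(tiny_network(), seed = 2)
  for (sz in c(16L, 24L)) {
    img <- array(rnorm(sz^3), dim = rep(sz, 3))
    out <- vnet_forward(model, img)
    expect_equal(dim(out$fused$value), c(rep(sz, 3), 2L))
    sums <- apply(out$probs$value, 1:3, sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
    # auxiliary paths at 1/2 and 1/4 resolution
    expect_equal(dim(out$paths$half$value)[1:3], rep(sz %/% 2L, 3))
    expect_equal(dim(out$paths$quarter$value)[1:3], rep(sz %/% 4L, 3))
  }
  expect_error(vnet_forward(model, array(0, dim = c(50, 50, 50))),
               "divisible by 8")
  # 48 is divisible by 8: accepted (shape checked lazily via a tiny volume)
  expect_silent(vnet_forward(vnet_build(tiny_network(), seed = 2),
                             array(0, dim = c(8, 8, 8))))
})

test_that("receptive-field probe reproduces the dilated extents", {
  expect_equal(receptive_field_probe(list(list(k = 3, r = 3))), 7L)
  expect_equal(receptive_field_probe(list(list(k = 3, r = 4))), 9L)
  expect_equal(receptive_field_probe(list(list(k = 3, r = 5))), 11L)
  expect_equal(receptive_field_probe(list(list(k = 3, r = 1))), 3L)
  # stacked rates 3,4,5: extents compose as 7 + 9 + 11 - 2 = 25
  stack <- dilated_stage_spec(vnet_build(tiny_network(), seed = 1))
  expect_equal(receptive_field_probe(stack), 25L)
})

test_that("training reduces the loss on a fixed phantom batch", {
  set.seed(30)
  cfg <- phantom_config(shape = c(16L, 16L, 16L), n_branch_levels = 2L,
                        root_radius = 1.8, noise_sigma = 10,
                        target_foreground_fraction = 0.03, rng_seed = 12L)
  ds <- preprocess_dataset(make_dataset(cfg, 1, master_seed = 31L))
  # one 16^3 volume, patch = whole volume, no augmentation: a fixed batch
  tc <- train_config(max_steps = 20L, patch_size = 16L, rng_seed = 3L,
                     dropout = 0, val_every = 50L, learning_rate = 1e-3,
                     augment = FALSE)
  run <- train(ds, tc, tiny_network())
  hist <- run$manifest$loss_history
  expect_lt(mean(tail(hist$total, 3)), hist$total[1])
})
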
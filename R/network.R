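# ---- improved 3-D V-Net -----------------------------------------------------
#
# Four-level residual encoder-decoder. Encoder levels 1-3 use 3x3x3 conv
# stages with stride-2 2x2x2 downsampling; level 4 replaces downsampling with
# three dilated 3x3x3 convolutions (rates 3, 4, 5). The decoder mirrors with
# stride-2 transposed convolutions halving channels. Every skip connection
# passes through a pyramidal convolution block (parallel 3/5/7 kernels +
# residual shortcut + trailing 1x1x1 conv). Deep-supervision heads sit on the
# decoder at full, 1/2 and 1/4 resolution; their logits are fused by
# trilinear upsampling and addition.

#' Network hyperparameter configuration
#'
#' @param in_channels input image channels (CT: 1)
#' @param n_classes output classes (foreground/background: 2)
#' @param base_channels channels at full resolution; doubled per level
#' @param conv_kernel spatial kernel of the residual-stage convolutions
#' @param dilation_rates dilation rates of the three level-4 convolutions
#' @param pyramid_kernels kernel sizes of the pyramid-block branches
#' @param dropout_p dropout probability at the end of each residual stage
#' @param use_pyramid set `FALSE` to replace pyramid blocks with identity
#'   (ablation switch)
#' @param dilated_arrangement `"series"` (default) or `"parallel"` wiring of
#'   the three dilated convolutions
#' @param fusion_merge `"add"` (default) or `"concat"` merge of the
#'   deep-supervision logit pyramid
#' @return a `vnet_config` list
#' @export
network_config <- function(in_channels = 1L, n_classes = 2L,
                           base_channels = 16L, conv_kernel = 3L,
                           dilation_rates = c(3L, 4L, 5L),
                           pyramid_kernels = c(3L, 5L, 7L),
                           dropout_p = 0.5, use_pyramid = TRUE,
                           dilated_arrangement = c("series", "parallel"),
                           fusion_merge = c("add", "concat")) {
  dilated_arrangement <- match.arg(dilated_arrangement)
  fusion_merge <- match.arg(fusion_merge)
  if (conv_kernel %% 2L != 1L || any(pyramid_kernels %% 2L != 1L))
    stop("all convolution kernels must be odd")
  if (any(dilation_rates < 1L)) stop("dilation rates must be >= 1")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  structure(list(
    in_channels = as.integer(in_channels),
    n_classes = as.integer(n_classes),
    base_channels = as.integer(base_channels),
    n_levels = 4L,
    conv_kernel = as.integer(conv_kernel),
    dilation_rates = as.integer(dilation_rates),
    pyramid_kernels = as.integer(pyramid_kernels),
    dropout_p = dropout_p,
    use_pyramid = isTRUE(use_pyramid),
    dilated_arrangement = dilated_arrangement,
    fusion_merge = fusion_merge,
    stage_depths = c(1L, 2L, 3L, 3L)
  ), class = "vnet_config")
}

#' Effective kernel size of a dilated convolution
#'
#' `kd = k + (k - 1)(r - 1)`: the spatial span of a kernel of size `k`
#' whose taps are spaced `r` voxels apart.
#'
#' @param k base kernel size (odd)
#' @param r dilation (expansion) rate, `>= 1`
#' @return effective kernel extent in voxels
#' @export
#' @examples
#' effective_kernel_size(3, 3) # 7
#' effective_kernel_size(3, 5) # 11
effective_kernel_size <- function(k, r) {
  if (any(r < 1)) stop("dilation rate r must be >= 1")
  k + (k - 1) * (r - 1)
}

# He-style initialization for a conv weight (k,k,k,cin,cout)
.init_conv <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  array(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(k, k, k, cin, cout))
}
.init_resample <- function(cin, cout) {
  fan_in <- 8 * cin
  array(stats::rnorm(8 * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(2, 2, 2, cin, cout))
}

#' Build the improved V-Net
#'
#' Instantiates all parameters (He-normal weights, zero biases, PReLU slopes
#' 0.25) and the layer registry used for introspection. Deterministic for a
#' fixed `seed`.
#'
#' @param config a [network_config()]
#' @param seed integer seed for weight initialization
#' @return object of class `vnet3d`
#' @export
vnet_build <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- config$base_channels
  ch <- B * c(1L, 2L, 4L, 8L)
  depths <- config$stage_depths
  params <- list()
  registry <- list()
  reg <- function(name, kind, k, dilation, cin, cout, level) {
    registry[[length(registry) + 1L]] <<- data.frame(
      name = name, kind = kind, kernel = k, dilation = dilation,
      cin = cin, cout = cout, level = level, stringsAsFactors = FALSE)
  }
  add_conv <- function(name, k, cin, cout, kind = "conv", dilation = 1L,
                       level = NA_integer_, prelu = TRUE) {
    params[[paste0(name, ".w")]] <<- ag_param(.init_conv(k, cin, cout))
    params[[paste0(name, ".b")]] <<- ag_param(numeric(cout))
    if (prelu) params[[paste0(name, ".a")]] <<- ag_param(rep(0.25, cout))
    reg(name, kind, k, dilation, cin, cout, level)
  }

  add_conv("in", config$conv_kernel, config$in_channels, ch[1], level = 1L)
  for (l in 1:3) {
    for (d in seq_len(depths[l]))
      add_conv(sprintf("enc%d.c%d", l, d), config$conv_kernel, ch[l], ch[l],
               level = l)
    params[[sprintf("down%d.w", l)]] <- ag_param(.init_resample(ch[l], ch[l + 1]))
    params[[sprintf("down%d.b", l)]] <- ag_param(numeric(ch[l + 1]))
    params[[sprintf("down%d.a", l)]] <- ag_param(rep(0.25, ch[l + 1]))
    reg(sprintf("down%d", l), "down", 2L, 1L, ch[l], ch[l + 1], l)
  }
  for (i in seq_along(config$dilation_rates))
    add_conv(sprintf("bott.c%d", i), config$conv_kernel, ch[4], ch[4],
             kind = "dilated", dilation = config$dilation_rates[i], level = 4L)
  for (l in 3:1) {
    params[[sprintf("up%d.w", l)]] <- ag_param(.init_resample(ch[l + 1], ch[l]))
    params[[sprintf("up%d.b", l)]] <- ag_param(numeric(ch[l]))
    params[[sprintf("up%d.a", l)]] <- ag_param(rep(0.25, ch[l]))
    reg(sprintf("up%d", l), "up", 2L, 1L, ch[l + 1], ch[l], l)
    if (config$use_pyramid) {
      for (pk in config$pyramid_kernels)
        add_conv(sprintf("pyr%d.k%d", l, pk), pk, ch[l], ch[l],
                 kind = "pyramid", level = l)
      add_conv(sprintf("pyr%d.post", l), 1L, ch[l], ch[l],
               kind = "pyramid", level = l, prelu = FALSE)
    }
    for (d in seq_len(depths[l]))
      add_conv(sprintf("dec%d.c%d", l, d), config$conv_kernel, ch[l], ch[l],
               level = l)
  }
  add_conv("head.full", 1L, ch[1], config$n_classes, kind = "head",
           level = 1L, prelu = FALSE)
  add_conv("head.half", 1L, ch[2], config$n_classes, kind = "head",
           level = 2L, prelu = FALSE)
  add_conv("head.quarter", 1L, ch[3], config$n_classes, kind = "head",
           level = 3L, prelu = FALSE)
  if (config$fusion_merge == "concat") {
    add_conv("fuse.half", 1L, 2L * config$n_classes, config$n_classes,
             kind = "fuse", level = 2L, prelu = FALSE)
    add_conv("fuse.full", 1L, 2L * config$n_classes, config$n_classes,
             kind = "fuse", level = 1L, prelu = FALSE)
  }

  structure(list(config = config, params = params,
                 layers = do.call(rbind, registry), channels = ch),
            class = "vnet3d")
}

#' Number of trainable parameters
#' @param model a `vnet3d` model
#' @return integer parameter count
#' @export
vnet_param_count <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' Layer registry of a model
#'
#' One row per convolution-like layer with its kind (`conv`, `dilated`,
#' `down`, `up`, `pyramid`, `head`, `fuse`), kernel size, dilation rate,
#' channel counts and resolution level.
#'
#' @param model a `vnet3d` model
#' @return data.frame
#' @export
vnet_layer_table <- function(model) model$layers

#' @export
print.vnet3d <- function(x, ...) {
  cfg <- x$config
  cat("Improved 3-D V-Net\n")
  cat(sprintf("  levels: %d, channel schedule: %s\n", cfg$n_levels,
              paste(x$channels, collapse = " -> ")))
  cat(sprintf("  dilated convolutions (level 4): rates %s\n",
              paste(cfg$dilation_rates, collapse = ", ")))
  cat(sprintf("  pyramid blocks on skips: %s (kernels %s)\n",
              ifelse(cfg$use_pyramid, "yes", "no (ablation)"),
              paste(cfg$pyramid_kernels, collapse = "/")))
  cat(sprintf("  dropout: %.2f, parameters: %d\n", cfg$dropout_p,
              vnet_param_count(x)))
  invisible(x)
}

# residual conv stage: h = x; depth convs with PReLU; output = h + x, dropout
.vnet_stage <- function(x, model, prefix, depth, dilations = NULL,
                        training = FALSE) {
  p <- model$params
  cfg <- model$config
  if (!is.null(dilations) && cfg$dilated_arrangement == "parallel") {
    branches <- lapply(seq_len(depth), function(d) {
      nm <- sprintf("%s.c%d", prefix, d)
      op_prelu(op_conv3d(x, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
                         dilation = dilations[d]), p[[paste0(nm, ".a")]])
    })
    h <- Reduce(op_add, branches)
  } else {
    h <- x
    for (d in seq_len(depth)) {
      nm <- sprintf("%s.c%d", prefix, d)
      r <- if (is.null(dilations)) 1L else dilations[d]
      h <- op_prelu(op_conv3d(h, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
                              dilation = r), p[[paste0(nm, ".a")]])
    }
  }
  op_dropout(op_add(h, x), cfg$dropout_p, training)
}

#' Pyramid convolution block forward pass
#'
#' Three parallel same-padded convolutions (kernels 3/5/7 by default) whose
#' outputs are summed with PReLU activations, added to the identity shortcut,
#' then passed through a trailing 1x1x1 convolution. Shape- and
#' channel-preserving.
#'
#' @param x input node or array of dim (nx, ny, nz, C)
#' @param weights named list with entries `k<K>.w`, `k<K>.b`, `k<K>.a` for
#'   each branch kernel K and `post.w`, `post.b`
#' @param kernels branch kernel sizes
#' @param bypass_post if `TRUE` the trailing 1x1x1 conv is skipped (test
#'   harness for the pure residual form)
#' @return output node with the same shape as the input
#' @export
pyramid_block_forward <- function(x, weights, kernels = c(3L, 5L, 7L),
                                  bypass_post = FALSE) {
  xv <- ag_value(x)
  cin <- dim(ag_value(weights[[paste0("k", kernels[1], ".w")]]))[4]
  if (nn_channels(xv) != cin)
    stop("channel mismatch: input has ", nn_channels(xv),
         " channels, block expects ", cin)
  branches <- lapply(kernels, function(k) {
    op_prelu(op_conv3d(x, weights[[paste0("k", k, ".w")]],
                       weights[[paste0("k", k, ".b")]]),
             weights[[paste0("k", k, ".a")]])
  })
  h <- op_add(Reduce(op_add, branches), x)
  if (bypass_post) return(h)
  op_conv3d(h, weights[["post.w"]], weights[["post.b"]])
}

.pyramid_weights <- function(model, level) {
  p <- model$params
  ks <- model$config$pyramid_kernels
  w <- list()
  for (k in ks) {
    for (suf in c("w", "b", "a"))
      w[[sprintf("k%d.%s", k, suf)]] <- p[[sprintf("pyr%d.k%d.%s", level, k, suf)]]
  }
  w[["post.w"]] <- p[[sprintf("pyr%d.post.w", level)]]
  w[["post.b"]] <- p[[sprintf("pyr%d.post.b", level)]]
  w
}

#' Forward pass of the improved V-Net
#'
#' @param model a `vnet3d` model
#' @param image 3-D array (nx, ny, nz) or (nx, ny, nz, in_channels); spatial
#'   extents must be divisible by 8
#' @param training apply dropout and keep the tape for backward
#' @return list with `fused` (full-resolution logits node), `paths` (logit
#'   nodes at full, 1/2, 1/4 resolution), `probs` (softmax of the fused
#'   logits) and `input` (the input node)
#' @export
vnet_forward <- function(model, image, training = FALSE) {
  cfg <- model$config
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  dims <- dim(image)[1:3]
  if (any(dims %% 8L != 0L))
    stop("spatial extents must be divisible by 8, got ",
         paste(dims, collapse = "x"))
  p <- model$params
  depths <- cfg$stage_depths

  x0 <- ag_constant(image)
  t0 <- op_prelu(op_conv3d(x0, p[["in.w"]], p[["in.b"]]), p[["in.a"]])
  skips <- vector("list", 3L)
  h <- t0
  for (l in 1:3) {
    h <- .vnet_stage(h, model, sprintf("enc%d", l), depths[l],
                     training = training)
    skips[[l]] <- h
    h <- op_prelu(op_downconv(h, p[[sprintf("down%d.w", l)]],
                              p[[sprintf("down%d.b", l)]]),
                  p[[sprintf("down%d.a", l)]])
  }
  h <- .vnet_stage(h, model, "bott", length(cfg$dilation_rates),
                   dilations = cfg$dilation_rates, training = training)
  dec <- vector("list", 3L)
  for (l in 3:1) {
    u <- op_prelu(op_upconv(h, p[[sprintf("up%d.w", l)]],
                            p[[sprintf("up%d.b", l)]]),
                  p[[sprintf("up%d.a", l)]])
    s <- if (cfg$use_pyramid)
      pyramid_block_forward(skips[[l]], .pyramid_weights(model, l),
                            kernels = cfg$pyramid_kernels)
    else skips[[l]]
    h <- .vnet_stage(op_add(u, s), model, sprintf("dec%d", l), depths[l],
                     training = training)
    dec[[l]] <- h
  }
  paths <- list(
    full = op_conv3d(dec[[1]], p[["head.full.w"]], p[["head.full.b"]]),
    half = op_conv3d(dec[[2]], p[["head.half.w"]], p[["head.half.b"]]),
    quarter = op_conv3d(dec[[3]], p[["head.quarter.w"]], p[["head.quarter.b"]]))
  fused <- fuse_pyramid(paths, merge = cfg$fusion_merge, model = model)
  list(fused = fused, paths = paths, probs = op_softmax(fused), input = x0)
}

#' Impulse-response extent of a linearized convolution stack
#'
#' Builds single-channel copies of the given convolutions with all weights
#' set to 1 and biases 0 (activations identity), feeds a centered unit
#' impulse, back-propagates an impulse seeded at the central output voxel and
#' returns the bounding-box extent of the non-zero input gradient per axis:
#' the receptive field of one output voxel.
#'
#' @param stage list of convolution specs, each `list(k = , r = )`; e.g.
#'   `dilated_stage_spec(model)` for the level-4 dilated stack
#' @return integer extent per axis (identical on all three axes)
#' @export
#' @examples
#' receptive_field_probe(list(list(k = 3, r = 5))) # 11
receptive_field_probe <- function(stage) {
  ks <- vapply(stage, function(s) effective_kernel_size(s$k, s$r), numeric(1))
  size <- as.integer(sum(ks - 1) + 1 + 4)
  if (size %% 2L == 0L) size <- size + 1L
  ctr <- (size + 1L) %/% 2L
  impulse <- array(0, dim = c(size, size, size, 1L))
  impulse[ctr, ctr, ctr, 1L] <- 1
  x <- ag_node(impulse)
  x$is_param <- TRUE   # request a gradient at the input
  h <- x
  for (s in stage) {
    w <- ag_constant(array(1, dim = c(s$k, s$k, s$k, 1L, 1L)))
    h <- op_conv3d(h, w, ag_constant(0), dilation = s$r)
  }
  seed <- array(0, dim = dim(impulse))
  seed[ctr, ctr, ctr, 1L] <- 1
  ag_backward(h, seed = seed)
  nz <- which(abs(x$grad) > 0, arr.ind = TRUE)
  extent <- apply(nz[, 1:3, drop = FALSE], 2, function(ix) diff(range(ix)) + 1L)
  if (length(unique(extent)) != 1L)
    warning("anisotropic receptive field: ", paste(extent, collapse = "x"))
  as.integer(extent[1])
}

#' Dilated-stage spec of a model, for the receptive-field probe
#' @param model a `vnet3d` model
#' @return list of `list(k, r)` convolution specs
#' @export
dilated_stage_spec <- function(model) {
  lapply(model$config$dilation_rates,
         function(r) list(k = model$config$conv_kernel, r = r))
}
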
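# ---- differentiable network operations --------------------------------------
#
# All feature fields are numeric arrays of dim (nx, ny, nz, channels).
# Convolution weights are (k, k, k, c_in, c_out); 2x2x2 resampling weights
# are (2, 2, 2, c_in, c_out). Every op returns an ag_node whose backward
# closure calls the matching C++ adjoint kernel.

nn_spatial <- function(x) dim(x)[1:3]
nn_channels <- function(x) dim(x)[4]

# does any gradient need to flow into this node?
nn_needs_grad <- function(x) {
  inherits(x, "ag_node") && (x$is_param || !is.null(x$backward))
}

# flip a conv kernel along all spatial axes and swap in/out channels:
# the weight array of the adjoint convolution
nn_flip_kernel <- function(w) {
  k <- dim(w)[1]
  aperm(w[k:1, k:1, k:1, , , drop = FALSE], c(1, 2, 3, 5, 4))
}

op_conv3d <- function(x, w, b, dilation = 1L) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  dims <- nn_spatial(xv)
  cin <- dim(wv)[4]; cout <- dim(wv)[5]; k <- dim(wv)[1]
  stopifnot(nn_channels(xv) == cin)
  y <- cc_conv3d_fwd(xv, as.integer(dims), wv, as.integer(k),
                     as.integer(dilation), cin, cout, bv)
  dim(y) <- c(dims, cout)
  x_needs <- nn_needs_grad(x)
  ag_node(y, parents = list(x, w, b), backward = function(gy) {
    gx <- NULL
    if (x_needs) {
      wf <- nn_flip_kernel(wv)
      gx <- cc_conv3d_fwd(gy, as.integer(dims), wf, as.integer(k),
                          as.integer(dilation), cout, cin, numeric(cin))
      dim(gx) <- c(dims, cin)
    }
    gw <- cc_conv3d_bww(xv, gy, as.integer(dims), as.integer(k),
                        as.integer(dilation), cin, cout)
    dim(gw) <- dim(wv)
    gb <- colSums(matrix(gy, ncol = cout))
    list(gx, gw, gb)
  })
}

op_downconv <- function(x, w, b) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  dims <- nn_spatial(xv)
  if (any(dims %% 2L != 0L))
    stop("downsampling requires even spatial extents, got ",
         paste(dims, collapse = "x"))
  cin <- dim(wv)[4]; cout <- dim(wv)[5]
  y <- cc_down_fwd(xv, as.integer(dims), wv, cin, cout, bv)
  dim(y) <- c(dims %/% 2L, cout)
  ag_node(y, parents = list(x, w, b), backward = function(gy) {
    gx <- cc_down_bwx(gy, as.integer(dims), wv, cin, cout)
    dim(gx) <- c(dims, cin)
    gw <- cc_down_bww(xv, gy, as.integer(dims), cin, cout)
    dim(gw) <- dim(wv)
    gb <- colSums(matrix(gy, ncol = cout))
    list(gx, gw, gb)
  })
}

op_upconv <- function(x, w, b) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  dims <- nn_spatial(xv)
  cin <- dim(wv)[4]; cout <- dim(wv)[5]
  y <- cc_up_fwd(xv, as.integer(dims), wv, cin, cout, bv)
  dim(y) <- c(dims * 2L, cout)
  ag_node(y, parents = list(x, w, b), backward = function(gy) {
    gx <- cc_up_bwx(gy, as.integer(dims), wv, cin, cout)
    dim(gx) <- c(dims, cin)
    gw <- cc_up_bww(xv, gy, as.integer(dims), cin, cout)
    dim(gw) <- dim(wv)
    gb <- colSums(matrix(gy, ncol = cout))
    list(gx, gw, gb)
  })
}

# PReLU with one learnable slope per channel (slope `a` is a plain vector)
op_prelu <- function(x, a) {
  xv <- ag_value(x); av <- ag_value(a)
  nc <- nn_channels(xv)
  nvox <- prod(nn_spatial(xv))
  a_full <- rep(av, each = nvox)
  neg <- xv < 0
  xneg <- xv * neg
  y <- xv - xneg + a_full * xneg
  dim(y) <- dim(xv)
  ag_node(y, parents = list(x, a), backward = function(gy) {
    gx <- gy * ((1 - neg) + a_full * neg)
    dim(gx) <- dim(xv)
    ga <- colSums(matrix(gy * xneg, ncol = nc))
    list(gx, ga)
  })
}

# inverted dropout; a no-op outside training
op_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  xv <- ag_value(x)
  keep <- 1 - p
  mask <- (stats::runif(length(xv)) < keep) / keep
  y <- xv * mask
  dim(y) <- dim(xv)
  ag_node(y, parents = list(x), backward = function(gy) {
    gx <- gy * mask
    dim(gx) <- dim(xv)
    list(gx)
  })
}

op_add <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  ag_node(xv + yv, parents = list(x, y),
          backward = function(g) list(g, g))
}

op_upsample2 <- function(x) {
  xv <- ag_value(x)
  dims <- nn_spatial(xv)
  nc <- nn_channels(xv)
  y <- cc_upsample2_fwd(xv, as.integer(dims), nc)
  dim(y) <- c(dims * 2L, nc)
  ag_node(y, parents = list(x), backward = function(gy) {
    gx <- cc_upsample2_bwd(gy, as.integer(dims), nc)
    dim(gx) <- c(dims, nc)
    list(gx)
  })
}

op_concat <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  cx <- nn_channels(xv); cy <- nn_channels(yv)
  dims <- nn_spatial(xv)
  v <- array(c(xv, yv), dim = c(dims, cx + cy))
  ag_node(v, parents = list(x, y), backward = function(g) {
    nvox <- prod(dims)
    gm <- matrix(g, ncol = cx + cy)
    gx <- array(gm[, seq_len(cx)], dim = c(dims, cx))
    gy <- array(gm[, cx + seq_len(cy)], dim = c(dims, cy))
    list(gx, gy)
  })
}

# channel softmax (any number of classes; the package uses 2)
op_softmax <- function(x) {
  xv <- ag_value(x)
  dims <- nn_spatial(xv)
  nc <- nn_channels(xv)
  m <- matrix(xv, ncol = nc)
  m <- m - apply(m, 1, max)
  e <- exp(m)
  pm <- e / rowSums(e)
  p <- array(pm, dim = c(dims, nc))
  ag_node(p, parents = list(x), backward = function(g) {
    gm <- matrix(g, ncol = nc)
    dot <- rowSums(gm * pm)
    gx <- array(pm * (gm - dot), dim = c(dims, nc))
    list(gx)
  })
}

# wrap a segmentation loss (value + analytic gradients w.r.t. p0 and p1,
# from the losses module) as a scalar graph node over a probability field
op_seg_loss <- function(probs, g0, loss_fn) {
  pv <- ag_value(probs)
  dims <- nn_spatial(pv)
  p0 <- array(pv[, , , 1], dim = dims)
  p1 <- array(pv[, , , 2], dim = dims)
  res <- loss_fn(p0, p1, g0)
  ag_node(res$value, parents = list(probs), backward = function(g) {
    gp <- array(c(res$grad_p0, res$grad_p1), dim = c(dims, 2L)) * g
    list(gp)
  })
}
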
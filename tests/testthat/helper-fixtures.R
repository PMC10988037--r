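# shared fixtures: everything is generated in code, nothing on disk

# a tiny network configuration that trains in seconds on a CPU
tiny_network <- function(...) {
  network_config(base_channels = 2L, dropout_p = 0, ...)
}

# small phantom configuration for fast dataset construction
tiny_phantom <- function(...) {
  phantom_config(shape = c(32L, 32L, 32L), n_branch_levels = 3L,
                 root_radius = 2.2, noise_sigma = 10,
                 target_foreground_fraction = 0.015, ...)
}

# replace fields of a classed config list
mod_cfg <- function(cfg, ...) {
  repl <- list(...)
  cfg[names(repl)] <- repl
  cfg
}

# a hand-built single-segment tree (axis-aligned capsule)
single_tube_tree <- function(p0, p1, radius, shape, spacing = c(1, 1, 1)) {
  segs <- data.frame(x0 = p0[1], y0 = p0[2], z0 = p0[3],
                     x1 = p1[1], y1 = p1[2], z1 = p1[3],
                     radius = radius, level = 1L, parent = 0L)
  structure(list(segments = segs, shape = as.integer(shape),
                 spacing = spacing), class = "vessel_tree")
}

# brute-force rasterization oracle: per-voxel point-to-segment distance in R
rasterize_oracle <- function(tree, shape, spacing) {
  segs <- tree$segments
  out <- array(0L, dim = shape)
  for (ix in seq_len(shape[1])) for (iy in seq_len(shape[2]))
    for (iz in seq_len(shape[3])) {
      p <- (c(ix, iy, iz) - 0.5) * spacing
      for (s in seq_len(nrow(segs))) {
        a <- as.numeric(segs[s, c("x0", "y0", "z0")])
        b <- as.numeric(segs[s, c("x1", "y1", "z1")])
        u <- b - a
        len2 <- sum(u^2)
        t <- if (len2 > 0) max(0, min(1, sum((p - a) * u) / len2)) else 0
        d2 <- sum((a + t * u - p)^2)
        if (d2 <= segs$radius[s]^2) { out[ix, iy, iz] <- 1L; break }
      }
    }
  out
}

# average-pool-then-threshold oracle for label downsampling (factor 2)
downsample_oracle <- function(arr) {
  d <- dim(arr) %/% 2L
  out <- array(0L, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    blk <- arr[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    out[i, j, k] <- as.integer(mean(blk) >= 0.5)
  }
  out
}

# random soft prediction + binary truth of n voxels
random_instance <- function(n, fg_prob = 0.3) {
  p0 <- runif(n)
  list(p0 = p0, p1 = 1 - p0, g0 = as.integer(runif(n) < fg_prob))
}

# scalar-sum wrapper so op outputs can be back-propagated in op-level tests
ag_sum_node <- function(o) {
  ve <- asNamespace("vesselvnet")
  ve$ag_node(sum(o$value), parents = list(o),
             backward = function(g) list(array(g, dim = dim(o$value))))
}
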
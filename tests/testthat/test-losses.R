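test_that("the worked Tversky example evaluates to 1.4/1.88", {
  idx <- tversky_index(c(0.8, 0.6, 0.2), c(1, 1, 0), alpha = 0.3, beta = 0.7)
  expect_equal(idx, 1.4 / 1.88, tolerance = 1e-4) # eps-smoothing tolerance
  expect_equal(tversky_index(c(0.8, 0.6, 0.2), c(1, 1, 0), alpha = 0.3,
                             beta = 0.7, eps = 0), 1.4 / 1.88)
  expect_equal(tversky_loss(c(0.8, 0.6, 0.2), c(1, 1, 0)),
               1 - 1.4 / 1.88, tolerance = 1e-4)
})

test_that("Tversky at alpha = beta = 0.5 is the soft Dice coefficient", {
  set.seed(100)
  for (i in 1:200) {
    inst <- random_instance(sample(4:64, 1))
    t05 <- tversky_index(inst$p0, inst$g0, alpha = 0.5, beta = 0.5)
    d <- 1 - dice_loss(inst$p0, inst$g0)
    expect_equal(t05, d, tolerance = 1e-6)
  }
})

test_that("Tversky index stays within [0, 1] and is 1 at perfect overlap", {
  set.seed(101)
  for (i in 1:100) {
    inst <- random_instance(sample(2:64, 1))
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    if (a + b == 0) a <- 0.5
    ti <- tversky_index(inst$p0, inst$g0, alpha = a, beta = b)
    expect_gte(ti, 0); expect_lte(ti, 1)
  }
  g <- c(1, 0, 1, 0)
  expect_equal(tversky_index(g, g, alpha = 0.3, beta = 0.7), 1,
               tolerance = 1e-5)
  expect_equal(tversky_loss(g, g), 0, tolerance = 1e-5)
})

test_that("loss increases with false-negative mass when beta > 0", {
  g0 <- c(rep(1, 10), rep(0, 10))
  losses <- vapply(seq(0, 0.8, by = 0.1), function(fn_mass) {
    p0 <- c(rep(1 - fn_mass, 10), rep(0.2, 10)) # fixed FP mass
    tversky_loss(p0, g0, alpha = 0.3, beta = 0.7)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("analytic Tversky gradient matches centered finite differences", {
  set.seed(102)
  eps_fd <- 1e-6
  for (i in 1:200) {
    n <- sample(2:64, 1)
    inst <- random_instance(n)
    p0 <- inst$p0; p1 <- inst$p1; g0 <- inst$g0
    gr <- tversky_gradient(p0, g0, alpha = 0.3, beta = 0.7, p1 = p1)
    j <- sample(n, 1)
    up <- p0; up[j] <- up[j] + eps_fd
    dn <- p0; dn[j] <- dn[j] - eps_fd
    num0 <- (tversky_index(up, g0, 0.3, 0.7, p1 = p1) -
               tversky_index(dn, g0, 0.3, 0.7, p1 = p1)) / (2 * eps_fd)
    up1 <- p1; up1[j] <- up1[j] + eps_fd
    dn1 <- p1; dn1[j] <- dn1[j] - eps_fd
    num1 <- (tversky_index(p0, g0, 0.3, 0.7, p1 = up1) -
               tversky_index(p0, g0, 0.3, 0.7, p1 = dn1)) / (2 * eps_fd)
    denom0 <- max(1, abs(num0), abs(gr$dT_dp0[j]))
    denom1 <- max(1, abs(num1), abs(gr$dT_dp1[j]))
    expect_lt(abs(gr$dT_dp0[j] - num0) / denom0, 1e-4)
    expect_lt(abs(gr$dT_dp1[j] - num1) / denom1, 1e-4)
  }
})

test_that("dT/dp1 vanishes exactly on background voxels", {
  set.seed(103)
  inst <- random_instance(32)
  gr <- tversky_gradient(inst$p0, inst$g0, p1 = inst$p1)
  expect_true(all(gr$dT_dp1[inst$g0 == 0] == 0))
  expect_true(all(gr$dT_dp1[inst$g0 == 1] < 0))
})

test_that("gradient is finite at perfect binary predictions (smoothed)", {
  g <- c(1, 1, 0, 0)
  gr <- tversky_gradient(g, g, p1 = 1 - g)
  expect_true(all(is.finite(gr$dT_dp0)))
  expect_true(all(is.finite(gr$dT_dp1)))
})

test_that("index is invariant under swapping alpha/beta with the error roles", {
  set.seed(104)
  for (i in 1:50) {
    inst <- random_instance(16)
    a <- runif(1, 0.1, 1); b <- runif(1, 0.1, 1)
    t1 <- tversky_index(inst$p0, inst$g0, alpha = a, beta = b, p1 = inst$p1)
    # swapping alpha<->beta while swapping the FP and FN error terms leaves
    # the index unchanged; verified on the raw sums:
    g0 <- inst$g0; p0 <- inst$p0; p1 <- inst$p1
    num <- sum(p0 * g0) + 1e-5
    d1 <- num + a * sum(p0 * (1 - g0)) + b * sum(p1 * g0)
    d2 <- num + b * sum(p1 * g0) + a * sum(p0 * (1 - g0))
    expect_equal(num / d1, num / d2)
    expect_equal(t1, num / d1)
  }
})

test_that("Dice loss agrees with hand computation and its Tversky identity", {
  expect_equal(dice_loss(c(0.5, 0.5), c(1, 0)), 0.5, tolerance = 1e-5)
  expect_equal(dice_loss(c(1, 0, 1), c(1, 0, 1)), 0, tolerance = 1e-5)
  set.seed(105)
  for (i in 1:20) {
    inst <- random_instance(24)
    expect_equal(dice_loss(inst$p0, inst$g0),
                 tversky_loss(inst$p0, inst$g0, alpha = 0.5, beta = 0.5),
                 tolerance = 1e-6)
  }
})

test_that("generalized Dice weights favor the rarer class", {
  set.seed(106)
  g0 <- c(rep(1, 3), rep(0, 29)) # rare foreground
  w0 <- 1 / sum(g0)^2
  w1 <- 1 / sum(1 - g0)^2
  expect_gt(w0, w1)

  inst <- random_instance(32)
  expect_equal(generalized_dice_loss(inst$g0, inst$g0, p1 = 1 - inst$g0), 0,
               tolerance = 1e-4)

  # balanced classes: equal weights cancel, giving the pooled two-class form
  gb <- c(rep(1, 16), rep(0, 16))
  p0 <- runif(32); p1 <- 1 - p0
  got <- generalized_dice_loss(p0, gb, p1 = p1)
  pooled <- 1 - 2 * (sum(p0 * gb) + sum(p1 * (1 - gb))) /
    (sum(p0) + sum(gb) + sum(p1) + sum(1 - gb))
  expect_equal(got, pooled, tolerance = 2e-4) # eps-smoothing tolerance
})

test_that("cross-entropy loss matches closed forms", {
  g <- c(1, 0, 1, 0)
  expect_lt(bce_loss(g, g), 1e-6)
  expect_equal(bce_loss(rep(0.5, 8), c(1, 1, 0, 0, 1, 0, 1, 0)), log(2))
  # element-wise hand computation on 4 voxels
  p0 <- c(0.9, 0.2, 0.6, 0.4); g0 <- c(1, 0, 0, 1)
  hand <- -mean(c(log(0.9), log(0.8), log(0.4), log(0.4)))
  expect_equal(bce_loss(p0, g0), hand, tolerance = 1e-12)
})

test_that("focal loss generalizes cross-entropy and focuses on hard voxels", {
  set.seed(107)
  inst <- random_instance(40)
  expect_equal(focal_loss(inst$p0, inst$g0, gamma = 0, weight = 1),
               bce_loss(inst$p0, inst$g0), tolerance = 1e-6)
  # correctly classified foreground voxel at p = 0.9
  expect_equal(focal_loss(0.9, 1, gamma = 2), (1 - 0.9)^2 * (-log(0.9)),
               tolerance = 1e-9)
  # easy voxels are progressively down-weighted as gamma grows
  easy_p <- rep(0.9, 10); easy_g <- rep(1, 10)
  ls <- vapply(c(0, 1, 2, 4), function(g)
    focal_loss(easy_p, easy_g, gamma = g), numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("all five losses vanish at perfect prediction, positive otherwise", {
  g <- c(1, 0, 0, 1, 0, 0, 0, 1)
  fns <- list(
    function(p, g) tversky_loss(p, g),
    function(p, g) dice_loss(p, g),
    function(p, g) generalized_dice_loss(p, g),
    function(p, g) bce_loss(p, g),
    function(p, g) focal_loss(p, g))
  for (f in fns) {
    expect_lt(f(g, g), 1e-3)
    expect_gt(f(abs(g - 0.4), g), 0.01)
  }
})

test_that("make_loss closures return gradients consistent with their values", {
  set.seed(108)
  inst <- random_instance(24)
  eps_fd <- 1e-6
  for (nm in c("tversky", "dice", "gdl", "bce", "focal")) {
    f <- make_loss(nm)
    res <- f(inst$p0, inst$p1, inst$g0)
    j <- sample(24, 1)
    up <- inst$p0; up[j] <- up[j] + eps_fd
    dn <- inst$p0; dn[j] <- dn[j] - eps_fd
    num <- (f(up, inst$p1, inst$g0)$value -
              f(dn, inst$p1, inst$g0)$value) / (2 * eps_fd)
    expect_lt(abs(res$grad_p0[j] - num) / max(1, abs(num)), 1e-4,
              label = paste("grad_p0 of", nm))
  }
  expect_error(make_loss("boundary"), "arg")
})
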
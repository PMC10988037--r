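# ---- segmentation losses ----------------------------------------------------
#
# All losses operate on soft two-class predictions: p0 is the per-voxel
# foreground probability, p1 the background probability (p0 + p1 = 1 when the
# prediction comes from a two-channel softmax, but the two are treated as
# independent variables for gradient purposes). g0 is the binary foreground
# label; g1 = 1 - g0.

.check_pred <- function(p0, g0, p1) {
  if (length(p0) != length(g0))
    stop("prediction and truth have different voxel counts: ",
         length(p0), " vs ", length(g0))
  if (length(p1) != length(p0))
    stop("p0 and p1 have different voxel counts")
  invisible(NULL)
}

#' Tversky index of a soft segmentation
#'
#' Computes the Tversky overlap index
#' \deqn{T = \frac{\sum_i p_{0i} g_{0i}}{\sum_i p_{0i} g_{0i}
#'   + \alpha \sum_i p_{0i} g_{1i} + \beta \sum_i p_{1i} g_{0i}}}
#' where `alpha` weights false positives and `beta` false negatives. With
#' `alpha = beta = 0.5` the index reduces to the soft Dice coefficient. A
#' smoothing constant `eps` is added to numerator and denominator so empty
#' foreground does not produce 0/0.
#'
#' @param p0 numeric array/vector of foreground probabilities in \[0, 1\]
#' @param g0 binary array/vector of foreground labels, same length as `p0`
#' @param alpha false-positive weight (default 0.3)
#' @param beta false-negative weight (default 0.7)
#' @param p1 background probabilities; defaults to `1 - p0`
#' @param eps smoothing constant added to numerator and denominator
#' @return scalar index in \[0, 1\]
#' @export
#' @examples
#' tversky_index(c(0.8, 0.6, 0.2), c(1, 1, 0), alpha = 0.3, beta = 0.7)
tversky_index <- function(p0, g0, alpha = 0.3, beta = 0.7, p1 = 1 - p0,
                          eps = 1e-5) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop("require alpha >= 0, beta >= 0 and alpha + beta > 0")
  .check_pred(p0, g0, p1)
  g1 <- 1 - g0
  num <- sum(p0 * g0) + eps
  den <- sum(p0 * g0) + alpha * sum(p0 * g1) + beta * sum(p1 * g0) + eps
  num / den
}

#' Tversky loss (1 - Tversky index)
#'
#' @inheritParams tversky_index
#' @return scalar loss, 0 at perfect prediction
#' @export
tversky_loss <- function(p0, g0, alpha = 0.3, beta = 0.7, p1 = 1 - p0,
                         eps = 1e-5) {
  1 - tversky_index(p0, g0, alpha = alpha, beta = beta, p1 = p1, eps = eps)
}

#' Analytic gradient of the Tversky index
#'
#' Differentiates the smoothed Tversky index with respect to every `p0[i]`
#' and `p1[i]` independently. With numerator \eqn{N} and denominator \eqn{D},
#' \deqn{\partial T/\partial p_{0i} = (g_{0i} D - N (g_{0i} + \alpha g_{1i}))/D^2,
#'       \quad \partial T/\partial p_{1i} = -\beta g_{0i} N / D^2.}
#' The gradient of the Tversky *loss* is the negative of these fields.
#'
#' @inheritParams tversky_index
#' @return list with per-voxel arrays `dT_dp0` and `dT_dp1`
#' @export
tversky_gradient <- function(p0, g0, alpha = 0.3, beta = 0.7, p1 = 1 - p0,
                             eps = 1e-5) {
  .check_pred(p0, g0, p1)
  g1 <- 1 - g0
  num <- sum(p0 * g0) + eps
  den <- sum(p0 * g0) + alpha * sum(p0 * g1) + beta * sum(p1 * g0) + eps
  d0 <- (g0 * den - num * (g0 + alpha * g1)) / den^2
  d1 <- -beta * g0 * num / den^2
  if (!is.null(dim(p0))) { dim(d0) <- dim(p0); dim(d1) <- dim(p0) }
  list(dT_dp0 = d0, dT_dp1 = d1)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p0 g0) + 2 eps) / (sum(p0) + sum(g0) + 2 eps)`; algebraically
#' identical to [tversky_loss()] at `alpha = beta = 0.5` when `p1 = 1 - p0`.
#'
#' @inheritParams tversky_index
#' @return scalar loss
#' @export
dice_loss <- function(p0, g0, eps = 1e-5) {
  .check_pred(p0, g0, p0)
  1 - (2 * sum(p0 * g0) + 2 * eps) / (sum(p0) + sum(g0) + 2 * eps)
}

#' Generalized Dice loss
#'
#' Two-class generalized Dice with squared-reciprocal class weights
#' `w_c = 1 / (sum(g_c))^2`, so the rarer class dominates the overlap term.
#'
#' @inheritParams tversky_index
#' @return scalar loss
#' @export
generalized_dice_loss <- function(p0, g0, p1 = 1 - p0, eps = 1e-5) {
  .check_pred(p0, g0, p1)
  g1 <- 1 - g0
  w0 <- if (sum(g0) > 0) 1 / sum(g0)^2 else 0 # absent class carries no weight
  w1 <- if (sum(g1) > 0) 1 / sum(g1)^2 else 0
  num <- w0 * sum(p0 * g0) + w1 * sum(p1 * g1) + eps
  den <- w0 * (sum(p0) + sum(g0)) + w1 * (sum(p1) + sum(g1)) + eps
  1 - 2 * num / den
}

#' Cross-entropy loss for binary segmentation
#'
#' Mean over voxels of the two-class cross-entropy
#' `-(g0 log p0 + g1 log p1)`; probabilities are clamped away from 0.
#'
#' @inheritParams tversky_index
#' @param clamp lower bound applied to probabilities before taking logs
#' @return scalar loss (per-voxel mean)
#' @export
bce_loss <- function(p0, g0, p1 = 1 - p0, clamp = 1e-7) {
  .check_pred(p0, g0, p1)
  g1 <- 1 - g0
  p0c <- pmax(p0, clamp)
  p1c <- pmax(p1, clamp)
  -mean(g0 * log(p0c) + g1 * log(p1c))
}

#' Focal loss for binary segmentation
#'
#' Mean over voxels of `w g0 (1-p0)^gamma (-log p0) + g1 (1-p1)^gamma
#' (-log p1)`: easy voxels (probability near 1 on the true class) are
#' down-weighted by the factor `(1-p)^gamma`. With `gamma = 0` and
#' `weight = 1` this reduces exactly to [bce_loss()].
#'
#' @inheritParams bce_loss
#' @param gamma focusing exponent (default 2)
#' @param weight multiplicative weight on the foreground term (default 1)
#' @return scalar loss (per-voxel mean)
#' @export
focal_loss <- function(p0, g0, gamma = 2, weight = 1, p1 = 1 - p0,
                       clamp = 1e-7) {
  .check_pred(p0, g0, p1)
  g1 <- 1 - g0
  p0c <- pmax(p0, clamp)
  p1c <- pmax(p1, clamp)
  mean(weight * g0 * (1 - p0c)^gamma * (-log(p0c)) +
         g1 * (1 - p1c)^gamma * (-log(p1c)))
}

#' Build a differentiable loss closure by name
#'
#' Returns a function `f(p0, p1, g0)` yielding `list(value, grad_p0,
#' grad_p1)`, the interface consumed by the training graph. This is the
#' switch behind the loss-comparison harness: `tversky`, `dice`, `gdl`,
#' `bce`, `focal`.
#'
#' @param name one of `"tversky"`, `"dice"`, `"gdl"`, `"bce"`, `"focal"`
#' @param alpha,beta Tversky weights (used by `"tversky"`)
#' @param gamma,weight focal parameters (used by `"focal"`)
#' @param eps smoothing constant for the overlap losses
#' @return closure computing loss value and per-voxel gradients
#' @export
make_loss <- function(name = c("tversky", "dice", "gdl", "bce", "focal"),
                      alpha = 0.3, beta = 0.7, gamma = 2, weight = 1,
                      eps = 1e-5) {
  name <- match.arg(name)
  clamp <- 1e-7
  switch(name,
    tversky = function(p0, p1, g0) {
      gr <- tversky_gradient(p0, g0, alpha = alpha, beta = beta, p1 = p1,
                             eps = eps)
      list(value = 1 - tversky_index(p0, g0, alpha = alpha, beta = beta,
                                     p1 = p1, eps = eps),
           grad_p0 = -gr$dT_dp0, grad_p1 = -gr$dT_dp1)
    },
    dice = function(p0, p1, g0) {
      gr <- tversky_gradient(p0, g0, alpha = 0.5, beta = 0.5, p1 = p1,
                             eps = eps)
      list(value = 1 - tversky_index(p0, g0, alpha = 0.5, beta = 0.5,
                                     p1 = p1, eps = eps),
           grad_p0 = -gr$dT_dp0, grad_p1 = -gr$dT_dp1)
    },
    gdl = function(p0, p1, g0) {
      g1 <- 1 - g0
      w0 <- if (sum(g0) > 0) 1 / sum(g0)^2 else 0
      w1 <- if (sum(g1) > 0) 1 / sum(g1)^2 else 0
      A <- w0 * sum(p0 * g0) + w1 * sum(p1 * g1) + eps
      B <- w0 * (sum(p0) + sum(g0)) + w1 * (sum(p1) + sum(g1)) + eps
      list(value = 1 - 2 * A / B,
           grad_p0 = -2 * (w0 * g0 * B - A * w0) / B^2,
           grad_p1 = -2 * (w1 * g1 * B - A * w1) / B^2)
    },
    bce = function(p0, p1, g0) {
      g1 <- 1 - g0
      n <- length(p0)
      p0c <- pmax(p0, clamp); p1c <- pmax(p1, clamp)
      list(value = -mean(g0 * log(p0c) + g1 * log(p1c)),
           grad_p0 = -g0 / p0c / n,
           grad_p1 = -g1 / p1c / n)
    },
    focal = function(p0, p1, g0) {
      g1 <- 1 - g0
      n <- length(p0)
      p0c <- pmin(pmax(p0, clamp), 1 - clamp)
      p1c <- pmin(pmax(p1, clamp), 1 - clamp)
      v <- mean(weight * g0 * (1 - p0c)^gamma * (-log(p0c)) +
                  g1 * (1 - p1c)^gamma * (-log(p1c)))
      d0 <- weight * g0 *
        (gamma * (1 - p0c)^(gamma - 1) * log(p0c) - (1 - p0c)^gamma / p0c) / n
      d1 <- g1 *
        (gamma * (1 - p1c)^(gamma - 1) * log(p1c) - (1 - p1c)^gamma / p1c) / n
      list(value = v, grad_p0 = d0, grad_p1 = d1)
    })
}
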
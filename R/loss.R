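# Deep-supervision Dice + cross-entropy loss and the polynomial
# learning-rate schedule.

#' Deep-supervision loss weights
#'
#' Finest-first geometric sequence with ratio 1/2, normalized to sum to 1:
#' the finest decoder head carries the largest weight and each coarser
#' head half of the previous one.
#'
#' @param n_heads Number of deep-supervision heads (>= 1).
#' @return Numeric vector of weights summing to 1 (e.g. `c(8, 4, 2, 1)/15`
#'   for four heads).
#' @export
supervision_weights <- function(n_heads) {
  if (n_heads < 1) stop("n_heads must be >= 1")
  w <- 0.5^(seq_len(n_heads) - 1)
  w / sum(w)
}

#' Per-head segmentation loss (cross-entropy + Dice)
#'
#' `CE` is the voxel-mean negative log-likelihood
#' `-(1/N) * sum(y*log(o) + (1-y)*log(1-o))` and the Dice term is
#' `D = -(2*sum(o*y) + s) / (sum(o) + sum(y) + s)` with smoothing `s`, so
#' perfect binary agreement drives `CE -> 0` and `D -> -1`.  Probabilities
#' are clamped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param o Predicted probability array in \[0, 1\].
#' @param y Binary label array of the same shape.
#' @param smooth Dice smoothing constant `s`.
#' @param eps Probability clamp.
#' @return Scalar loss `CE + D` (lower bounded by -1 as `s, eps -> 0`).
#' @export
head_loss <- function(o, y, smooth = 1e-5, eps = 1e-7) {
  if (!identical(dim(o) %||% length(o), dim(y) %||% length(y)))
    stop("prediction and label shapes must match")
  oc <- pmin(pmax(o, eps), 1 - eps)
  ce <- -mean(y * log(oc) + (1 - y) * log(1 - oc))
  d <- -(2 * sum(oc * y) + smooth) / (sum(oc) + sum(y) + smooth)
  ce + d
}

# Gradient of head_loss with respect to pre-sigmoid logits.
head_loss_grad_z <- function(o, y, smooth = 1e-5, eps = 1e-7) {
  n <- length(o)
  oc <- pmin(pmax(o, eps), 1 - eps)
  gce <- (o - y) / n
  A <- 2 * sum(oc * y) + smooth
  B <- sum(oc) + sum(y) + smooth
  gd_o <- -(2 * y * B - A) / B^2
  gce + gd_o * o * (1 - o)
}

#' Composite deep-supervision loss
#'
#' Weighted sum of per-head losses, `sum_i w_i * (CE_i + D_i)`; weights
#' must sum to 1 (see [supervision_weights()]).
#'
#' @param bundle List with elements `outputs` (probability arrays,
#'   finest first), `labels` (matched-resolution binary arrays), and
#'   `weights`.
#' @return Scalar total loss.
#' @export
composite_loss <- function(bundle) {
  no <- length(bundle$outputs)
  if (length(bundle$weights) != no || length(bundle$labels) != no)
    stop("outputs, labels and weights must have matching lengths")
  if (abs(sum(bundle$weights) - 1) > 1e-9)
    stop("weights must sum to 1")
  sum(vapply(seq_len(no), function(i)
    bundle$weights[i] * head_loss(bundle$outputs[[i]], bundle$labels[[i]]),
    numeric(1)))
}

#' Polynomial learning-rate decay
#'
#' `lr0 * (1 - iteration / total_iterations)^poly_exponent`: starts at
#' `lr0` and decays monotonically to 0 at the final iteration.
#'
#' @param iteration Current iteration, `0 <= iteration <=
#'   total_iterations`.
#' @param cfg A [train_config()] (uses `lr0`, `poly_exponent`,
#'   `total_iterations`).
#' @return Learning rate.
#' @export
poly_lr <- function(iteration, cfg) {
  if (iteration < 0 || iteration > cfg$total_iterations)
    stop("iteration must lie in [0, total_iterations]")
  cfg$lr0 * (1 - iteration / cfg$total_iterations)^cfg$poly_exponent
}
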
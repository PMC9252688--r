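# Training losses: binary cross-entropy, soft Dice, and the weighted
# composite tau * BCE + Dice used to train the network.  All losses
# micro-average over every pixel of the batch jointly.

#' Loss configuration
#'
#' @param tau Weight on the binary cross-entropy term of the composite
#'   loss.  The default 1.5e-3 balances the pixel-wise cross-entropy
#'   against the region-overlap Dice term.
#' @param gamma Dice smoothing constant added to numerator and
#'   denominator; keeps the loss defined when both prediction and truth
#'   are empty.
#' @param clamp_eps Probabilities are clamped to
#'   `[clamp_eps, 1 - clamp_eps]` before taking logarithms so the loss
#'   stays finite at saturated predictions.
#' @return An object of class `"loss_config"`.
#' @export
loss_config <- function(tau = 1.5e-3, gamma = 1.0, clamp_eps = 1e-7) {
  if (tau < 0) stop("tau must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (clamp_eps <= 0 || clamp_eps >= 0.5)
    stop("clamp_eps must be in (0, 0.5)")
  structure(list(tau = tau, gamma = gamma, clamp_eps = clamp_eps),
            class = "loss_config")
}

check_loss_inputs <- function(p, t) {
  if (length(p) != length(t))
    stop("prediction and truth have different lengths (",
         length(p), " vs ", length(t), ")")
  if (length(p) == 0L) stop("empty input")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (any(t != 0 & t != 1)) stop("truth labels must be 0 or 1")
}

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(t * log(p) + (1 - t) * log(1 - p))` over all N pixels,
#' with probabilities clamped away from 0 and 1.
#'
#' @param p Predicted per-pixel foreground probabilities (any numeric
#'   array; flattened).
#' @param t Ground-truth labels in `{0, 1}`, same length.
#' @param cfg A [loss_config()].
#' @return A single non-negative number.
#' @export
bce_loss <- function(p, t, cfg = loss_config()) {
  check_loss_inputs(p, t)
  .bce(as.numeric(p), as.numeric(t), cfg$clamp_eps)
}

.bce <- function(p, t, eps) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(pc) + (1 - t) * log(1 - pc))
}

.bce_grad <- function(p, t, eps) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  g <- -(t / pc - (1 - t) / (1 - pc)) / length(p)
  g[p < eps | p > 1 - eps] <- 0   # clamped region: flat
  g
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + gamma) / (sum(p^2) + sum(t^2) + gamma)`.
#' Zero for a perfect binary prediction; the smoothing constant `gamma`
#' prevents a vanishing denominator when both inputs are empty.
#'
#' @inheritParams bce_loss
#' @return A single number in `[0, 1]`.
#' @export
dice_loss <- function(p, t, cfg = loss_config()) {
  check_loss_inputs(p, t)
  .dice(as.numeric(p), as.numeric(t), cfg$gamma)
}

.dice <- function(p, t, gamma) {
  num <- 2 * sum(p * t) + gamma
  den <- sum(p * p) + sum(t * t) + gamma
  1 - num / den
}

.dice_grad <- function(p, t, gamma) {
  num <- 2 * sum(p * t) + gamma
  den <- sum(p * p) + sum(t * t) + gamma
  -(2 * t) / den + num * 2 * p / (den * den)
}

#' Weighted composite loss
#'
#' `tau * bce_loss + dice_loss`: the Dice term drives region overlap and
#' is robust to foreground/background imbalance, while the small
#' cross-entropy term keeps per-pixel gradients informative everywhere.
#'
#' @inheritParams bce_loss
#' @return A single non-negative number.
#' @export
composite_loss <- function(p, t, cfg = loss_config()) {
  check_loss_inputs(p, t)
  p <- as.numeric(p)
  t <- as.numeric(t)
  cfg$tau * .bce(p, t, cfg$clamp_eps) + .dice(p, t, cfg$gamma)
}

# Loss value + gradient w.r.t. p in one pass, for the training loop.
loss_value_grad <- function(p, t, which, cfg) {
  pv <- as.numeric(p)
  tv <- as.numeric(t)
  switch(which,
    bce = list(value = .bce(pv, tv, cfg$clamp_eps),
               grad = .bce_grad(pv, tv, cfg$clamp_eps)),
    dice = list(value = .dice(pv, tv, cfg$gamma),
                grad = .dice_grad(pv, tv, cfg$gamma)),
    composite = list(
      value = cfg$tau * .bce(pv, tv, cfg$clamp_eps) + .dice(pv, tv, cfg$gamma),
      grad = cfg$tau * .bce_grad(pv, tv, cfg$clamp_eps) +
        .dice_grad(pv, tv, cfg$gamma)),
    stop("unknown loss: ", which))
}
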
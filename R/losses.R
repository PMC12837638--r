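# Occlusion-aware loss arithmetic: focal and Dice losses on probability
# arrays plus the sign-driven adaptive weighting of their combination. These
# are standalone numeric operations (no autodiff, no training loop).

LOSS_EPS <- 1e-7
WEIGHT_FLOOR <- 1e-8

#' Focal loss for occlusion probabilities
#'
#' Per-element loss `(1 - pt)^2 * [-yt log(pt) - (1 - yt) log(1 - pt)]`,
#' averaged. The squared modulation factor down-weights easy examples so
#' training signal concentrates on hard, typically occluded, pixels.
#' Probabilities are clipped to `\[1e-7, 1 - 1e-7\]` before the logs.
#'
#' As printed, the modulation uses `(1 - pt)^2` for both label values. The
#' conventional focal loss modulates by the label-aligned probability
#' (`pt` for `yt = 0`); set `standard = TRUE` for that variant.
#'
#' @param pt predicted occlusion probabilities in (0, 1).
#' @param yt binary ground-truth labels, same shape.
#' @param standard use the label-aligned modulation factor.
#' @return mean loss (nats), a non-negative scalar.
#' @examples
#' focalLoss(0.5, 1) # 0.25 * log(2)
#' @export
focalLoss <- function(pt, yt, standard = FALSE) {
  if (length(pt) != length(yt)) stop("pt and yt must have the same length")
  pt <- pmin(pmax(as.numeric(pt), LOSS_EPS), 1 - LOSS_EPS)
  yt <- as.numeric(yt)
  if (any(yt != 0 & yt != 1)) stop("yt must be binary")
  ce <- -yt * log(pt) - (1 - yt) * log(1 - pt)
  mod <- if (standard) {
    palign <- yt * pt + (1 - yt) * (1 - pt)
    (1 - palign)^2
  } else {
    (1 - pt)^2
  }
  mean(mod * ce)
}

#' Dice loss between a probability map and a binary mask
#'
#' `1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)`. The smoothing term
#' `eps` rescues the all-empty case (loss 0 when both maps are empty) and
#' bounds the loss in \[0, 1\]; it directly targets overlap, mitigating
#' pixel-level class imbalance.
#'
#' @param p predicted probability map.
#' @param y binary mask, same shape.
#' @param eps smoothing constant, positive.
#' @return loss in \[0, 1\].
#' @examples
#' diceLoss(rep(0, 9), rep(1, 9)) # 1 - 1/10
#' @export
diceLoss <- function(p, y, eps = 1) {
  if (length(p) != length(y)) stop("p and y must have the same length")
  if (eps <= 0) stop("eps must be positive")
  p <- as.numeric(p); y <- as.numeric(y)
  1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
}

#' Sign-driven adaptive update of the focal/Dice weights
#'
#' Each weight takes a multiplicative step against the sign of its loss
#' gradient, `w * (1 - eta * sign(grad))`, is floored at 1e-8, and the pair
#' is renormalised to sum to one. A weight whose loss is still rising (its
#' gradient positive) is shrunk; one whose loss is falling grows, keeping the
#' two terms in balance. This is a deliberate reading of the adaptive rule:
#' taken literally, a raw `w * sign(grad) + 1e-8` step can flip or zero a
#' weight, which contradicts the balance it is meant to enforce.
#'
#' @param weights a [LossWeights-class].
#' @param gradAlpha,gradBeta signed scalar gradients of the current loss with
#'   respect to alpha and beta.
#' @param eta relative step size.
#' @return the updated [LossWeights-class] (alpha + beta = 1, both positive).
#' @examples
#' adaptWeights(lossWeights(0.5), gradAlpha = 1, gradBeta = -1)
#' @export
adaptWeights <- function(weights, gradAlpha, gradBeta, eta = 0.05) {
  stopifnot(is(weights, "LossWeights"))
  if (!is.finite(gradAlpha) || !is.finite(gradBeta)) stop("gradients must be finite")
  a <- max(weights@alpha * (1 - eta * sign(gradAlpha)), WEIGHT_FLOOR)
  b <- max(weights@beta * (1 - eta * sign(gradBeta)), WEIGHT_FLOOR)
  new("LossWeights", alpha = a / (a + b), beta = b / (a + b),
      wBase = weights@wBase)
}

#' Combined occlusion loss
#'
#' `wBase * (alpha * lFocal + beta * lDice)`: the base occlusion-loss weight
#' scales the whole adaptively weighted sum.
#'
#' @param lFocal focal-loss value, non-negative.
#' @param lDice Dice-loss value, non-negative.
#' @param weights a [LossWeights-class].
#' @return scalar total loss.
#' @examples
#' totalLoss(0.4, 0.2, lossWeights(0.5, wBase = 2)) # 0.6
#' @export
totalLoss <- function(lFocal, lDice, weights = lossWeights()) {
  stopifnot(is(weights, "LossWeights"))
  if (lFocal < 0 || lDice < 0) stop("component losses must be non-negative")
  weights@wBase * (weights@alpha * lFocal + weights@beta * lDice)
}
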
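# Online false-negative mining: foreground voxels the current model predicts
# as background (F with P < 0.5) get their per-voxel loss up-weighted by a
# constant factor. Only false negatives are emphasized — false positives keep
# weight 1, because partially annotated volumes contain true but unlabeled
# fibers that must not be punished harder.

#' Extract the on-the-fly false-negative voxel set
#'
#' `FN = F & (P < 0.5)`: label foreground the current segmentation misses.
#' The mask is a plain logical array; no gradient flows through its
#' construction (it re-weights the loss, it is not part of it).
#'
#' @param F Binary foreground label (0/1 array of any shape).
#' @param P Foreground probability in \[0,1\], same shape as `F`.
#' @return Logical array, `TRUE` exactly on false-negative voxels.
#' @export
extractFalseNegatives <- function(F, P) {
  if (!identical(dim(F), dim(P)) || length(F) != length(P))
    stop("F and P must have identical shape")
  if (any(P < 0) || any(P > 1)) stop("P must lie in [0, 1]")
  (F == 1) & (P < 0.5)
}

#' Build the per-voxel loss weight map
#'
#' Weight `wFN` on false-negative voxels, 1 elsewhere. `wFN = 1.5` was the
#' line-searched default; `wFN = 1` reduces to unweighted training.
#'
#' @param FN Logical false-negative mask from [extractFalseNegatives()].
#' @param wFN False-negative weight, >= 1.
#' @return Numeric array of weights, same shape as `FN`.
#' @export
buildWeightMap <- function(FN, wFN = 1.5) {
  if (wFN < 1) stop("wFN must be >= 1 (only false negatives are up-weighted)")
  w <- array(1, dim = if (is.null(dim(FN))) length(FN) else dim(FN))
  w[FN] <- wFN
  w
}

#' Weighted mean of per-voxel losses
#'
#' `(1/N) * sum(w * loss)` over all `N` entries (every batch, channel and
#' spatial position). The divisor is the voxel count `N`, not `sum(w)`, so
#' up-weighting false negatives strictly increases the loss they contribute.
#'
#' @param perVoxelLoss Numeric array of per-voxel losses.
#' @param weights Numeric array of the same shape.
#' @return Scalar loss.
#' @export
weightedVoxelLoss <- function(perVoxelLoss, weights) {
  if (length(perVoxelLoss) != length(weights))
    stop("loss and weight shapes differ")
  sum(weights * perVoxelLoss) / length(perVoxelLoss)
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(P * F) / (sum(P) + sum(F) + eps)`. Unweighted: Dice is a
#' set-overlap measure, not a per-voxel loss, so false-negative weights do
#' not apply to it by default (a weighted variant is available in the
#' training configuration).
#'
#' @param P Foreground probability array in \[0,1\].
#' @param F Binary foreground label of the same shape.
#' @param eps Smoothing constant.
#' @return Scalar loss in \[0, 1 + eps\].
#' @export
diceLoss <- function(P, F, eps = 1e-5) {
  1 - 2 * sum(P * F) / (sum(P) + sum(F) + eps)
}

# cross-entropy + dice for one head; returns loss components and the exact
# gradient w.r.t. the head's logits. z: [N,2] logits, f: length-N binary
# label, w: length-N voxel weights (FN map), wDice: up-weight dice too?
headLossGrad <- function(z, f, w, eps = 1e-5, wDice = FALSE) {
  n <- nrow(z)
  p <- softmax2(z)
  pf <- p[, 2]
  ce <- -(f * log(pmax(pf, 1e-12)) + (1 - f) * log(pmax(1 - pf, 1e-12)))
  ceLoss <- sum(w * ce) / n
  # d(weighted CE)/dz = (w/n) * (p - y)
  y <- cbind(1 - f, f)
  dzCE <- (w / n) * (p - y)
  # dice on the foreground channel
  dw <- if (wDice) w else rep(1, n)
  num <- 2 * sum(dw * pf * f)
  den <- sum(dw * pf) + sum(dw * f) + eps
  diceL <- 1 - num / den
  dpf <- -(2 * dw * f * den - num * dw) / den^2
  # chain through softmax: dz_c = p_c * (dp_c - sum_k dp_k p_k) with dp
  # nonzero only on channel 2
  s <- dpf * pf
  dzDice <- cbind(-p[, 1] * s, pf * dpf - pf * s)
  list(loss = ceLoss + diceL, ce = ceLoss, dice = diceL, dz = dzCE + dzDice)
}

# max-pool a binary label (length-N vector over dims) down one level so
# 1-voxel fibers survive for the auxiliary head
downsampleLabelMax <- function(f, dims) {
  mp <- maxpool3(matrix(f, ncol = 1), as.integer(dims))
  as.numeric(mp$y)
}

#' Deep-supervision loss over the two output heads
#'
#' Total loss `1.0 * (dice + weighted CE)(final head) + auxWeight * (dice +
#' weighted CE)(auxiliary head)`. The auxiliary head is compared against the
#' label max-pooled to its resolution (max pooling keeps 1-voxel fibers
#' foreground). With false-negative mining enabled, the CE weights come from
#' the final head's current prediction; a perfect prediction leaves the FN
#' set empty and the weighted loss equals the unweighted loss exactly.
#'
#' @param fw Output of [netForward()] (both heads' logits).
#' @param label Binary label array matching the input crop.
#' @param wFN False-negative weight (>= 1).
#' @param fnm Enable false-negative mining.
#' @param auxWeight Weight of the auxiliary head (default 0.5).
#' @param weightedDice Apply FN weights inside the dice term too.
#' @param withGrad Also return gradients w.r.t. both heads' logits.
#' @return List with `loss`, `ce`, `dice`, `nFN` and (optionally)
#'   `dFinal`, `dAux`.
#' @export
deepSupervisionLoss <- function(fw, label, wFN = 1.5, fnm = TRUE,
                                auxWeight = 0.5, weightedDice = FALSE,
                                withGrad = FALSE) {
  f <- as.numeric(label)
  stopifnot(length(f) == nrow(fw$final))
  p <- softmax2(fw$final)[, 2]
  if (fnm) {
    fnMask <- extractFalseNegatives(array(f), array(p))
    w <- as.numeric(buildWeightMap(fnMask, wFN))
    nFN <- sum(fnMask)
  } else {
    w <- rep(1, length(f))
    nFN <- 0L
  }
  hf <- headLossGrad(fw$final, f, w, wDice = weightedDice)
  fa <- downsampleLabelMax(f, fw$dims)
  if (fnm) {
    wa <- as.numeric(buildWeightMap(
      array(downsampleLabelMax(as.numeric(w > 1), fw$dims) > 0), wFN))
  } else {
    wa <- rep(1, length(fa))
  }
  ha <- headLossGrad(fw$aux, fa, wa, wDice = weightedDice)
  out <- list(loss = hf$loss + auxWeight * ha$loss,
              ce = hf$ce + auxWeight * ha$ce,
              dice = hf$dice + auxWeight * ha$dice,
              nFN = as.integer(nFN))
  if (withGrad) {
    out$dFinal <- hf$dz
    out$dAux <- auxWeight * ha$dz
  }
  out
}
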
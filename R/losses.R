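# Coupled segmentation loss: pixel-averaged multi-class cross entropy plus
# soft Dice, combined 0.6/0.4. Cross entropy drives per-pixel probability
# calibration; Dice, computed on softmax probabilities against the one-hot
# target, is insensitive to class imbalance and sharpens region overlap.

#' Loss configuration
#'
#' @param ce_weight weight of the cross-entropy term (default 0.6).
#' @param dice_weight weight of the Dice-loss term (default 0.4).
#' @param class_weights optional per-class cross-entropy weights.
#' @param ignore_index optional 0-based label value excluded from both
#'   terms.
#' @param dice_smooth small positive constant guarding empty-class ratios.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(ce_weight = 0.6, dice_weight = 0.4,
                        class_weights = NULL, ignore_index = NULL,
                        dice_smooth = 1e-6) {
  stopifnot(ce_weight >= 0, dice_weight >= 0, dice_smooth > 0)
  structure(list(ce_weight = ce_weight, dice_weight = dice_weight,
                 class_weights = class_weights, ignore_index = ignore_index,
                 dice_smooth = dice_smooth),
            class = "loss_config")
}

as_label_mask <- function(target) {
  d <- dim(target)
  if (is.null(d)) stop("target must be an array")
  if (length(d) == 2) dim(target) <- c(d, 1L)
  else if (length(d) != 3) stop("target must be [H, W, N] (or [H, W])")
  target
}

#' Pixel-averaged cross-entropy loss
#'
#' Mean over non-ignored pixels of the negative log softmax probability of
#' the true class, optionally class-weighted (a weighted mean in that
#' case).
#'
#' @param logits array `[H, W, K, N]`.
#' @param target 0-based integer mask `[H, W, N]` (values in `0..K-1` or
#'   the ignore index).
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(logits, target, cfg = loss_config()) {
  logits <- as_feature_map(logits)
  target <- as_label_mask(target)
  ag_value(ag_cross_entropy(as_node(logits), target, cfg$class_weights,
                            cfg$ignore_index))
}

ag_dice_loss <- function(logits, target, cfg) {
  d <- dim(ag_value(logits))
  K <- d[3]
  tgt <- as.integer(target)
  keep <- if (is.null(cfg$ignore_index)) rep(TRUE, length(tgt))
          else tgt != cfg$ignore_index
  if (!any(keep)) {
    warning("dice_loss: no non-ignored pixels; returning 0")
    return(ag_node(0))
  }
  if (any(tgt[keep] < 0L | tgt[keep] >= K))
    stop("target class out of range [0, ", K - 1, "]")
  npix <- d[1] * d[2] * d[4]
  onehot_m <- matrix(0, K, npix)
  lin <- tgt + 1L; lin[!keep] <- 1L
  onehot_m[cbind(lin, seq_len(npix))] <- 1
  onehot_m[, !keep] <- 0
  onehot <- aperm(array(onehot_m, dim = c(K, d[1], d[2], d[4])), c(2, 3, 1, 4))
  keep_arr <- aperm(array(rep(as.numeric(keep), each = K),
                          dim = c(K, d[1], d[2], d[4])), c(2, 3, 1, 4))
  p <- ag_softmax_c(logits)
  pm <- ag_mul(p, ag_node(keep_arr))
  inter <- ag_sum_c(ag_mul(pm, ag_node(onehot)))        # K-vector
  psum <- ag_sum_c(pm)
  gsum <- sum_c(onehot)
  s <- cfg$dice_smooth
  dice <- ag_div(ag_add_const(ag_scale(inter, 2), s),
                 ag_add_const(ag_add(psum, ag_node(gsum)), s))
  ag_add_const(ag_scale(ag_mean(dice), -1), 1)
}

#' Soft Dice loss
#'
#' Per class k, with A_k the softmax probability mass and B_k the one-hot
#' target mass over all non-ignored pixels:
#' `1 - mean_k (2 sum(A_k B_k) + s) / (sum(A_k) + sum(B_k) + s)`.
#'
#' @inheritParams cross_entropy_loss
#' @return scalar loss in `[0, 1]` (up to the smooth term).
#' @export
dice_loss <- function(logits, target, cfg = loss_config()) {
  logits <- as_feature_map(logits)
  target <- as_label_mask(target)
  ag_value(ag_dice_loss(as_node(logits), target, cfg))
}

ag_total_loss <- function(logits, target, cfg) {
  ce <- ag_cross_entropy(logits, target, cfg$class_weights, cfg$ignore_index)
  if (cfg$dice_weight == 0) return(ag_scale(ce, cfg$ce_weight))
  dl <- ag_dice_loss(logits, target, cfg)
  ag_add(ag_scale(ce, cfg$ce_weight), ag_scale(dl, cfg$dice_weight))
}

#' Coupled total loss
#'
#' `ce_weight * cross_entropy + dice_weight * dice_loss` (defaults 0.6 and
#' 0.4). The Dice term enters as a loss (1 - Dice coefficient) so that
#' better overlap always lowers the total.
#'
#' @inheritParams cross_entropy_loss
#' @return scalar loss.
#' @export
total_loss <- function(logits, target, cfg = loss_config()) {
  logits <- as_feature_map(logits)
  target <- as_label_mask(target)
  ag_value(ag_total_loss(as_node(logits), target, cfg))
}
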
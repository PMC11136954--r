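# SimAM: parameter-free 3-D attention. Each neuron t in a channel is scored
# by the closed-form minimum e* of a linear-separability energy: a neuron
# that is easy to separate from its peers (large |t - mu|) has low energy,
# and low energy maps to a high attention weight sigmoid(1/e*). The module
# holds no trainable weights.
#
# Energy of neuron t with channel moments mu, sigma^2 and regularizer lambda:
#   e* = 4 (sigma^2 + lambda) / ((t - mu)^2 + 2 sigma^2 + 2 lambda)
# and the output is sigmoid(1/e*) * x, elementwise.

#' SimAM configuration
#'
#' @param lambda_reg non-negative regularization constant of the energy
#'   function. Default 1e-4 (the value used by the original SimAM authors;
#'   never learned).
#' @param variance_denominator `"M-1"` (default, matching the 1/(M-1)
#'   averaging in the energy function) or `"M"`; M = H*W neurons per channel.
#' @return an object of class `simam_config`.
#' @export
simam_config <- function(lambda_reg = 1e-4,
                         variance_denominator = c("M-1", "M")) {
  variance_denominator <- match.arg(variance_denominator)
  if (!is.numeric(lambda_reg) || length(lambda_reg) != 1 || lambda_reg < 0)
    stop("lambda_reg must be a single non-negative number")
  structure(list(lambda_reg = lambda_reg,
                 variance_denominator = variance_denominator),
            class = "simam_config")
}

# Coerce input to the package's [H, W, C, N] layout.
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a ", class(x)[1])
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) dim(x) <- c(d, 1L)
  else if (length(d) != 4) stop("expected a 2-4 dimensional array")
  x
}

#' Per-channel spatial moments
#'
#' Mean and variance of every (channel, sample) slice over its H*W spatial
#' positions, the statistics entering the SimAM energy.
#'
#' @param x feature map `[H, W, C, N]` (lower-dimensional arrays are
#'   promoted).
#' @param cfg a [simam_config()].
#' @return list with `mean` and `variance`, each a C x N matrix.
#' @export
channel_moments <- function(x, cfg = simam_config()) {
  x <- as_feature_map(x)
  d <- dim(x)
  M <- d[1] * d[2]
  denom <- if (cfg$variance_denominator == "M-1") M - 1 else M
  if (denom < 1)
    stop("variance denominator M-1 requires at least 2 spatial positions")
  mu <- sum_hw(x) / M
  xc <- x - bcast_hw(mu, d[1], d[2])
  v <- sum_hw(xc * xc) / denom
  list(mean = mu, variance = v)
}

#' SimAM energy map
#'
#' Closed-form minimal energy e* of every neuron (Eq. above). Lower energy
#' means the neuron stands out from its channel.
#'
#' @inheritParams channel_moments
#' @return array of the same shape as `x` with e* values (all > 0 when
#'   `lambda_reg > 0`).
#' @export
simam_energy <- function(x, cfg = simam_config()) {
  x <- as_feature_map(x)
  if (!all(is.finite(x))) stop("simam: non-finite values in input")
  ag_value(ag_simam_energy(as_node(x), cfg))
}

ag_simam_energy <- function(x, cfg) {
  d <- dim(ag_value(x))
  M <- d[1] * d[2]
  denom <- if (cfg$variance_denominator == "M-1") M - 1 else M
  if (denom < 1)
    stop("variance denominator M-1 requires at least 2 spatial positions")
  lam <- cfg$lambda_reg
  mom <- channel_moments(ag_value(x), cfg)
  if (lam == 0 && any(mom$variance == 0))
    stop("simam: lambda_reg = 0 on a constant channel gives zero energy ",
         "denominator; use lambda_reg > 0")
  mu <- ag_mean_hw(x)                                   # C x N
  xc <- ag_sub(x, ag_bcast_hw(mu, d[1], d[2]))
  sq <- ag_mul(xc, xc)
  v <- ag_scale(ag_mean_hw(sq), M / denom)
  num <- ag_scale(ag_add_const(v, lam), 4)              # 4 (sigma^2 + lambda)
  den <- ag_add_const(ag_add(sq, ag_bcast_hw(ag_scale(v, 2), d[1], d[2])),
                      2 * lam)
  ag_div(ag_bcast_hw(num, d[1], d[2]), den)
}

#' Apply SimAM attention to a feature map
#'
#' Re-weights every activation by `sigmoid(1 / e*)`, where e* is the
#' neuron's closed-form energy; the output has the same shape as the input.
#'
#' @inheritParams channel_moments
#' @return re-weighted feature map.
#' @export
apply_simam <- function(x, cfg = simam_config()) {
  xm <- as_feature_map(x)
  if (!all(is.finite(xm))) stop("simam: non-finite values in input")
  out <- ag_value(ag_apply_simam(as_node(xm), cfg))
  dim(out) <- dim(xm)
  out
}

ag_apply_simam <- function(x, cfg) {
  e <- ag_simam_energy(x, cfg)
  ones <- array(1, dim = dim(ag_value(e)))
  w <- ag_sigmoid(ag_div(ag_node(ones), e))
  ag_mul(w, x)
}

# ---- closed-form neuron solution (used by the optimality oracle) -----------

#' Closed-form minimizer of the per-neuron energy
#'
#' For a target neuron value `t` and its M-1 channel peers, the energy
#' e(w, b) = (1/(M-1)) sum_i (-1 - (w x_i + b))^2 + (1 - (w t + b))^2
#'           + lambda w^2
#' is minimized in closed form by
#'   w = 2 (t - mu) / ((t - mu)^2 + 2 sigma^2 + 2 lambda),
#'   b = -(t + mu) w / 2,
#' with mu, sigma^2 the mean and (population) variance of the peers. The
#' attained minimum is 4 (sigma^2 + lambda) / ((t - mu)^2 + 2 sigma^2 +
#' 2 lambda).
#'
#' @param t scalar neuron value.
#' @param others numeric vector of the remaining M-1 neurons in the channel.
#' @param lambda_reg regularization constant.
#' @return list with `w`, `b` and the attained `energy`.
#' @export
simam_neuron_solution <- function(t, others, lambda_reg = 1e-4) {
  mu <- mean(others)
  s2 <- mean((others - mu)^2)
  D <- (t - mu)^2 + 2 * s2 + 2 * lambda_reg
  w <- 2 * (t - mu) / D
  b <- -(t + mu) * w / 2
  list(w = w, b = b, energy = 4 * (s2 + lambda_reg) / D)
}

#' Evaluate the per-neuron energy at arbitrary (w, b)
#'
#' @inheritParams simam_neuron_solution
#' @param w,b linear transform coefficients.
#' @return scalar energy.
#' @export
simam_neuron_energy <- function(w, b, t, others, lambda_reg = 1e-4) {
  mean((-1 - (w * others + b))^2) + (1 - (w * t + b))^2 + lambda_reg * w^2
}
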
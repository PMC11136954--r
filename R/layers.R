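# Network building blocks: plain conv / batch-norm layers plus the
# ERFnet-family modules reused by EPAnet (Non-bottleneck-1D residual block,
# concat downsampler, transposed-convolution upsampler) and the depthwise
# over-parameterized convolution (DO-Conv) primitive used by the FDPN
# connector.
#
# A "module" is an environment with `params` (named list of ag_param),
# `submodules` (named list of modules) and `forward(x, training)`.

new_module <- function(kind) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$params <- list()
  m$submodules <- list()
  class(m) <- c(paste0("epanet_", kind), "epanet_module")
  m
}

#' Collect all trainable parameters of a module tree
#' @param module a module created by one of the layer constructors.
#' @return named list of parameter nodes.
#' @export
collect_params <- function(module) {
  out <- module$params
  for (nm in names(module$submodules)) {
    sub <- collect_params(module$submodules[[nm]])
    if (length(sub)) names(sub) <- paste0(nm, ".", names(sub))
    out <- c(out, sub)
  }
  out
}

#' Count trainable scalars in a module tree
#' @param module a module.
#' @return integer number of trainable scalar parameters.
#' @export
count_params <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$value), numeric(1)))
}

# Kaiming-normal initialization for a conv weight [kh, kw, cin, cout].
init_conv_weight <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin, cout))
}

layer_conv2d <- function(kh, kw, cin, cout, stride = c(1L, 1L),
                         pad = c(0L, 0L), dil = c(1L, 1L), bias = TRUE) {
  m <- new_module("conv2d")
  m$params$weight <- ag_param(init_conv_weight(kh, kw, cin, cout))
  if (bias) m$params$bias <- ag_param(numeric(cout))
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$dil <- as.integer(dil)
  m$cin <- cin; m$cout <- cout
  m$forward <- function(x, training = FALSE) {
    ag_conv2d(x, m$params$weight, m$params$bias %||% NULL,
              stride = m$stride, pad = m$pad, dil = m$dil)
  }
  m
}

layer_conv_transpose2d <- function(cin, cout, bias = TRUE) {
  m <- new_module("conv_transpose2d")
  # adjoint conv weight: [3, 3, cout, cin]
  m$params$weight <- ag_param(init_conv_weight(3L, 3L, cout, cin))
  if (bias) m$params$bias <- ag_param(numeric(cout))
  m$cin <- cin; m$cout <- cout
  m$forward <- function(x, training = FALSE) {
    ag_conv_transpose2d(x, m$params$weight, m$params$bias %||% NULL)
  }
  m
}

layer_batchnorm <- function(C, eps = 1e-3, momentum = 0.1) {
  m <- new_module("batchnorm")
  m$params$gamma <- ag_param(rep(1, C))
  m$params$beta <- ag_param(numeric(C))
  m$running_mean <- numeric(C)
  m$running_var <- rep(1, C)
  m$eps <- eps; m$momentum <- momentum
  m$forward <- function(x, training = FALSE) {
    ag_batchnorm(x, m$params$gamma, m$params$beta, m, training,
                 momentum = m$momentum, eps = m$eps)
  }
  m
}

# ---- DO-Conv ----------------------------------------------------------------

#' Depthwise over-parameterized convolution (DO-Conv) layer
#'
#' Training-time composition of a per-input-channel depthwise operator `D`
#' (shape k^2 x D_mul per channel) with a conventional kernel `W` (shape
#' D_mul x cout per channel). The composed operator is mathematically equal
#' to a single conventional convolution with the folded kernel
#' `W'[, , i, ] = D_i %*% W_i`, which is how the forward pass evaluates it;
#' gradients flow to both factors, giving the over-parameterized training
#' dynamics. `D` is initialized to the identity fold so the layer starts
#' exactly equal to a plain convolution with `W`.
#'
#' @param cin,cout input / output channel counts.
#' @param k square kernel size.
#' @param d_mul depth multiplier, must be >= k^2 (default k^2).
#' @param stride,pad convolution geometry.
#' @param bias add a per-output-channel bias.
#' @return a module; `forward(x, training)` applies the layer.
#' @export
do_conv <- function(cin, cout, k, d_mul = k * k, stride = c(1L, 1L),
                    pad = c(0L, 0L), bias = TRUE) {
  if (d_mul < k * k) stop("do_conv: d_mul must be >= k*k (got ", d_mul, ")")
  m <- new_module("do_conv")
  D <- array(0, dim = c(k * k, d_mul, cin))
  for (i in seq_len(cin)) D[, seq_len(k * k), i] <- diag(k * k)
  W <- array(0, dim = c(d_mul, cin, cout))
  W[seq_len(k * k), , ] <- init_conv_weight(k, k, cin, cout)
  m$params$D <- ag_param(D)
  m$params$W <- ag_param(W)
  if (bias) m$params$bias <- ag_param(numeric(cout))
  m$k <- as.integer(k); m$cin <- cin; m$cout <- cout
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$forward <- function(x, training = FALSE) {
    folded <- ag_doconv_fold(m$params$D, m$params$W, m$k, m$cin, m$cout)
    ag_conv2d(x, folded, m$params$bias %||% NULL,
              stride = m$stride, pad = m$pad)
  }
  m
}

# Fold the DO-Conv factors into a conventional kernel [k, k, cin, cout].
ag_doconv_fold <- function(D, W, k, cin, cout) {
  D <- as_node(D); W <- as_node(W)
  Dv <- D$value; Wv <- W$value
  d_mul <- dim(Dv)[2]
  out <- array(0, dim = c(k, k, cin, cout))
  for (i in seq_len(cin)) {
    Di <- matrix(Dv[, , i], k * k, d_mul)
    Wi <- matrix(Wv[, i, ], d_mul, cout)
    out[, , i, ] <- array(Di %*% Wi, dim = c(k, k, cout))
  }
  ag_op(out, list(D, W), function(g) {
    dD <- array(0, dim = dim(Dv)); dW <- array(0, dim = dim(Wv))
    for (i in seq_len(cin)) {
      gi <- matrix(g[, , i, ], k * k, cout)
      Di <- matrix(Dv[, , i], k * k, d_mul)
      Wi <- matrix(Wv[, i, ], d_mul, cout)
      dD[, , i] <- gi %*% t(Wi)
      dW[, i, ] <- crossprod(Di, gi)
    }
    list(dD, dW)
  })
}

#' Fold a DO-Conv layer's factors into a plain convolution kernel
#'
#' @param layer a module created by [do_conv()].
#' @return numeric array `[k, k, cin, cout]`, the folded kernel.
#' @export
doconv_folded_kernel <- function(layer) {
  ag_value(ag_doconv_fold(layer$params$D, layer$params$W, layer$k,
                          layer$cin, layer$cout))
}

# ---- ERFnet-family blocks ---------------------------------------------------

#' Non-bottleneck-1D residual block
#'
#' Factorized residual block: 3x1 conv, ReLU, 1x3 conv, BN, ReLU, dilated
#' 3x1 conv, ReLU, dilated 1x3 conv, BN, dropout, identity shortcut, ReLU.
#' Channel count is preserved (the shortcut is the identity).
#'
#' @param channels channel width (input = output).
#' @param dilation dilation of the second factorized pair.
#' @param dropout_p dropout probability in `[0, 1)`, applied before the
#'   residual addition during training.
#' @return a module.
#' @export
non_bt_1d <- function(channels, dilation = 1L, dropout_p = 0) {
  stopifnot(channels >= 1, dilation >= 1, dropout_p >= 0, dropout_p < 1)
  d <- as.integer(dilation)
  m <- new_module("non_bt_1d")
  m$channels <- channels; m$dilation <- d; m$dropout_p <- dropout_p
  m$submodules$conv1 <- layer_conv2d(3L, 1L, channels, channels, pad = c(1L, 0L))
  m$submodules$conv2 <- layer_conv2d(1L, 3L, channels, channels, pad = c(0L, 1L))
  m$submodules$bn1 <- layer_batchnorm(channels)
  m$submodules$conv3 <- layer_conv2d(3L, 1L, channels, channels,
                                     pad = c(d, 0L), dil = c(d, 1L))
  m$submodules$conv4 <- layer_conv2d(1L, 3L, channels, channels,
                                     pad = c(0L, d), dil = c(1L, d))
  m$submodules$bn2 <- layer_batchnorm(channels)
  m$forward <- function(x, training = FALSE) {
    if (dim(ag_value(x))[3] != m$channels)
      stop("non_bt_1d: expected ", m$channels, " channels, got ",
           dim(ag_value(x))[3])
    s <- m$submodules
    h <- ag_relu(s$conv1$forward(x))
    h <- ag_relu(s$bn1$forward(s$conv2$forward(h), training))
    h <- ag_relu(s$conv3$forward(h))
    h <- s$bn2$forward(s$conv4$forward(h), training)
    h <- ag_dropout(h, m$dropout_p, training)
    ag_relu(ag_add(h, x))
  }
  m
}

#' Concat downsampler block
#'
#' Concatenation of a stride-2 3x3 convolution (`out - in` filters) with a
#' 2x2 max-pool of the input, followed by BN and ReLU; halves the spatial
#' size. When `cout <= cin` the block falls back to the convolution alone
#' with `cout` filters.
#'
#' @param cin,cout input / output channel counts.
#' @return a module.
#' @export
downsampler <- function(cin, cout) {
  m <- new_module("downsampler")
  m$cin <- cin; m$cout <- cout
  m$conv_only <- cout <= cin
  nconv <- if (m$conv_only) cout else cout - cin
  m$submodules$conv <- layer_conv2d(3L, 3L, cin, nconv,
                                    stride = c(2L, 2L), pad = c(1L, 1L))
  m$submodules$bn <- layer_batchnorm(cout)
  m$forward <- function(x, training = FALSE) {
    d <- dim(ag_value(x))
    if (d[1] %% 2L || d[2] %% 2L)
      stop("downsampler: H and W must be even, got ", d[1], "x", d[2])
    h <- if (m$conv_only) m$submodules$conv$forward(x)
         else ag_concat_c(list(m$submodules$conv$forward(x), ag_maxpool2(x)))
    ag_relu(m$submodules$bn$forward(h, training))
  }
  m
}

#' Transposed-convolution upsampler block
#'
#' Stride-2 3x3 transposed convolution doubling H and W, followed by BN and
#' ReLU unless `bn_relu = FALSE` (the network's final logits layer).
#'
#' @param cin,cout input / output channel counts.
#' @param bn_relu apply BN + ReLU after the transposed convolution.
#' @return a module.
#' @export
upsampler <- function(cin, cout, bn_relu = TRUE) {
  m <- new_module("upsampler")
  m$cin <- cin; m$cout <- cout; m$bn_relu <- bn_relu
  m$submodules$deconv <- layer_conv_transpose2d(cin, cout)
  if (bn_relu) m$submodules$bn <- layer_batchnorm(cout)
  m$forward <- function(x, training = FALSE) {
    h <- m$submodules$deconv$forward(x)
    if (m$bn_relu) h <- ag_relu(m$submodules$bn$forward(h, training))
    h
  }
  m
}

# Forward through a module on a plain array without recording gradients.
module_apply <- function(module, x, training = FALSE) {
  ag_value(module$forward(as_node(x), training))
}
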
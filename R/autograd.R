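# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Values are plain R arrays in [H, W, C, N] layout wrapped in "ag_node"
# environments. Operations record a vector-Jacobian-product closure on the
# active tape; ag_backward() walks the tape in reverse. Parameters are leaf
# nodes whose gradients accumulate across backward passes until zeroed.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_recording <- function() !is.null(.ag$tape)

#' Run an expression with gradient recording enabled
#'
#' Opens a fresh tape, evaluates `expr`, and returns its result. Call
#' [ag_backward()] on a scalar node produced inside before the tape is
#' replaced by the next `with_tape()` call.
#' @param expr expression building the computation graph.
#' @return the value of `expr`.
#' @keywords internal
with_tape <- function(expr) {
  old <- .ag$tape
  .ag$tape <- new.env(parent = emptyenv())
  .ag$tape$nodes <- vector("list", 256L)
  .ag$tape$n <- 0L
  on.exit(.ag$tape <- old)
  expr
}

ag_node <- function(value, parents = list(), vjp = NULL, tracked = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$vjp <- vjp
  node$tracked <- tracked
  class(node) <- "ag_node"
  if (tracked && !is.null(vjp)) {
    tp <- .ag$tape
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[tp$n]] <- node
  }
  node
}

#' Create a trainable parameter node
#' @param value numeric array holding the initial value.
#' @return an `ag_node` whose gradient accumulates across backward passes.
#' @keywords internal
ag_param <- function(value) {
  node <- ag_node(value)
  node$is_param <- TRUE
  node$grad <- array(0, dim = dim(value) %||% length(value))
  node
}

is_node <- function(x) inherits(x, "ag_node")
node_tracked <- function(x) is_node(x) && (isTRUE(x$tracked) || isTRUE(x$is_param))

#' Extract the plain array value from a node (identity on arrays)
#' @param x node or array.
#' @keywords internal
ag_value <- function(x) if (is_node(x)) x$value else x

as_node <- function(x) if (is_node(x)) x else ag_node(x)

track <- function(...) ag_recording() && any(vapply(list(...), node_tracked, logical(1)))

# Record an op result. `vjp(g)` must return a list of gradients aligned with
# `parents`; entries for untracked parents may be NULL.
ag_op <- function(value, parents, vjp) {
  if (ag_recording() && any(vapply(parents, node_tracked, logical(1)))) {
    ag_node(value, parents = parents, vjp = vjp, tracked = TRUE)
  } else {
    ag_node(value)
  }
}

accum_grad <- function(node, g) {
  if (!node_tracked(node)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the active tape
#' @param loss an `ag_node` holding a length-1 value.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  tp <- .ag$tape
  if (is.null(tp)) stop("ag_backward() called outside with_tape()")
  loss$grad <- 1
  for (k in rev(seq_len(tp$n))) {
    node <- tp$nodes[[k]]
    if (is.null(node$grad) || is.null(node$vjp)) next
    gs <- node$vjp(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) accum_grad(node$parents[[j]], gs[[j]])
    }
    node$grad <- NULL # free memory as we go
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- array(0, dim = dim(p$value) %||% length(p$value))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise ops --------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_div <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_op(av / bv, list(a, b),
        function(g) list(g / bv, -g * av / (bv * bv)))
}

ag_scale <- function(x, s) {
  x <- as_node(x)
  ag_op(x$value * s, list(x), function(g) list(g * s))
}

ag_add_const <- function(x, c) {
  x <- as_node(x)
  ag_op(x$value + c, list(x), function(g) list(g))
}

ag_relu <- function(x) {
  x <- as_node(x)
  mask <- x$value > 0
  ag_op(x$value * mask, list(x), function(g) list(g * mask))
}

ag_sigmoid <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$value))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

# ---- reductions and broadcasts ---------------------------------------------

ag_sum <- function(x) {
  x <- as_node(x)
  shp <- dim(x$value) %||% length(x$value)
  ag_op(sum(x$value), list(x), function(g) list(array(g, dim = shp)))
}

ag_mean <- function(x) {
  x <- as_node(x)
  n <- length(x$value)
  shp <- dim(x$value) %||% n
  ag_op(mean(x$value), list(x), function(g) list(array(g / n, dim = shp)))
}

# Per-(channel, sample) reduction over the spatial dims of [H,W,C,N];
# result is a C x N matrix.
sum_hw <- function(v) {
  d <- dim(v)
  matrix(colSums(matrix(v, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

# Broadcast a C x N matrix over spatial dims to [H,W,C,N].
bcast_hw <- function(m, H, W) {
  array(rep(as.vector(m), each = H * W), dim = c(H, W, nrow(m), ncol(m)))
}

# Broadcast a per-channel vector to [H,W,C,N].
bcast_c <- function(v, H, W, N) {
  array(rep(rep(v, each = H * W), N), dim = c(H, W, length(v), N))
}

# Per-channel sum over h, w, n.
sum_c <- function(v) rowSums(sum_hw(v))

ag_mean_hw <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  m <- sum_hw(x$value) / (d[1] * d[2])
  ag_op(m, list(x),
        function(g) list(bcast_hw(g / (d[1] * d[2]), d[1], d[2])))
}

ag_bcast_hw <- function(m, H, W) {
  m <- as_node(m)
  ag_op(bcast_hw(m$value, H, W), list(m), function(g) list(sum_hw(g)))
}

ag_sum_c <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  ag_op(sum_c(x$value), list(x),
        function(g) list(bcast_c(g, d[1], d[2], d[4])))
}

ag_concat_c <- function(xs) {
  xs <- lapply(xs, as_node)
  vals <- lapply(xs, `[[`, "value")
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  offsets <- c(0L, cumsum(cs))
  ag_op(out, xs, function(g) {
    lapply(seq_along(cs), function(k) {
      g[, , offsets[k] + seq_len(cs[k]), , drop = FALSE]
    })
  })
}

# ---- structural / convolution ops ------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L),
                      dil = c(1L, 1L)) {
  x <- as_node(x); w <- as_node(w)
  bnode <- if (is.null(b)) NULL else as_node(b)
  bias <- if (is.null(bnode)) numeric(0) else as.numeric(bnode$value)
  xv <- x$value; wv <- w$value
  y <- conv2d_fwd_cpp(xv, wv, bias, stride[1], stride[2], pad[1], pad[2],
                      dil[1], dil[2])
  parents <- if (is.null(bnode)) list(x, w) else list(x, w, bnode)
  ag_op(y, parents, function(g) {
    dx <- if (node_tracked(x))
      conv2d_bwd_input_cpp(g, wv, dim(xv)[1], dim(xv)[2], stride[1], stride[2],
                           pad[1], pad[2], dil[1], dil[2]) else NULL
    wb <- conv2d_bwd_weight_cpp(xv, g, dim(wv)[1], dim(wv)[2], stride[1],
                                stride[2], pad[1], pad[2], dil[1], dil[2])
    if (is.null(bnode)) list(dx, wb$dw) else list(dx, wb$dw, wb$db)
  })
}

# Transposed convolution, stride 2, 3x3 kernel, padding 1, output padding 1:
# exactly doubles H and W. `w` has shape [3, 3, Cout, Cin] (a conv weight of
# the adjoint convolution).
ag_conv_transpose2d <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  bnode <- if (is.null(b)) NULL else as_node(b)
  xv <- x$value; wv <- w$value
  d <- dim(xv)
  Ho <- 2L * d[1]; Wo <- 2L * d[2]
  y <- conv2d_bwd_input_cpp(xv, wv, Ho, Wo, 2L, 2L, 1L, 1L, 1L, 1L)
  if (!is.null(bnode)) y <- y + bcast_c(as.numeric(bnode$value), Ho, Wo, d[4])
  parents <- if (is.null(bnode)) list(x, w) else list(x, w, bnode)
  ag_op(y, parents, function(g) {
    dx <- if (node_tracked(x))
      conv2d_fwd_cpp(g, wv, numeric(0), 2L, 2L, 1L, 1L, 1L, 1L) else NULL
    dw <- conv2d_bwd_weight_cpp(g, xv, dim(wv)[1], dim(wv)[2],
                                2L, 2L, 1L, 1L, 1L, 1L)$dw
    if (is.null(bnode)) list(dx, dw) else list(dx, dw, sum_c(g))
  })
}

ag_maxpool2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  fw <- maxpool2_fwd_cpp(x$value)
  ag_op(fw$y, list(x),
        function(g) list(maxpool2_bwd_cpp(fw$idx, g, d[1], d[2])))
}

ag_avgpool <- function(x, k) {
  x <- as_node(x)
  d <- dim(x$value)
  ag_op(avgpool_fwd_cpp(x$value, k), list(x),
        function(g) list(avgpool_bwd_cpp(g, k, d[1], d[2])))
}

ag_upsample_nearest2 <- function(x) {
  x <- as_node(x)
  ag_op(upsample_nearest2_fwd_cpp(x$value), list(x),
        function(g) list(upsample_nearest2_bwd_cpp(g)))
}

ag_upsample_bilinear <- function(x, Ho, Wo) {
  x <- as_node(x)
  d <- dim(x$value)
  ag_op(upsample_bilinear_fwd_cpp(x$value, Ho, Wo), list(x),
        function(g) list(upsample_bilinear_bwd_cpp(g, d[1], d[2])))
}

ag_dropout <- function(x, p, training) {
  x <- as_node(x)
  if (!training || p <= 0) return(x)
  mask <- (array(stats::runif(length(x$value)), dim = dim(x$value)) >= p) / (1 - p)
  ag_op(x$value * mask, list(x), function(g) list(g * mask))
}

# Batch normalization over (H, W, N) per channel. `layer` is an environment
# holding running_mean / running_var, updated as a side effect in training.
ag_batchnorm <- function(x, gamma, beta, layer, training,
                         momentum = 0.1, eps = 1e-3) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  if (training) {
    mu <- sum_c(x$value) / m
    xc <- x$value - bcast_c(mu, H, W, N)
    v <- sum_c(xc * xc) / m
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var +
      momentum * v * m / max(m - 1, 1)
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
    xc <- x$value - bcast_c(mu, H, W, N)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * bcast_c(invstd, H, W, N)
  gv <- as.numeric(gamma$value)
  y <- xhat * bcast_c(gv, H, W, N) + bcast_c(as.numeric(beta$value), H, W, N)
  ag_op(y, list(x, gamma, beta), function(g) {
    dbeta <- sum_c(g)
    dgamma <- sum_c(g * xhat)
    dxhat <- g * bcast_c(gv, H, W, N)
    if (training) {
      s1 <- sum_c(dxhat)
      s2 <- sum_c(dxhat * xhat)
      dx <- (dxhat - bcast_c(s1 / m, H, W, N) -
               xhat * bcast_c(s2 / m, H, W, N)) *
        bcast_c(invstd, H, W, N)
    } else {
      dx <- dxhat * bcast_c(invstd, H, W, N)
    }
    list(dx, dgamma, dbeta)
  })
}

ag_softmax_c <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  ex <- exp(x$value - rep_c(smax_c(x$value), d[3]))
  den <- ssum_c(ex)                           # [H,W,N]
  p <- ex / rep_c(den, d[3])
  ag_op(p, list(x), function(g) {
    dot <- ssum_c(g * p)
    list(p * (g - rep_c(dot, d[3])))
  })
}

# Sum over the channel dim of [H,W,C,N], keeping [H,W,N].
ssum_c <- function(v) {
  d <- dim(v)
  out <- v[, , 1, , drop = FALSE]
  for (k in seq_len(d[3])[-1]) out <- out + v[, , k, , drop = FALSE]
  array(out, dim = d[c(1, 2, 4)])
}

# Channel-wise max of [H,W,C,N], keeping [H,W,N].
smax_c <- function(v) {
  d <- dim(v)
  out <- v[, , 1, , drop = FALSE]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, v[, , k, , drop = FALSE])
  array(out, dim = d[c(1, 2, 4)])
}

# Replicate an [H,W,N] array along a new channel dim -> [H,W,C,N].
rep_c <- function(v, C) {
  d <- dim(v)
  aperm(array(rep(as.vector(v), C), dim = c(d[1], d[2], d[3], C)),
        c(1, 2, 4, 3))
}

# Pixel-averaged multi-class cross entropy with optional class weights and
# ignore index. Targets are 0-based integers in [H,W,N].
ag_cross_entropy <- function(logits, target, class_weights = NULL,
                             ignore_index = NULL) {
  logits <- as_node(logits)
  d <- dim(logits$value)
  K <- d[3]
  ex <- exp(logits$value - rep_c(smax_c(logits$value), K))
  den <- ssum_c(ex)
  p <- ex / rep_c(den, K)                     # softmax probabilities
  tgt <- as.integer(target)
  keep <- if (is.null(ignore_index)) rep(TRUE, length(tgt)) else tgt != ignore_index
  if (any(tgt[keep] < 0L | tgt[keep] >= K))
    stop("target class out of range [0, ", K - 1, "]")
  if (!any(keep)) stop("cross_entropy: no non-ignored pixels")
  # per-pixel probability of the true class
  npix <- d[1] * d[2] * d[4]
  pm <- matrix(aperm(p, c(3, 1, 2, 4)), K, npix)   # channels x pixels
  lin <- tgt + 1L
  lin[!keep] <- 1L
  ptrue <- pm[cbind(lin, seq_len(npix))]
  wpix <- rep(1, npix)
  if (!is.null(class_weights)) wpix <- class_weights[lin]
  wpix[!keep] <- 0
  denom <- sum(wpix)
  loss <- sum(-log(pmax(ptrue, 1e-12)) * wpix) / denom
  ag_op(loss, list(logits), function(g) {
    onehot <- matrix(0, K, npix)
    onehot[cbind(lin, seq_len(npix))] <- 1
    dm <- (pm - onehot) * rep(wpix, each = K) * (g / denom)
    dl <- aperm(array(dm, dim = c(K, d[1], d[2], d[4])), c(2, 3, 1, 4))
    list(dl)
  })
}

#' Numerical gradient check helper
#'
#' Central-difference gradient of a scalar-valued function of one array,
#' used by the test suite to validate analytic backward passes.
#' @keywords internal
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
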
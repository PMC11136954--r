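# Point-wise spatial attention (PSA) decoder head.
#
# Each spatial position i of an H x W feature map predicts an over-complete
# (2H-1)(2W-1)-channel vector. Reshaped to a (2H-1) x (2W-1) plane, the
# valid H x W window aligned so that position i coincides with the plane
# centre yields that position's attention map over all positions j. The
# Collect branch gathers information to each position (z_i = mean_j a_ij x_j),
# the Distribute branch spreads it outward (z_j accumulates a_ij x_i); the
# two branches are structurally symmetric with independent weights.

#' PSA head configuration
#'
#' @param in_channels C1, channel width entering the head.
#' @param reduced_channels C2 <= C1, width after the 1x1 reduction (default
#'   `max(1, in_channels %/% 2)`).
#' @param max_attention_size spatial cap: if the incoming map is larger it
#'   is average-pooled below this size before attention (the over-complete
#'   representation grows as (H*W)^2, so a cap is what makes the head
#'   affordable away from the coarsest resolution). Default 32.
#' @return object of class `psa_head_config`.
#' @export
psa_head_config <- function(in_channels,
                            reduced_channels = max(1L, in_channels %/% 2L),
                            max_attention_size = 32L) {
  stopifnot(in_channels >= 1, reduced_channels >= 1, max_attention_size >= 1)
  if (reduced_channels > in_channels)
    stop("reduced_channels must not exceed in_channels")
  structure(list(in_channels = as.integer(in_channels),
                 reduced_channels = as.integer(reduced_channels),
                 max_attention_size = as.integer(max_attention_size)),
            class = "psa_head_config")
}

#' Number of over-complete channels for an H x W attention grid
#' @param H,W spatial size.
#' @return `(2H-1) * (2W-1)`.
#' @export
overcomplete_channels <- function(H, W) (2L * H - 1L) * (2L * W - 1L)

# Cache of gather-index matrices keyed by "HxW". lin[i, j] is the 1-based
# linear index into the (HW x Ch) per-sample matrix picking a_{i,j}.
.psa_cache <- new.env(parent = emptyenv())

psa_index_matrix <- function(H, W) {
  key <- paste0(H, "x", W)
  if (!is.null(.psa_cache[[key]])) return(.psa_cache[[key]])
  HW <- H * W
  p <- seq_len(HW)
  r <- (p - 1L) %% H            # 0-based row of each position
  cc <- (p - 1L) %/% H          # 0-based column
  # plane row/col indices for pair (i, j): (H-1-r_i+r_j, W-1-c_i+c_j),
  # plane stored column-major with 2H-1 rows.
  rr <- outer(-r, r, `+`) + (H - 1L)      # [i, j]
  ccc <- outer(-cc, cc, `+`) + (W - 1L)
  ch0 <- rr + (2L * H - 1L) * ccc          # 0-based channel index
  out <- list(ch0 = ch0, lin = matrix(p, HW, HW) + HW * ch0)
  .psa_cache[[key]] <- out
  out
}

# Fused adaption + attention crop: produces the attention node directly
# from the reduced features and the adaption layer's 1x1 kernel, without
# materializing the over-complete map (only the cropped entries are ever
# read). Numerically identical to adaption convolution + crop.
ag_psa_attention_fused <- function(xr, wgt, bias, H, W) {
  xr <- as_node(xr); wgt <- as_node(wgt); bias <- as_node(bias)
  ch0 <- psa_index_matrix(H, W)$ch0
  xv <- xr$value; wv <- wgt$value
  A <- psa_attn_fused_fwd_cpp(xv, wv, as.numeric(bias$value), ch0)
  ag_op(A, list(xr, wgt, bias), function(g) {
    gr <- psa_attn_fused_bwd_cpp(xv, wv, g, ch0, node_tracked(xr))
    list(gr$dx, gr$dw, gr$db)
  })
}

ag_psa_attention <- function(h, H, W) {
  h <- as_node(h)
  d <- dim(h$value)
  Ch <- overcomplete_channels(H, W)
  if (d[1] != H || d[2] != W || d[3] != Ch)
    stop("overcomplete map must be [", H, ",", W, ",", Ch, ",N]")
  HW <- H * W
  lin <- psa_index_matrix(H, W)$lin
  N <- d[4]
  A <- array(0, dim = c(HW, HW, N))
  hv <- h$value
  per <- HW * Ch
  linv <- as.vector(lin)                     # plain linear indices
  for (n in seq_len(N))
    A[, , n] <- hv[linv + (n - 1L) * per]    # gather, no slice copy
  ag_op(A, list(h), function(g) {
    dh <- array(0, dim = d)
    for (n in seq_len(N))
      dh[linv + (n - 1L) * per] <- g[, , n]  # gather indices are distinct
    list(dh)
  })
}

#' Attention maps from an over-complete representation
#'
#' For each position i = (r, c) the (2H-1)(2W-1) channel vector is reshaped
#' (column-major) to a (2H-1) x (2W-1) plane and the H x W window with rows
#' `[H-1-r, 2H-1-r)` and columns `[W-1-c, 2W-1-c)` is cropped, aligning
#' position i with the plane centre.
#'
#' @param h over-complete map `[H, W, (2H-1)(2W-1), N]` (3-d arrays are
#'   promoted to N = 1).
#' @return attention array `[H*W, H*W, N]`; `a[i, j, n]` weights position j
#'   as seen from position i.
#' @export
attention_from_overcomplete <- function(h) {
  h <- as_feature_map(h)
  ag_value(ag_psa_attention(as_node(h), dim(h)[1], dim(h)[2]))
}

ag_psa_aggregate <- function(x, a, branch = c("collect", "distribute")) {
  branch <- match.arg(branch)
  x <- as_node(x); a <- as_node(a)
  d <- dim(x$value)
  HW <- d[1] * d[2]
  N <- d[4]
  z <- array(0, dim = d)
  for (n in seq_len(N)) {
    Xn <- matrix(x$value[, , , n], HW, d[3])
    An <- a$value[, , n]
    Zn <- if (branch == "collect") An %*% Xn else crossprod(An, Xn)
    z[, , , n] <- array(Zn / HW, dim = d[1:3])
  }
  ag_op(z, list(x, a), function(g) {
    dx <- array(0, dim = d)
    da <- array(0, dim = dim(a$value))
    for (n in seq_len(N)) {
      Gn <- matrix(g[, , , n], HW, d[3]) / HW
      Xn <- matrix(x$value[, , , n], HW, d[3])
      An <- a$value[, , n]
      if (branch == "collect") {
        dx[, , , n] <- array(crossprod(An, Gn), dim = d[1:3])
        da[, , n] <- tcrossprod(Gn, Xn)
      } else {
        dx[, , , n] <- array(An %*% Gn, dim = d[1:3])
        da[, , n] <- tcrossprod(Xn, Gn)
      }
    }
    list(dx, da)
  })
}

#' Weighted aggregation of features by point-wise attention
#'
#' Collect: `z_i = (1/(H*W)) * sum_j a[i, j] x_j`. Distribute: `z_j =
#' (1/(H*W)) * sum_i a[i, j] x_i`.
#'
#' @param x reduced feature map `[H, W, C2, N]`.
#' @param a attention array `[H*W, H*W, N]` from
#'   [attention_from_overcomplete()].
#' @param branch `"collect"` or `"distribute"`.
#' @return aggregated feature map, same shape as `x`.
#' @export
psa_aggregate <- function(x, a, branch = c("collect", "distribute")) {
  x <- as_feature_map(x)
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
  ag_value(ag_psa_aggregate(as_node(x), as_node(a), branch))
}

#' Point-wise spatial attention decoder head
#'
#' Builds the full PSA head: optional average pooling below
#' `max_attention_size`; per branch a 1x1 reduction (BN + ReLU) and a 1x1
#' adaption convolution to the over-complete width (no BN on this final
#' projection); attention generation and aggregation for the Collect and
#' Distribute branches; concatenation of the two aggregates and a 1x1
#' projection back to C1; bilinear upsampling back to the input size when
#' pooled; concatenation with the head input (2*C1 channels) and a final
#' 1x1 convolution back to C1.
#'
#' The adaption and projection layers depend on the attention grid size, so
#' they are instantiated on first use for a given resolution and reused
#' afterwards.
#'
#' @param cfg a [psa_head_config()].
#' @return a module.
#' @export
psa_head <- function(cfg) {
  stopifnot(inherits(cfg, "psa_head_config"))
  m <- new_module("psa_head")
  m$cfg <- cfg
  C1 <- cfg$in_channels; C2 <- cfg$reduced_channels
  m$submodules$reduce_c <- layer_conv2d(1L, 1L, C1, C2)
  m$submodules$bn_c <- layer_batchnorm(C2)
  m$submodules$reduce_d <- layer_conv2d(1L, 1L, C1, C2)
  m$submodules$bn_d <- layer_batchnorm(C2)
  m$submodules$proj <- layer_conv2d(1L, 1L, 2L * C2, C1)
  m$submodules$out <- layer_conv2d(1L, 1L, 2L * C1, C1)
  m$adaption_for <- function(H, W, branch) {
    key <- paste0("adaption_", branch, "_", H, "x", W)
    if (is.null(m$submodules[[key]]))
      m$submodules[[key]] <- layer_conv2d(1L, 1L, C2,
                                          overcomplete_channels(H, W))
    m$submodules[[key]]
  }
  m$forward <- function(x, training = FALSE) psa_forward(m, x, training)
  m
}

psa_pool_factor <- function(H, W, max_size) {
  f <- max(ceiling(H / max_size), ceiling(W / max_size))
  if (f > 1L && (H %% f || W %% f))
    stop("psa_head: spatial size ", H, "x", W, " is not divisible by the ",
         "pooling factor ", f, " needed to respect max_attention_size = ",
         max_size, "; raise max_attention_size or change the input size")
  as.integer(f)
}

# One branch up to its aggregated feature Z (a node).
psa_branch <- function(m, xp, branch, training) {
  d <- dim(ag_value(xp))
  red <- if (branch == "collect") m$submodules$reduce_c else m$submodules$reduce_d
  bn <- if (branch == "collect") m$submodules$bn_c else m$submodules$bn_d
  xr <- ag_relu(bn$forward(red$forward(xp), training))
  ad <- m$adaption_for(d[1], d[2], branch)
  a <- ag_psa_attention_fused(xr, ad$params$weight, ad$params$bias,
                              d[1], d[2])
  ag_psa_aggregate(xr, a, branch)
}

psa_forward <- function(m, x, training = FALSE) {
  x <- as_node(x)
  if (!all(is.finite(ag_value(x)))) stop("psa_head: non-finite input")
  d <- dim(ag_value(x))
  if (d[3] != m$cfg$in_channels)
    stop("psa_head: expected ", m$cfg$in_channels, " channels, got ", d[3])
  f <- psa_pool_factor(d[1], d[2], m$cfg$max_attention_size)
  xp <- if (f > 1L) ag_avgpool(x, f) else x
  zc <- psa_branch(m, xp, "collect", training)
  zd <- psa_branch(m, xp, "distribute", training)
  z <- m$submodules$proj$forward(ag_concat_c(list(zc, zd)))
  if (f > 1L) z <- ag_upsample_bilinear(z, d[1], d[2])
  m$submodules$out$forward(ag_concat_c(list(x, z)))
}

#' Over-complete map of one PSA branch (inspection helper)
#'
#' Runs the head's pooling, reduction and adaption convolution for one
#' branch and returns the over-complete representation.
#'
#' @param head a module from [psa_head()].
#' @param x input feature map `[H, W, C1, N]`.
#' @param branch `"collect"` or `"distribute"`.
#' @return array `[H', W', (2H'-1)(2W'-1), N]` at the (possibly pooled)
#'   attention resolution.
#' @export
psa_overcomplete <- function(head, x, branch = c("collect", "distribute")) {
  branch <- match.arg(branch)
  x <- as_node(as_feature_map(x))
  d <- dim(ag_value(x))
  f <- psa_pool_factor(d[1], d[2], head$cfg$max_attention_size)
  xp <- if (f > 1L) ag_avgpool(x, f) else x
  dp <- dim(ag_value(xp))
  red <- if (branch == "collect") head$submodules$reduce_c else head$submodules$reduce_d
  bn <- if (branch == "collect") head$submodules$bn_c else head$submodules$bn_d
  xr <- ag_relu(bn$forward(red$forward(xp), FALSE))
  ag_value(head$adaption_for(dp[1], dp[2], branch)$forward(xr))
}
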
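# PSA head: over-complete channel counts, crop indexing against a naive
# double-loop oracle, aggregation against a dense matrix product, branch
# symmetry, full-head shapes and differentiability.

test_that("over-complete channel count is (2H-1)(2W-1)", {
  expect_equal(overcomplete_channels(2, 2), 9)
  expect_equal(overcomplete_channels(4, 3), 35)
  expect_equal(overcomplete_channels(1, 1), 1)
})

test_that("attention crops match the naive per-pair index oracle", {
  H <- 3; W <- 3
  set.seed(1)
  h <- array(rnorm(H * W * overcomplete_channels(H, W)),
             dim = c(H, W, overcomplete_channels(H, W), 1))
  a <- attention_from_overcomplete(h)
  expect_equal(dim(a), c(H * W, H * W, 1))
  # oracle: channel plane of position i reshaped (2H-1)x(2W-1), entry for
  # j = (r2, c2) sits at plane[H-1-r1+r2, W-1-c1+c2] (0-based)
  for (i in seq_len(H * W)) {
    r1 <- (i - 1) %% H; c1 <- (i - 1) %/% H
    plane <- array(h[r1 + 1, c1 + 1, , 1], dim = c(2 * H - 1, 2 * W - 1))
    for (j in seq_len(H * W)) {
      r2 <- (j - 1) %% H; c2 <- (j - 1) %/% H
      expect_equal(a[i, j, 1], plane[H - r1 + r2, W - c1 + c2])
    }
  }
})

test_that("degenerate attention grids behave: 1x1 single value, constant map", {
  h1 <- array(5, dim = c(1, 1, 1, 1))
  expect_equal(attention_from_overcomplete(h1)[1, 1, 1], 5)
  h2 <- array(1, dim = c(2, 2, 9, 1))
  expect_true(all(attention_from_overcomplete(h2) == 1))
})

test_that("aggregation equals the dense matrix-product oracle in both directions", {
  H <- 2; W <- 2
  set.seed(2)
  x <- array(rnorm(H * W * 3), dim = c(H, W, 3, 1))
  a <- array(rnorm(16), dim = c(4, 4, 1))
  X <- matrix(x[, , , 1], 4, 3)
  zc <- psa_aggregate(x, a, "collect")
  expect_equal(matrix(zc[, , , 1], 4, 3), a[, , 1] %*% X / 4)
  zd <- psa_aggregate(x, a, "distribute")
  expect_equal(matrix(zd[, , , 1], 4, 3), t(a[, , 1]) %*% X / 4)
  # uniform attention on constant features averages to the constant
  xc <- array(3, dim = c(2, 2, 1, 1))
  au <- array(1, dim = c(4, 4, 1))
  expect_equal(as.vector(psa_aggregate(xc, au, "collect")), rep(3, 4))
  # delta attention scaled by H*W reproduces x
  ad <- array(diag(4) * 4, dim = c(4, 4, 1))
  expect_equal(psa_aggregate(x, ad, "collect"), x)
})

test_that("the fused attention path equals adaption convolution plus crop", {
  H <- 4; W <- 4; C2 <- 3
  set.seed(3)
  Ch <- overcomplete_channels(H, W)
  xr <- array(rnorm(H * W * C2 * 2), dim = c(H, W, C2, 2))
  w <- array(rnorm(C2 * Ch) * 0.2, dim = c(1, 1, C2, Ch))
  b <- rnorm(Ch) * 0.1
  hc <- ag$conv2d_fwd_cpp(xr, w, b, 1L, 1L, 0L, 0L, 1L, 1L)
  a_ref <- attention_from_overcomplete(hc)
  a_fused <- ag$ag_value(ag$ag_psa_attention_fused(ag$ag_node(xr), w, b, H, W))
  expect_lt(max(abs(a_ref - a_fused)), 1e-12)
})

test_that("whole attention path equals a dense formulation for small grids", {
  # end to end: reduced features -> adaption -> crop -> aggregate, versus
  # an explicitly built (H*W) x (H*W) attention matrix applied by matmul
  for (hw in list(c(2, 2), c(3, 4))) {
    H <- hw[1]; W <- hw[2]
    set.seed(10 * H + W)
    C2 <- 2
    Ch <- overcomplete_channels(H, W)
    xr <- array(rnorm(H * W * C2), dim = c(H, W, C2, 1))
    w <- array(rnorm(C2 * Ch) * 0.3, dim = c(1, 1, C2, Ch))
    b <- rnorm(Ch) * 0.1
    a <- ag$ag_value(ag$ag_psa_attention_fused(ag$ag_node(xr), w, b, H, W))
    z <- psa_aggregate(xr, a, "collect")
    # dense oracle built entry by entry
    HW <- H * W
    Amat <- matrix(0, HW, HW)
    hc <- ag$conv2d_fwd_cpp(xr, w, b, 1L, 1L, 0L, 0L, 1L, 1L)
    for (i in seq_len(HW)) {
      r1 <- (i - 1) %% H; c1 <- (i - 1) %/% H
      plane <- array(hc[r1 + 1, c1 + 1, , 1], dim = c(2 * H - 1, 2 * W - 1))
      for (j in seq_len(HW)) {
        r2 <- (j - 1) %% H; c2 <- (j - 1) %/% H
        Amat[i, j] <- plane[H - r1 + r2, W - c1 + c2]
      }
    }
    z_ref <- Amat %*% matrix(xr[, , , 1], HW, C2) / HW
    expect_lt(max(abs(matrix(z[, , , 1], HW, C2) - z_ref)), 1e-5)
  }
})

test_that("head config validates and the head reports the right shapes", {
  expect_error(psa_head_config(8L, 16L), "exceed")
  cfg <- psa_head_config(16L)
  expect_equal(cfg$reduced_channels, 8L)
  set.seed(4)
  head <- psa_head(cfg)
  x <- rand_map(8, 8, 16, 2)
  y <- ag$module_apply(head, x)
  expect_equal(dim(y), dim(x))            # C1 out after the final 1x1
  # both branches are structurally symmetric: same parameter shapes
  pc <- collect_params(head)
  expect_equal(dim(pc[["reduce_c.weight"]]$value),
               dim(pc[["reduce_d.weight"]]$value))
  expect_equal(dim(pc[["adaption_collect_8x8.weight"]]$value),
               dim(pc[["adaption_distribute_8x8.weight"]]$value))
  expect_error(ag$module_apply(head, rand_map(8, 8, 4, 1)), "channels")
})

test_that("zero adaption weights give a zero over-complete map", {
  set.seed(5)
  head <- psa_head(psa_head_config(8L))
  x <- rand_map(4, 4, 8, 1)
  invisible(ag$module_apply(head, x))  # instantiate adaption layers
  adc <- head$submodules$adaption_collect_4x4
  adc$params$weight$value <- adc$params$weight$value * 0
  adc$params$bias$value <- adc$params$bias$value * 0
  expect_equal(max(abs(psa_overcomplete(head, x, "collect"))), 0)
  expect_equal(dim(psa_overcomplete(head, x, "collect"))[3],
               overcomplete_channels(4, 4))
})

test_that("oversized inputs are pooled below the cap and non-divisible sizes are rejected", {
  set.seed(6)
  head <- psa_head(psa_head_config(4L, 2L, max_attention_size = 8L))
  x <- rand_map(16, 16, 4, 1)
  y <- ag$module_apply(head, x)
  expect_equal(dim(y), dim(x))
  expect_true(!is.null(head$submodules$adaption_collect_8x8))
  head2 <- psa_head(psa_head_config(4L, 2L, max_attention_size = 6L))
  expect_error(ag$module_apply(head2, rand_map(16, 16, 4, 1)),
               "max_attention_size")
})

test_that("the head is differentiable on random input", {
  set.seed(7)
  head <- psa_head(psa_head_config(8L))
  x <- rand_map(8, 8, 8, 1)
  xn <- ag$ag_param(x)
  ag$with_tape({
    y <- head$forward(xn, TRUE)
    loss <- ag$ag_mean(ag$ag_mul(y, y))
    ag$ag_backward(loss)
  })
  expect_true(all(is.finite(xn$grad)))
  for (p in collect_params(head)) expect_true(all(is.finite(p$grad)))
  expect_error(ag$module_apply(head, x * NA), "non-finite")
})
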
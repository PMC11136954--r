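# ERFnet-family blocks: residual identity, shape contracts, parameter
# counts, pooling oracle, DO-Conv fold equivalence, differentiability.

test_that("non_bt_1d preserves shape and reduces to ReLU with zeroed weights", {
  set.seed(1)
  blk <- non_bt_1d(8L, dilation = 2L)
  x <- rand_map(6, 6, 8, 2)
  y <- ag$module_apply(blk, x)
  expect_equal(dim(y), dim(x))
  # zero all conv weights and BN scale: the residual path is all that is left
  for (p in collect_params(blk)) p$value <- p$value * 0
  y0 <- ag$module_apply(blk, x)
  expect_equal(y0, pmax(x, 0))
  expect_error(ag$module_apply(blk, rand_map(6, 6, 4, 1)), "channels")
})

test_that("non_bt_1d parameter count matches the factorized-conv formula", {
  C <- 64L
  blk <- non_bt_1d(C)
  # four 3x1/1x3 convs (3 C^2 weights + C bias each) + two BN (2C each)
  expect_equal(count_params(blk), 4 * (3 * C * C + C) + 2 * 2 * C)
})

test_that("non_bt_1d is deterministic without dropout and stochastic with it", {
  set.seed(2)
  blk <- non_bt_1d(4L, dropout_p = 0)
  x <- rand_map(4, 4, 4, 1)
  expect_identical(ag$module_apply(blk, x, training = TRUE),
                   ag$module_apply(blk, x, training = TRUE))
  blk2 <- non_bt_1d(4L, dropout_p = 0.5)
  set.seed(3); a <- ag$module_apply(blk2, x, training = TRUE)
  set.seed(4); b <- ag$module_apply(blk2, x, training = TRUE)
  expect_false(identical(a, b))
  # eval mode ignores dropout
  expect_identical(ag$module_apply(blk2, x), ag$module_apply(blk2, x))
})

test_that("downsampler halves the spatial size and concatenates conv with max-pool", {
  set.seed(5)
  ds <- downsampler(3L, 16L)
  x <- rand_map(64, 64, 3, 1)
  y <- ag$module_apply(ds, x)
  expect_equal(dim(y), c(32, 32, 16, 1))
  expect_error(ag$module_apply(ds, rand_map(7, 8, 3, 1)), "even")

  # the pooled branch of a constant image is constant, and pooling equals
  # a brute-force 2x2 window maximum
  xc <- array(2.5, dim = c(8, 8, 3, 1))
  pooled <- ag$ag_value(ag$ag_maxpool2(ag$ag_node(xc)))
  expect_equal(as.vector(pooled), rep(2.5, 4 * 4 * 3))
  xr <- rand_map(8, 10, 2, 2, seed = 6)
  pooled <- ag$ag_value(ag$ag_maxpool2(ag$ag_node(xr)))
  brute <- array(0, dim = c(4, 5, 2, 2))
  for (i in 1:4) for (j in 1:5) for (cc in 1:2) for (n in 1:2)
    brute[i, j, cc, n] <- max(xr[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), cc, n])
  expect_equal(pooled, brute)
})

test_that("downsampler falls back to conv-only when out <= in channels", {
  ds <- downsampler(8L, 4L)
  y <- ag$module_apply(ds, rand_map(8, 8, 8, 1, seed = 7))
  expect_equal(dim(y), c(4, 4, 4, 1))
})

test_that("upsampler doubles the spatial size exactly and round-trips with downsampler", {
  set.seed(8)
  up <- upsampler(8L, 4L)
  x <- rand_map(16, 16, 8, 1)
  y <- ag$module_apply(up, x)
  expect_equal(dim(y), c(32, 32, 4, 1))
  ds <- downsampler(4L, 8L)
  expect_equal(dim(ag$module_apply(ds, y)), dim(x))
  # final-layer variant: logits may be negative (no ReLU)
  up2 <- upsampler(8L, 3L, bn_relu = FALSE)
  y2 <- ag$module_apply(up2, x)
  expect_true(any(y2 < 0))
})

test_that("DO-Conv composed operator equals the single folded convolution", {
  for (k in c(1L, 3L)) {
    set.seed(10 + k)
    dc <- do_conv(4L, 6L, k, pad = c(k %/% 2L, k %/% 2L))
    x <- rand_map(8, 8, 4, 1)
    y <- ag$module_apply(dc, x)
    folded <- doconv_folded_kernel(dc)
    y_ref <- ag$conv2d_fwd_cpp(x, folded, as.numeric(dc$params$bias$value),
                               1L, 1L, k %/% 2L, k %/% 2L, 1L, 1L)
    expect_lt(max(abs(y - y_ref)), 1e-5)
  }
})

test_that("DO-Conv identity init folds to W and zero W gives zero output", {
  set.seed(12)
  dc <- do_conv(3L, 2L, 3L, pad = c(1L, 1L))
  # identity-fold at step 0: folded kernel == the W rows laid out as k x k
  folded <- doconv_folded_kernel(dc)
  W <- dc$params$W$value
  for (i in 1:3)
    expect_equal(array(folded[, , i, ], dim = c(9, 2)), W[1:9, i, ])
  # richer depth multiplier is accepted; smaller is not
  expect_error(do_conv(2L, 2L, 3L, d_mul = 4L), "d_mul")
  dc2 <- do_conv(2L, 2L, 3L, d_mul = 12L, pad = c(1L, 1L))
  x <- rand_map(6, 6, 2, 1)
  expect_equal(dim(ag$module_apply(dc2, x)), c(6, 6, 2, 1))
  # zero W: composed output is zero regardless of D
  dc2$params$W$value <- dc2$params$W$value * 0
  dc2$params$bias$value <- dc2$params$bias$value * 0
  dc2$params$D$value <- array(rnorm(length(dc2$params$D$value)),
                              dim = dim(dc2$params$D$value))
  expect_equal(max(abs(ag$module_apply(dc2, x))), 0)
})

test_that("every block is differentiable end to end", {
  set.seed(13)
  for (blk in list(non_bt_1d(4L, 2L), downsampler(4L, 8L),
                   upsampler(4L, 2L), do_conv(4L, 4L, 3L, pad = c(1L, 1L)))) {
    x <- rand_map(8, 8, 4, 1)
    xn <- ag$ag_param(x)
    ag$with_tape({
      y <- blk$forward(xn, TRUE)
      loss <- ag$ag_mean(ag$ag_mul(y, y))
      ag$ag_backward(loss)
    })
    for (p in collect_params(blk)) expect_true(all(is.finite(p$grad)))
    expect_true(all(is.finite(xn$grad)))
  }
})
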
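# Loss identities: cross entropy against a hand-applied softmax oracle,
# Dice against the set formula, total-loss linearity, differentiability.

hard_logits <- function(target, K = 3, scale = 50) {
  d <- dim(target)
  out <- array(-scale, dim = c(d[1], d[2], K, d[3]))
  for (n in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    out[i, j, target[i, j, n] + 1, n] <- scale
  out
}

test_that("cross entropy: perfect prediction 0, uniform logits log(K)", {
  set.seed(1)
  y <- array(sample(0:2, 4 * 4, TRUE), dim = c(4, 4, 1))
  expect_lt(cross_entropy_loss(hard_logits(y), y), 1e-10)
  expect_equal(cross_entropy_loss(array(0, dim = c(4, 4, 3, 1)), y), log(3))
  expect_error(cross_entropy_loss(array(0, dim = c(2, 2, 3, 1)),
                                  array(5L, dim = c(2, 2, 1))),
               "out of range")
})

test_that("cross entropy matches a fully hand-computed case", {
  # 2x2, 2 classes, explicit softmax arithmetic
  logits <- array(c(1, -1, 0.5, 2,    # class-0 plane
                    0, 1, -0.5, 0),   # class-1 plane
                  dim = c(2, 2, 2, 1))
  y <- array(c(0L, 1L, 1L, 0L), dim = c(2, 2, 1))
  p_true <- c(exp(1) / (exp(1) + exp(0)),
              exp(1) / (exp(-1) + exp(1)),
              exp(-0.5) / (exp(0.5) + exp(-0.5)),
              exp(2) / (exp(2) + exp(0)))
  expect_equal(cross_entropy_loss(logits, y), mean(-log(p_true)))
  # class weights: weighted mean
  cfg <- loss_config(class_weights = c(1, 3))
  w <- c(1, 3, 3, 1)
  expect_equal(cross_entropy_loss(logits, y, cfg),
               sum(w * -log(p_true)) / sum(w))
  # ignore_index removes pixels
  y2 <- y; y2[1, 1, 1] <- 9L
  cfg2 <- loss_config(ignore_index = 9L)
  expect_equal(cross_entropy_loss(logits, y2, cfg2), mean(-log(p_true[-1])))
})

test_that("dice loss: perfect 0, disjoint 1, hand case for half-probabilities", {
  set.seed(2)
  y <- array(sample(0:1, 16, TRUE), dim = c(4, 4, 1))
  expect_lt(dice_loss(hard_logits(y, K = 2), y), 1e-6)
  # hard, fully wrong 2-class prediction: intersection 0 for both classes
  expect_gt(dice_loss(hard_logits(1L - y, K = 2), y), 1 - 1e-6)
  # uniform logits on 2 classes: probabilities 0.5 everywhere;
  # per class: 2*(0.5*|B_k|) / (0.5*M + |B_k|)
  logits <- array(0, dim = c(4, 4, 2, 1))
  nb <- sum(y == 0); M <- 16
  d0 <- 2 * 0.5 * nb / (0.5 * M + nb)
  d1 <- 2 * 0.5 * (M - nb) / (0.5 * M + (M - nb))
  expect_equal(dice_loss(logits, y), 1 - mean(c(d0, d1)), tolerance = 1e-5)
})

test_that("total loss is the 0.6/0.4 combination and perfect prediction gives 0", {
  set.seed(3)
  y <- array(sample(0:2, 8 * 8 * 2, TRUE), dim = c(8, 8, 2))
  logits <- array(rnorm(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  cfg <- loss_config()
  expect_equal(total_loss(logits, y, cfg),
               0.6 * cross_entropy_loss(logits, y, cfg) +
                 0.4 * dice_loss(logits, y, cfg))
  expect_lt(total_loss(hard_logits(y), y), 1e-6)
  # custom weights honoured
  cfg2 <- loss_config(ce_weight = 0.3, dice_weight = 0.7)
  expect_equal(total_loss(logits, y, cfg2),
               0.3 * cross_entropy_loss(logits, y, cfg2) +
                 0.7 * dice_loss(logits, y, cfg2))
})

test_that("losses are non-negative and decrease in cross entropy at fixed Dice", {
  set.seed(4)
  for (rep in 1:5) {
    y <- array(sample(0:2, 16, TRUE), dim = c(4, 4, 1))
    logits <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3, 1))
    expect_gte(cross_entropy_loss(logits, y), 0)
    expect_gte(dice_loss(logits, y), 0)
    expect_gte(total_loss(logits, y), 0)
  }
  # total is monotone in its CE component by construction (linearity)
  y <- array(sample(0:2, 16, TRUE), dim = c(4, 4, 1))
  l1 <- array(rnorm(48), dim = c(4, 4, 3, 1))
  ce1 <- cross_entropy_loss(l1, y); dl1 <- dice_loss(l1, y)
  expect_equal(total_loss(l1, y), 0.6 * ce1 + 0.4 * dl1)
})

test_that("loss gradients are finite, even near-perfect, and match numeric gradients", {
  set.seed(5)
  y <- array(sample(0:2, 16, TRUE), dim = c(4, 4, 1))
  for (logits in list(array(rnorm(48), dim = c(4, 4, 3, 1)),
                      hard_logits(y, scale = 12))) {
    ln <- ag$ag_param(logits)
    ag$with_tape({
      loss <- ag$ag_total_loss(ln, y, loss_config())
      ag$ag_backward(loss)
    })
    expect_true(all(is.finite(ln$grad)))
    ng <- num_grad(function(l) total_loss(array(l, dim = dim(logits)), y),
                   logits, eps = 1e-5)
    expect_lt(max(abs(ng - ln$grad)), 1e-6)
  }
})

test_that("empty non-ignored region returns 0 with a warning for dice", {
  y <- array(9L, dim = c(2, 2, 1))
  logits <- array(rnorm(8), dim = c(2, 2, 2, 1))
  cfg <- loss_config(ignore_index = 9L)
  expect_warning(v <- dice_loss(logits, y, cfg), "no non-ignored")
  expect_equal(v, 0)
})
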
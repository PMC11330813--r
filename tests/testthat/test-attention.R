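test_that("squeeze-and-excitation matches its closed form and limits", {
  # gains forced to ~1: large positive second-layer bias
  se <- nn_se_block(8)
  se$params$w2$value[] <- 0
  se$params$b2$value[] <- 40
  x <- array(rnorm(1 * 6 * 6 * 8), c(1, 6, 6, 8))
  expect_equal(module_forward(se, x), x, tolerance = 1e-10)

  # reduction = channels with zeroed second layer: uniform gain sigmoid(0)=0.5
  se05 <- nn_se_block(8, reduction = 8)
  se05$params$w2$value[] <- 0
  se05$params$b2$value[] <- 0
  expect_equal(module_forward(se05, x), 0.5 * x)

  # constant-valued input: closed form through the two linear layers
  se2 <- nn_se_block(4, reduction = 2)
  v <- rep(3, 4)
  h <- pmax(v %*% se2$params$w1$value + se2$params$b1$value, 0)
  gains <- 1 / (1 + exp(-(h %*% se2$params$w2$value + se2$params$b2$value)))
  xc <- array(3, c(1, 5, 5, 4))
  out <- module_forward(se2, xc)
  expect_equal(out[1, 1, 1, ], 3 * as.vector(gains), tolerance = 1e-12)

  # shape contract: 32x32x64, reduction 16 -> hidden 4
  se3 <- nn_se_block(64, reduction = 16)
  expect_equal(se3$hidden, 4)
  x64 <- array(rnorm(32 * 32 * 64), c(1, 32, 32, 64))
  expect_equal(dim(module_forward(se3, x64)), c(1, 32, 32, 64))
})

test_that("channel attention follows the shared-MLP construction", {
  cam <- nn_channel_attention(4, reduction = 2)
  # spatially constant input: max pool equals average pool, w = sigmoid(2 MLP(v))
  xc <- array(rep(c(1, -2, 0.5, 3), each = 9), c(1, 3, 3, 4))
  v <- c(1, -2, 0.5, 3)
  mlp <- function(v) {
    h <- pmax(v %*% cam$params$w1$value + cam$params$b1$value, 0)
    as.vector(h %*% cam$params$w2$value + cam$params$b2$value)
  }
  expect_equal(as.vector(module_forward(cam, xc)),
               1 / (1 + exp(-2 * mlp(v))), tolerance = 1e-12)

  # hand-set weights on a toy map against manual matrix arithmetic
  cam2 <- nn_channel_attention(4, reduction = 2)
  cam2$params$w1$value <- matrix(seq(-0.3, 0.4, length.out = 16), 4, 4)
  cam2$params$b1$value <- c(0.1, -0.1, 0.2, 0)
  cam2$params$w2$value <- matrix(seq(0.2, -0.5, length.out = 16), 4, 4)
  cam2$params$b2$value <- c(0, 0.3, -0.2, 0.1)
  set.seed(3)
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  w <- module_forward(cam2, x)
  for (n in 1:2) {
    va <- apply(x[n, , , , drop = FALSE], 4, mean)
    vm <- apply(x[n, , , , drop = FALSE], 4, max)
    mlp2 <- function(v) {
      h <- pmax(v %*% cam2$params$w1$value + cam2$params$b1$value, 0)
      as.vector(h %*% cam2$params$w2$value + cam2$params$b2$value)
    }
    expect_equal(w[n, ], 1 / (1 + exp(-(mlp2(va) + mlp2(vm)))),
                 tolerance = 1e-12)
  }
  expect_true(all(w > 0 & w < 1))

  # invariant to spatial permutation
  perm <- sample(16)
  xp <- x
  for (n in 1:2) for (c in 1:4) xp[n, , , c] <- matrix(x[n, , , c][perm], 4)
  expect_equal(module_forward(cam2, xp), w)
})

test_that("the printed-equation channel-attention variant sums two sigmoids", {
  camp <- nn_channel_attention(6, combine = "sigmoid_then_sum")
  x <- array(rnorm(1 * 4 * 4 * 6), c(1, 4, 4, 6))
  w <- module_forward(camp, x)
  expect_true(all(w > 0 & w < 2))
  mlp <- function(v) {
    h <- pmax(v %*% camp$params$w1$value + camp$params$b1$value, 0)
    as.vector(h %*% camp$params$w2$value + camp$params$b2$value)
  }
  va <- apply(x[1, , , , drop = FALSE], 4, mean)
  vm <- apply(x[1, , , , drop = FALSE], 4, max)
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(as.vector(w), sig(mlp(va)) + sig(mlp(vm)), tolerance = 1e-12)
})

test_that("spatial attention reduces to one channel via the 7x7 convolution", {
  sam <- nn_spatial_attention()
  x <- array(rnorm(1 * 12 * 12 * 5), c(1, 12, 12, 5))
  w <- module_forward(sam, x)
  expect_equal(dim(w), c(1, 12, 12, 1))
  expect_true(all(w > 0 & w < 1))

  # channel-constant input: mean map equals max map
  xc <- array(rep(rnorm(36), times = 3), c(1, 6, 6, 3))
  wc <- module_forward(sam, xc)
  kernel <- array(sam$children$conv$params$w$value, c(7, 7, 2, 1))
  pooled <- array(0, c(1, 6, 6, 2))
  pooled[1, , , 1] <- xc[1, , , 1]
  pooled[1, , , 2] <- xc[1, , , 1]
  direct <- naive_conv(pooled, kernel, sam$children$conv$params$b$value)
  expect_equal(wc, 1 / (1 + exp(-direct)), tolerance = 1e-4)

  # 5x5 toy grid with a hand-set kernel against the direct convolution oracle
  sam2 <- nn_spatial_attention()
  k <- array(0, c(7, 7, 2, 1))
  k[4, 4, 1, 1] <- 1    # identity tap on the mean map
  k[3, 5, 2, 1] <- -0.5 # one off-centre tap on the max map
  sam2$children$conv$params$w$value <- matrix(k, ncol = 1)
  sam2$children$conv$params$b$value <- 0.2
  x5 <- array(rnorm(1 * 5 * 5 * 3), c(1, 5, 5, 3))
  pooled5 <- array(0, c(1, 5, 5, 2))
  pooled5[1, , , 1] <- apply(x5[1, , , ], c(1, 2), mean)
  pooled5[1, , , 2] <- apply(x5[1, , , ], c(1, 2), max)
  expect_equal(module_forward(sam2, x5),
               1 / (1 + exp(-naive_conv(pooled5, k, 0.2))), tolerance = 1e-4)
})

test_that("CBAM composes channel then spatial attention and contracts magnitudes", {
  cb <- nn_cbam(4)
  set.seed(9)
  x <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
  out <- module_forward(cb, x)
  expect_equal(dim(out), dim(x))
  expect_true(all(abs(out) <= abs(x)))

  # equals sequential application of its own submodules
  wch <- module_forward(cb$children$cam, x)
  xp <- x
  for (c in 1:4) xp[1, , , c] <- x[1, , , c] * wch[1, c]
  wsp <- module_forward(cb$children$sam, xp)
  expected <- xp
  for (c in 1:4) expected[1, , , c] <- xp[1, , , c] * wsp[1, , , 1]
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("the attention gate rescales the skip by coefficients in (0,1)", {
  ag <- nn_attention_gate(8)
  gate <- array(rnorm(1 * 6 * 6 * 8), c(1, 6, 6, 8))
  skip <- array(rnorm(1 * 6 * 6 * 8), c(1, 6, 6, 8))
  out <- module_forward(ag, gate, skip)
  expect_equal(dim(out), dim(skip))
  expect_true(all(abs(out) < abs(skip) | skip == 0))

  # alpha -> 1: large positive shift in the final batch norm
  ag1 <- nn_attention_gate(8)
  ag1$children$psi$children$bn$params$beta$value <- 60
  expect_equal(module_forward(ag1, gate, skip), skip, tolerance = 1e-8)

  # alpha -> 0: large negative shift (background suppression limit)
  ag0 <- nn_attention_gate(8)
  ag0$children$psi$children$bn$params$beta$value <- -60
  expect_equal(max(abs(module_forward(ag0, gate, skip))), 0, tolerance = 1e-8)

  expect_error(module_forward(ag, gate, skip[, 1:3, , , drop = FALSE]),
               "mismatch")
})

test_that("attention-gate coefficients match scalar arithmetic on a 2x2 toy", {
  ag <- nn_attention_gate(2, inter_channels = 1)
  neutral_bn(ag)
  wg <- matrix(c(0.5, -0.25), 2, 1)
  wx <- matrix(c(1, 0.75), 2, 1)
  wpsi <- matrix(2, 1, 1)
  ag$children$theta_g$children$conv$params$w$value <- wg
  ag$children$theta_g$children$conv$params$b$value <- 0.1
  ag$children$theta_x$children$conv$params$w$value <- wx
  ag$children$theta_x$children$conv$params$b$value <- -0.2
  ag$children$psi$children$conv$params$w$value <- wpsi
  ag$children$psi$children$conv$params$b$value <- 0.05
  gate <- array(c(1, -1, 0.5, 2, 0.3, 0, -0.7, 1.2), c(1, 2, 2, 2))
  skip <- array(rnorm(8), c(1, 2, 2, 2))
  out <- module_forward(ag, gate, skip)
  for (h in 1:2) for (w in 1:2) {
    g1 <- sum(gate[1, h, w, ] * wg) + 0.1
    x1 <- sum(skip[1, h, w, ] * wx) - 0.2
    a <- 1 / (1 + exp(-(2 * max(g1 + x1, 0) + 0.05)))
    expect_equal(out[1, h, w, ], skip[1, h, w, ] * a, tolerance = 1e-12)
  }
})
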
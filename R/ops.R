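# Tensor operations on the autodiff tape.  Feature maps are (N*H*W) x C
# matrices with a dims attribute (see fm_new); channel descriptors are N x C
# matrices; spatial gain maps are feature maps with one channel.
#
# Memory discipline: backward closures capture as little as possible.  Parent
# node values are still alive when a node's backward runs (consumers are
# processed first), so anything derivable from them is recomputed there
# instead of being captured.

# replicate an N x C matrix down the rows of the (N*H*W) x C flattening
.rep_rows <- function(n, hw) rep.int(seq_len(n), hw)

.as_grad <- function(g, d) cpp_set_fmd(g, as.integer(d))

# ---- convolution -----------------------------------------------------------

# Shape-preserving k x k convolution with dilation; pad = dil * (k - 1) / 2.
# w: node holding a (k*k*Cin) x Cout matrix; b: node holding length-Cout bias
# (or NULL).
op_conv <- function(tape, x, w, b, k, dilation = 1L) {
  d <- fm_dims(x$value)
  pad <- as.integer(dilation * (k - 1L) / 2L)
  stopifnot(nrow(w$value) == k * k * d[4])
  dout <- c(d[1:3], ncol(w$value))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  if (k == 1L) {
    ym <- x$value %*% w$value
    if (!is.null(b)) ym <- cpp_col_affine(ym, nrow(ym), rep(1, ncol(ym)),
                                          b$value)
    return(ag_node(tape, fm_new(ym, dout), parents, function(g) {
      g <- .as_grad(g, dout)
      dx <- fm_new(g %*% t(w$value), d)
      dw <- crossprod(x$value, g)
      if (is.null(b)) list(dx, dw) else list(dx, dw, colSums(g))
    }))
  }
  bias <- if (is.null(b)) numeric(0) else b$value
  val <- cpp_conv2d_fw(x$value, as.integer(d), w$value, bias,
                       as.integer(k), as.integer(dilation), pad)
  ag_node(tape, fm_new(val, dout), parents, function(g) {
    bw <- cpp_conv2d_bw(x$value, g, as.integer(d), w$value,
                        as.integer(k), as.integer(dilation), pad)
    dx <- fm_new(bw$dx, d)
    if (is.null(b)) list(dx, bw$dw) else list(dx, bw$dw, bw$db)
  })
}

# 2x2 stride-2 transposed convolution.  w: node holding a Cin x (4*Cout)
# matrix whose column index is kh + 2*kw + 4*(co-1) (see conv_transpose_weight).
op_conv_transpose2 <- function(tape, x, w, b) {
  d <- fm_dims(x$value)
  cout <- ncol(w$value) %/% 4L
  dout <- c(d[1], 2L * d[2], 2L * d[3], cout)
  y <- cpp_pixelshuffle2_fw(x$value %*% w$value, as.integer(d), cout)
  if (!is.null(b)) {
    y <- cpp_col_affine(y, prod(dout[1:3]), rep(1, cout), b$value)
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(tape, fm_new(y, dout), parents, function(g) {
    g <- .as_grad(g, dout)
    gm <- cpp_pixelshuffle2_bw(g, as.integer(d), cout)
    dim(gm) <- c(prod(d[1:3]), 4L * cout)
    dx <- fm_new(gm %*% t(w$value), d)
    dw <- crossprod(x$value, gm)
    if (is.null(b)) list(dx, dw) else list(dx, dw, colSums(g))
  })
}

# Build the internal Cin x (4*Cout) matrix from an array dim c(2,2,Cin,Cout).
conv_transpose_weight <- function(arr) {
  d <- dim(arr)
  stopifnot(length(d) == 4L, d[1] == 2L, d[2] == 2L)
  matrix(aperm(arr, c(3L, 1L, 2L, 4L)), nrow = d[3])
}

# ---- pooling and resampling ------------------------------------------------

op_maxpool2 <- function(tape, x) {
  d <- fm_dims(x$value)
  dout <- c(d[1], d[2] %/% 2L, d[3] %/% 2L, d[4])
  fw <- cpp_maxpool2_fw(x$value, as.integer(d))
  idx <- fw$idx
  y <- fm_new(fw$y, dout)
  rm(fw)
  ag_node(tape, y, list(x), function(g) {
    dx <- numeric(prod(d))
    dx[idx] <- g
    list(fm_new(dx, d))
  })
}

# nearest-neighbour x2 upsampling
op_upsample2 <- function(tape, x) {
  d <- fm_dims(x$value)
  dout <- c(d[1], 2L * d[2], 2L * d[3], d[4])
  val <- fm_new(cpp_upsample2_fw(x$value, as.integer(d)), dout)
  ag_node(tape, val, list(x), function(g) {
    list(fm_new(cpp_upsample2_bw(g, as.integer(d)), d))
  })
}

# ---- normalisation ---------------------------------------------------------

# Batch normalisation over (N, H, W) per channel.  `layer` is the module
# environment carrying running statistics; gamma/beta are parameter nodes.
op_batch_norm <- function(tape, x, gamma, beta, layer, train) {
  d <- fm_dims(x$value)
  m <- prod(d[1:3])
  if (train) {
    mv <- cpp_col_meanvar(x$value, m)
    mu <- mv$mean
    va <- mv$var
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * va
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  s <- sqrt(va + layer$eps)
  xhat <- cpp_col_affine(x$value, m, 1 / s, -mu / s)
  dim(xhat) <- c(m, d[4])
  val <- fm_new(cpp_col_affine(xhat, m, gamma$value, beta$value), d)
  ag_node(tape, val, list(x, gamma, beta), function(g) {
    g <- .as_grad(g, d)
    dbeta <- colSums(g)
    dgamma <- colSums(g * xhat)
    if (train) {
      dxm <- cpp_bn_bw(g, xhat, m, dbeta, dgamma, gamma$value / s)
    } else {
      dxm <- cpp_col_affine(g, m, gamma$value / s, numeric(d[4]))
    }
    list(fm_new(dxm, d), dgamma, dbeta)
  })
}

# ---- elementwise -----------------------------------------------------------

op_relu <- function(tape, x) {
  d <- fm_dims(x$value)
  ag_node(tape, fm_new(cpp_relu_fw(x$value), d), list(x),
          function(g) list(fm_new(cpp_relu_bw(g, x$value), d)))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

op_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

# ---- channel-dimension reshuffles ------------------------------------------

op_concat <- function(tape, xs) {
  d1 <- fm_dims(xs[[1]]$value)
  cc <- vapply(xs, function(x) fm_dims(x$value)[4], 1L)
  val <- fm_new(do.call(cbind, lapply(xs, function(x) x$value)),
                c(d1[1:3], sum(cc)))
  ends <- cumsum(cc)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ag_node(tape, val, xs, function(g) {
    g <- .as_grad(g, c(d1[1:3], sum(cc)))
    lapply(seq_along(cc), function(i) {
      fm_new(g[, starts[i]:ends[i], drop = FALSE], c(d1[1:3], cc[i]))
    })
  })
}

# multiply feature map by per-channel gains (N x C matrix node)
op_mul_channel <- function(tape, x, wch) {
  d <- fm_dims(x$value)
  rn <- .rep_rows(d[1], d[2] * d[3])
  val <- fm_new(x$value * wch$value[rn, , drop = FALSE], d)
  ag_node(tape, val, list(x, wch), function(g) {
    g <- .as_grad(g, d)
    dx <- fm_new(g * wch$value[rn, , drop = FALSE], d)
    dw <- rowsum(g * x$value, rn)
    dimnames(dw) <- NULL
    list(dx, dw)
  })
}

# multiply feature map by a spatial gain map (N, H, W, 1)
op_mul_spatial <- function(tape, x, wsp) {
  d <- fm_dims(x$value)
  val <- fm_new(x$value * as.vector(wsp$value), d)
  ag_node(tape, val, list(x, wsp), function(g) {
    g <- .as_grad(g, d)
    dx <- fm_new(g * as.vector(wsp$value), d)
    dw <- fm_new(rowSums(g * x$value), c(d[1:3], 1L))
    list(dx, dw)
  })
}

# ---- global and channel-wise pooling ---------------------------------------

# global average pool -> N x C
op_gap <- function(tape, x) {
  d <- fm_dims(x$value)
  hw <- d[2] * d[3]
  rn <- .rep_rows(d[1], hw)
  val <- rowsum(x$value, rn) / hw
  dimnames(val) <- NULL
  ag_node(tape, val, list(x), function(g) {
    list(fm_new(g[rn, , drop = FALSE] / hw, d))
  })
}

# global max pool -> N x C
op_gmp <- function(tape, x) {
  d <- fm_dims(x$value)
  hw <- d[2] * d[3]
  val <- matrix(0, d[1], d[4])
  idx <- matrix(0L, d[1], d[4])
  for (n in seq_len(d[1])) {
    rows <- seq.int(n, by = d[1], length.out = hw)
    sub <- x$value[rows, , drop = FALSE]
    j <- vapply(seq_len(d[4]), function(c) which.max(sub[, c]), 1L)
    val[n, ] <- sub[cbind(j, seq_len(d[4]))]
    idx[n, ] <- rows[j]
  }
  ag_node(tape, val, list(x), function(g) {
    dxm <- matrix(0, prod(d[1:3]), d[4])
    dxm[cbind(as.vector(idx), rep(seq_len(d[4]), each = d[1]))] <- as.vector(g)
    list(fm_new(dxm, d))
  })
}

# per-pixel mean over channels -> (N, H, W, 1)
op_chan_mean <- function(tape, x) {
  d <- fm_dims(x$value)
  val <- fm_new(rowMeans(x$value), c(d[1:3], 1L))
  ag_node(tape, val, list(x), function(g) {
    list(fm_new(matrix(as.vector(g) / d[4], prod(d[1:3]), d[4]), d))
  })
}

# per-pixel max over channels -> (N, H, W, 1)
op_chan_max <- function(tape, x) {
  d <- fm_dims(x$value)
  j <- max.col(x$value, ties.method = "first")
  rows <- seq_len(prod(d[1:3]))
  val <- fm_new(x$value[cbind(rows, j)], c(d[1:3], 1L))
  ag_node(tape, val, list(x), function(g) {
    dxm <- matrix(0, prod(d[1:3]), d[4])
    dxm[cbind(rows, j)] <- as.vector(g)
    list(fm_new(dxm, d))
  })
}

# ---- fully connected (on N x C matrices) -----------------------------------

op_fc <- function(tape, x, w, b) {
  ym <- x$value %*% w$value
  if (!is.null(b)) ym <- sweep(ym, 2L, b$value, "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(tape, ym, parents, function(g) {
    dx <- g %*% t(w$value)
    dw <- crossprod(x$value, g)
    if (is.null(b)) list(dx, dw) else list(dx, dw, colSums(g))
  })
}

op_mat_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

op_mat_relu <- function(tape, x) {
  ag_node(tape, x$value * (x$value > 0), list(x),
          function(g) list(g * (x$value > 0)))
}

op_mat_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

# ---- loss ------------------------------------------------------------------

# Smoothed Dice loss, averaged over the images of the batch.
# p: one-channel probability feature-map node; truth: 0/1 values of the same
# length (any shape).
op_dice_loss <- function(tape, p, truth, eps = 1) {
  d <- fm_dims(p$value)
  rn <- .rep_rows(d[1], d[2] * d[3])
  pv <- as.vector(p$value)
  gv <- as.vector(truth)
  num <- 2 * rowsum(pv * gv, rn) + eps
  den <- rowsum(pv, rn) + rowsum(gv, rn) + eps
  loss <- mean(1 - num / den)
  rm(pv, truth)
  ag_node(tape, loss, list(p), function(g) {
    dp <- -(2 * gv * den[rn] - num[rn]) / (den[rn]^2) / d[1]
    list(fm_new(g * dp, d))
  })
}
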
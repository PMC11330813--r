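# Attention primitives: squeeze-and-excitation, channel attention (CAM),
# spatial attention (SAM), their composition CBAM, and the attention gate used
# on the decoder skip connections.

se_hidden <- function(channels, reduction, floor = 4L) {
  max(as.integer(channels %/% reduction), as.integer(floor))
}

#' Squeeze-and-excitation block
#'
#' Global average pooling followed by a bottlenecked two-layer transform
#' (`C -> max(C/reduction, 4) -> C`) with ReLU and sigmoid, producing per-channel
#' gains in (0, 1) that rescale the input feature map.
#'
#' @param channels input channel count
#' @param reduction bottleneck reduction ratio
#' @return a `mares_module`
#' @export
nn_se_block <- function(channels, reduction = 16L) {
  hidden <- se_hidden(channels, reduction)
  params <- list(w1 = new_param(init_fc_weight(channels, hidden)),
                 b1 = new_param(numeric(hidden)),
                 w2 = new_param(init_fc_weight(hidden, channels)),
                 b2 = new_param(numeric(channels)))
  new_module("se_block", params = params,
             forward = function(tape, x, train = FALSE) {
               w1 <- ag_leaf(tape, params$w1$value); params$w1$node <- w1
               b1 <- ag_leaf(tape, params$b1$value); params$b1$node <- b1
               w2 <- ag_leaf(tape, params$w2$value); params$w2$node <- w2
               b2 <- ag_leaf(tape, params$b2$value); params$b2$node <- b2
               v <- op_gap(tape, x)
               h <- op_mat_relu(tape, op_fc(tape, v, w1, b1))
               s <- op_mat_sigmoid(tape, op_fc(tape, h, w2, b2))
               op_mul_channel(tape, x, s)
             },
             extra = list(channels = channels, hidden = hidden))
}

#' Channel attention module (CAM)
#'
#' Global max-pool and average-pool channel descriptors pass through a shared
#' two-layer perceptron. By default the two branch outputs are summed
#' element-wise and then passed through one sigmoid (gains in (0, 1)); set
#' `combine = "sigmoid_then_sum"` for the variant that applies a sigmoid to
#' each branch before summing (gains in (0, 2)).
#'
#' @param channels input channel count
#' @param reduction MLP reduction ratio
#' @param combine `"sum_then_sigmoid"` (default) or `"sigmoid_then_sum"`
#' @return a `mares_module`; its forward returns an `N x C` gain matrix
#' @export
nn_channel_attention <- function(channels, reduction = 16L,
                                 combine = c("sum_then_sigmoid",
                                             "sigmoid_then_sum")) {
  combine <- match.arg(combine)
  hidden <- se_hidden(channels, reduction)
  params <- list(w1 = new_param(init_fc_weight(channels, hidden)),
                 b1 = new_param(numeric(hidden)),
                 w2 = new_param(init_fc_weight(hidden, channels)),
                 b2 = new_param(numeric(channels)))
  new_module("channel_attention", params = params,
             forward = function(tape, x, train = FALSE) {
               w1 <- ag_leaf(tape, params$w1$value); params$w1$node <- w1
               b1 <- ag_leaf(tape, params$b1$value); params$b1$node <- b1
               w2 <- ag_leaf(tape, params$w2$value); params$w2$node <- w2
               b2 <- ag_leaf(tape, params$b2$value); params$b2$node <- b2
               mlp <- function(v) {
                 op_fc(tape, op_mat_relu(tape, op_fc(tape, v, w1, b1)), w2, b2)
               }
               ma <- mlp(op_gap(tape, x))
               mm <- mlp(op_gmp(tape, x))
               if (combine == "sum_then_sigmoid") {
                 op_mat_sigmoid(tape, op_mat_add(tape, ma, mm))
               } else {
                 op_mat_add(tape, op_mat_sigmoid(tape, ma),
                            op_mat_sigmoid(tape, mm))
               }
             },
             extra = list(channels = channels, hidden = hidden,
                          combine = combine))
}

#' Spatial attention module (SAM)
#'
#' Channel-wise max and mean maps are concatenated into an `H x W x 2` map and
#' reduced by a shape-preserving `7x7` convolution to a single channel, then
#' passed through a sigmoid, yielding an `H x W x 1` gain map in (0, 1).
#'
#' @param k spatial kernel size (odd; default 7)
#' @return a `mares_module`; its forward returns an `(N, H, W, 1)` gain map
#' @export
nn_spatial_attention <- function(k = 7L) {
  conv <- nn_conv2d(2L, 1L, k = k)
  new_module("spatial_attention", children = list(conv = conv),
             forward = function(tape, x, train = FALSE) {
               pooled <- op_concat(tape, list(op_chan_mean(tape, x),
                                              op_chan_max(tape, x)))
               op_sigmoid(tape, conv$forward(tape, pooled, train))
             })
}

#' Convolutional block attention module (CBAM)
#'
#' Sequential channel-then-spatial attention: `F' = F (*) CAM(F)` broadcast
#' over space, followed by `F'' = F' (*) SAM(F')` broadcast over channels.
#'
#' @inheritParams nn_channel_attention
#' @return a `mares_module`
#' @export
nn_cbam <- function(channels, reduction = 16L,
                    combine = c("sum_then_sigmoid", "sigmoid_then_sum")) {
  combine <- match.arg(combine)
  cam <- nn_channel_attention(channels, reduction, combine)
  sam <- nn_spatial_attention()
  new_module("cbam", children = list(cam = cam, sam = sam),
             forward = function(tape, x, train = FALSE) {
               xp <- op_mul_channel(tape, x, cam$forward(tape, x, train))
               op_mul_spatial(tape, xp, sam$forward(tape, xp, train))
             },
             extra = list(channels = channels))
}

#' Attention gate
#'
#' Computes spatial attention coefficients from a gating feature (the
#' upsampled decoder map) and a skip feature of equal spatial size: each input
#' goes through a `1x1` convolution and batch normalisation, the results are
#' summed and rectified, then reduced to one channel by a second `1x1`
#' convolution + batch normalisation and a sigmoid. The resulting coefficient
#' map multiplies the skip feature.
#'
#' @param channels channel count of both inputs
#' @param inter_channels intermediate width (default `channels / 2`)
#' @return a `mares_module`; forward signature `(tape, gate, skip, train)`
#' @export
nn_attention_gate <- function(channels, inter_channels = NULL) {
  if (is.null(inter_channels)) inter_channels <- max(channels %/% 2L, 1L)
  children <- list(
    theta_g = nn_conv_bn(channels, inter_channels, k = 1L, relu = FALSE),
    theta_x = nn_conv_bn(channels, inter_channels, k = 1L, relu = FALSE),
    psi = nn_conv_bn(inter_channels, 1L, k = 1L, relu = FALSE)
  )
  new_module("attention_gate", children = children,
             forward = function(tape, gate, skip, train = FALSE) {
               dg <- fm_dims(gate$value)
               ds <- fm_dims(skip$value)
               if (!all(dg[1:3] == ds[1:3])) {
                 stop(sprintf(
                   "attention gate: spatial size mismatch (gate %dx%d, skip %dx%d)",
                   dg[2], dg[3], ds[2], ds[3]))
               }
               g1 <- children$theta_g$forward(tape, gate, train)
               x1 <- children$theta_x$forward(tape, skip, train)
               a <- op_relu(tape, op_add(tape, g1, x1))
               alpha <- op_sigmoid(tape, children$psi$forward(tape, a, train))
               op_mul_spatial(tape, skip, alpha)
             },
             extra = list(channels = channels,
                          inter_channels = inter_channels))
}
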
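# Scale-aware feature extraction module (SFEM).
#
# Three parallel 3x3 convolution branches at dilation rates 1, 3 and 5 widen
# the receptive field without extra parameters per tap.  Neighbouring branch
# pairs are fused by channel concatenation, passed through an ordinary 3x3
# convolution, re-concatenated with their parent branches and refined by an
# attention block (CBAM by default).  The refined maps and the input are
# concatenated and projected back to the input width by a 1x1 convolution, so
# the module is a drop-in on any skip connection.

#' Dilated convolution branch
#'
#' Shape-preserving `3x3` convolution at dilation rate 1, 3 or 5 (zero padding
#' equal to the rate), followed by batch normalisation and ReLU; channel count
#' is preserved.
#'
#' @param channels input (= output) channel count
#' @param rate dilation rate, one of 1, 3, 5
#' @return a `mares_module`
#' @export
nn_dilated_branch <- function(channels, rate) {
  if (!rate %in% c(1L, 3L, 5L)) {
    stop("unsupported dilation rate: ", rate, " (must be 1, 3 or 5)")
  }
  stage <- nn_conv_bn(channels, channels, k = 3L, dilation = as.integer(rate))
  new_module("dilated_branch", children = list(stage = stage),
             forward = function(tape, x, train = FALSE) {
               stage$forward(tape, x, train)
             },
             extra = list(rate = rate, channels = channels))
}

sfem_attention_module <- function(channels, variant,
                                  combine = "sum_then_sigmoid") {
  switch(variant,
         none = NULL,
         cam = nn_channel_attention(channels, combine = combine),
         sam = nn_spatial_attention(),
         cbam = nn_cbam(channels, combine = combine),
         stop("unknown sfem attention variant: ", variant))
}

apply_sfem_attention <- function(tape, mod, variant, x, train) {
  switch(variant,
         none = x,
         cam = op_mul_channel(tape, x, mod$forward(tape, x, train)),
         sam = op_mul_spatial(tape, x, mod$forward(tape, x, train)),
         cbam = mod$forward(tape, x, train))
}

#' Scale-aware feature extraction module
#'
#' @param channels input (= output) channel count
#' @param attention attention refinement applied to each fused map:
#'   `"cbam"` (default), `"cam"`, `"sam"` or `"none"` (direct connection)
#' @param cam_combine branch combination rule for channel attention; see
#'   [nn_channel_attention()]
#' @return a `mares_module`
#' @export
nn_sfem <- function(channels, attention = c("cbam", "cam", "sam", "none"),
                    cam_combine = "sum_then_sigmoid") {
  attention <- match.arg(attention)
  c2 <- 2L * channels       # width of each fused pair
  c4 <- 4L * channels       # conv(F12) (+) F1 (+) F2
  children <- list(
    branch1 = nn_dilated_branch(channels, 1L),
    branch3 = nn_dilated_branch(channels, 3L),
    branch5 = nn_dilated_branch(channels, 5L),
    fuse12 = nn_conv_bn(c2, c2),
    fuse23 = nn_conv_bn(c2, c2),
    project = nn_conv_bn(4L * c2 + channels, channels, k = 1L)
  )
  att12 <- sfem_attention_module(c4, attention, cam_combine)
  att23 <- sfem_attention_module(c4, attention, cam_combine)
  if (!is.null(att12)) {
    children$att12 <- att12
    children$att23 <- att23
  }
  new_module("sfem", children = children,
             forward = function(tape, x, train = FALSE) {
               f1 <- children$branch1$forward(tape, x, train)
               f2 <- children$branch3$forward(tape, x, train)
               f3 <- children$branch5$forward(tape, x, train)
               f12 <- op_concat(tape, list(f1, f2))
               f23 <- op_concat(tape, list(f2, f3))
               g12 <- op_concat(tape, list(
                 children$fuse12$forward(tape, f12, train), f1, f2))
               g23 <- op_concat(tape, list(
                 children$fuse23$forward(tape, f23, train), f2, f3))
               r12 <- apply_sfem_attention(tape, children$att12, attention,
                                           g12, train)
               r23 <- apply_sfem_attention(tape, children$att23, attention,
                                           g23, train)
               all <- op_concat(tape, list(r12, r23, x))
               children$project$forward(tape, all, train)
             },
             extra = list(channels = channels, attention = attention))
}
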
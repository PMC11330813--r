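# Multi-scale compression-excitation module (MCEM).
#
# Each encoder level X_i passes through a 3x3 convolution, squeeze-and-
# excitation reweighting and a 1x1 convolution, giving excited maps Y_i.  The
# deepest map passes straight through (F_deepest = Y_deepest); every shallower
# output merges top-down context: F_i = conv3x3(Y_i + upsample(project(F_{i+1}))),
# with a 1x1 channel projection and nearest-neighbour x2 upsampling, so every
# F_i keeps X_i's shape and feeds the matching decoder level.

# one compress-excite path: conv3x3 -> SE -> conv1x1 (channel preserving)
nn_compress_excite <- function(channels, reduction = 16L) {
  children <- list(
    conv3 = nn_conv_bn(channels, channels),
    se = nn_se_block(channels, reduction),
    conv1 = nn_conv_bn(channels, channels, k = 1L)
  )
  new_module("compress_excite", children = children,
             forward = function(tape, x, train = FALSE) {
               h <- children$conv3$forward(tape, x, train)
               h <- children$se$forward(tape, h, train)
               children$conv1$forward(tape, h, train)
             },
             extra = list(channels = channels))
}

# one top-down merge step: Y_i + upsample(project(F_{i+1})) -> conv3x3
nn_topdown_step <- function(channels, upper_channels) {
  children <- list(
    project = nn_conv_bn(upper_channels, channels, k = 1L, relu = FALSE),
    merge = nn_conv_bn(channels, channels)
  )
  new_module("topdown_step", children = children,
             forward = function(tape, y, f_upper, train = FALSE) {
               ctx <- op_upsample2(tape,
                                   children$project$forward(tape, f_upper, train))
               dy <- fm_dims(y$value)
               dc <- fm_dims(ctx$value)
               if (!all(dy[1:3] == dc[1:3])) {
                 stop(sprintf(
                   "top-down fusion: non-dyadic size chain (level %dx%d vs upsampled context %dx%d)",
                   dy[2], dy[3], dc[2], dc[3]))
               }
               children$merge$forward(tape, op_add(tape, y, ctx), train)
             },
             extra = list(channels = channels))
}

#' Multi-scale compression-excitation module
#'
#' @param channels integer vector of channel counts, finest level first
#'   (e.g. `c(16, 32, 64, 128)`); spatial sizes must halve level to level
#' @param reduction squeeze-and-excitation reduction ratio
#' @return a `mares_module`; its forward maps a list of feature-map nodes
#'   (finest first) to a list of context-enriched maps of identical shapes
#' @export
nn_mcem <- function(channels, reduction = 16L) {
  L <- length(channels)
  paths <- lapply(channels, nn_compress_excite, reduction = reduction)
  names(paths) <- paste0("path", seq_len(L))
  steps <- list()
  for (i in seq_len(L - 1L)) {
    steps[[paste0("topdown", i)]] <- nn_topdown_step(channels[i],
                                                     channels[i + 1L])
  }
  new_module("mcem", children = c(paths, steps),
             forward = function(tape, xs, train = FALSE) {
               ys <- lapply(seq_len(L), function(i) {
                 paths[[i]]$forward(tape, xs[[i]], train)
               })
               fs <- vector("list", L)
               fs[[L]] <- ys[[L]]  # deepest level passes through uninterrupted
               for (i in seq.int(L - 1L, 1L)) {
                 fs[[i]] <- steps[[paste0("topdown", i)]]$forward(
                   tape, ys[[i]], fs[[i + 1L]], train)
               }
               fs
             },
             extra = list(channels = channels))
}
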
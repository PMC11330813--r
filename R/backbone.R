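# Residual encoder-decoder backbone and full model assembly.
#
# The encoder halves the spatial size per stage with 2x2 max pooling and
# doubles the channel width (base_width * 2^(i-1) at stage i, bottleneck at
# base_width * 2^depth).  Skip connections optionally pass through a
# scale-aware feature extraction module (SFEM) per level and then a shared
# multi-scale compression-excitation module (MCEM); the decoder upsamples with
# 2x2 transposed convolutions, optionally gates each skip with an attention
# gate, concatenates and applies a residual (or plain) block.  A final 1x1
# convolution and sigmoid produce the lesion probability map.

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Model architecture configuration
#'
#' Switches for the residual backbone and each attachable module. All flags
#' off gives the plain U-Net baseline; all flags on gives the full multi-scale
#' attention residual network (MARes-Net).
#'
#' @param base_width channel width of the first stage (doubles per stage)
#' @param depth number of down-sampling stages
#' @param in_channels input image channels (1 for grayscale radiographs)
#' @param use_residual residual double-conv blocks instead of plain ones
#' @param use_sfem scale-aware feature extraction on every skip connection
#' @param use_mcem multi-scale compression-excitation across the skip levels
#' @param use_ag attention gates on the decoder skips
#' @param sfem_attention attention refinement inside the SFEM:
#'   `"cbam"`, `"cam"`, `"sam"` or `"none"`
#' @param cam_combine how channel attention merges its two pooled branches;
#'   see [nn_channel_attention()]
#' @param seed integer seed for weight initialisation
#' @return an object of class `model_config`
#' @export
model_config <- function(base_width = 16L, depth = 4L, in_channels = 1L,
                         use_residual = TRUE, use_sfem = TRUE,
                         use_mcem = TRUE, use_ag = TRUE,
                         sfem_attention = c("cbam", "cam", "sam", "none"),
                         cam_combine = c("sum_then_sigmoid",
                                         "sigmoid_then_sum"),
                         seed = 1L) {
  sfem_attention <- match.arg(sfem_attention)
  cam_combine <- match.arg(cam_combine)
  if (base_width < 4L) stop("base_width must be at least 4")
  if (depth < 2L) stop("depth must be at least 2")
  if (in_channels < 1L) stop("in_channels must be at least 1")
  structure(list(base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 use_residual = isTRUE(use_residual),
                 use_sfem = isTRUE(use_sfem),
                 use_mcem = isTRUE(use_mcem),
                 use_ag = isTRUE(use_ag),
                 sfem_attention = sfem_attention,
                 cam_combine = cam_combine,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Human-readable variant name for a configuration
#'
#' Plain baseline is "U-Net"; the residual backbone is "ResU" with enabled
#' modules appended, e.g. "ResU + AG + SFEM + MCEM".
#'
#' @param config a [model_config()]
#' @return character scalar
#' @export
variant_name <- function(config) {
  base <- if (config$use_residual) "ResU" else "U-Net"
  mods <- c(if (config$use_ag) "AG",
            if (config$use_sfem) "SFEM",
            if (config$use_mcem) "MCEM")
  if (!config$use_residual && length(mods)) {
    base <- "U-Net (no residual)"
  }
  paste(c(base, mods), collapse = " + ")
}

#' Build a segmentation model
#'
#' Wires the encoder, optional SFEM/MCEM skip processing, optional attention
#' gates and the decoder according to `config`. Weight initialisation is
#' deterministic for a fixed `config$seed`.
#'
#' @param config a [model_config()]
#' @return an object of class `mares_model`
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, build_model_impl(config))
}

build_model_impl <- function(config) {
  depth <- config$depth
  widths <- config$base_width * 2L^(seq_len(depth) - 1L)
  bott <- config$base_width * 2L^depth

  enc <- list()
  cin <- config$in_channels
  for (i in seq_len(depth)) {
    enc[[paste0("enc", i)]] <- nn_residual_block(cin, widths[i],
                                                 residual = config$use_residual)
    cin <- widths[i]
  }
  enc$bottleneck <- nn_residual_block(widths[depth], bott,
                                      residual = config$use_residual)

  skips <- list()
  if (config$use_sfem) {
    for (i in seq_len(depth)) {
      skips[[paste0("sfem", i)]] <- nn_sfem(widths[i],
                                            attention = config$sfem_attention,
                                            cam_combine = config$cam_combine)
    }
  }
  if (config$use_mcem) skips$mcem <- nn_mcem(widths)

  dec <- list()
  cup <- bott
  for (i in seq.int(depth, 1L)) {
    dec[[paste0("up", i)]] <- nn_upconv2(cup, widths[i])
    if (config$use_ag) {
      dec[[paste0("gate", i)]] <- nn_attention_gate(widths[i])
    }
    dec[[paste0("dec", i)]] <- nn_residual_block(2L * widths[i], widths[i],
                                                 residual = config$use_residual)
    cup <- widths[i]
  }
  dec$head <- nn_conv2d(widths[1], 1L, k = 1L)

  children <- c(enc, skips, dec)
  root <- new_module("model", children = children,
                     forward = NULL,
                     extra = list(config = config, widths = widths,
                                  bottleneck_width = bott))
  structure(list(config = config, widths = widths, bottleneck_width = bott,
                 modules = root),
            class = "mares_model")
}

check_divisible <- function(h, w, depth) {
  f <- 2L^depth
  if (h %% f != 0L) {
    stop(sprintf("input height %d is not divisible by 2^depth = %d", h, f))
  }
  if (w %% f != 0L) {
    stop(sprintf("input width %d is not divisible by 2^depth = %d", w, f))
  }
}

# encoder pass on the tape; returns list(stages = <pre-pool features>,
# bottleneck = <node>)
model_encode <- function(model, tape, x, train) {
  cfg <- model$config
  d <- fm_dims(x$value)
  check_divisible(d[2], d[3], cfg$depth)
  mods <- model$modules$children
  stages <- vector("list", cfg$depth)
  h <- x
  for (i in seq_len(cfg$depth)) {
    stages[[i]] <- mods[[paste0("enc", i)]]$forward(tape, h, train)
    h <- op_maxpool2(tape, stages[[i]])
  }
  list(stages = stages, bottleneck = mods$bottleneck$forward(tape, h, train))
}

# skip processing (SFEM per level, then MCEM across levels)
model_skips <- function(model, tape, stages, train) {
  cfg <- model$config
  mods <- model$modules$children
  skips <- stages
  if (cfg$use_sfem) {
    skips <- lapply(seq_along(skips), function(i) {
      mods[[paste0("sfem", i)]]$forward(tape, skips[[i]], train)
    })
  }
  if (cfg$use_mcem) skips <- mods$mcem$forward(tape, skips, train)
  skips
}

# decoder pass; returns the sigmoid probability node
model_decode <- function(model, tape, bottleneck, skips, train) {
  cfg <- model$config
  mods <- model$modules$children
  h <- bottleneck
  for (i in seq.int(cfg$depth, 1L)) {
    up <- mods[[paste0("up", i)]]$forward(tape, h, train)
    skip <- skips[[i]]
    du <- fm_dims(up$value)
    ds <- fm_dims(skip$value)
    if (!all(du[1:3] == ds[1:3])) {
      stop(sprintf("decoder level %d: skip %dx%d does not match upsampled %dx%d",
                   i, ds[2], ds[3], du[2], du[3]))
    }
    if (cfg$use_ag) {
      skip <- mods[[paste0("gate", i)]]$forward(tape, up, skip, train)
    }
    h <- mods[[paste0("dec", i)]]$forward(tape, op_concat(tape, list(up, skip)),
                                          train)
  }
  op_sigmoid(tape, mods$head$forward(tape, h, train))
}

model_forward <- function(model, tape, x, train = FALSE) {
  st <- model_encode(model, tape, x, train)
  skips <- model_skips(model, tape, st$stages, train)
  model_decode(model, tape, st$bottleneck, skips, train)
}

#' Encoder forward pass
#'
#' Runs the encoder on a plain input array and returns the per-stage pre-pool
#' feature maps (finest first) and the bottleneck map.
#'
#' @param model a [build_model()] result
#' @param image array `c(N, H, W, C)` with H, W divisible by `2^depth`
#' @param train use batch statistics in batch-norm layers
#' @return `list(stages = <list of arrays>, bottleneck = <array>)`
#' @export
encoder_forward <- function(model, image, train = FALSE) {
  tape <- ag_tape()
  st <- model_encode(model, tape, ag_leaf(tape, fm_wrap(image)), train)
  list(stages = lapply(st$stages, function(n) fm_unwrap(n$value)),
       bottleneck = fm_unwrap(st$bottleneck$value))
}

#' Decoder forward pass
#'
#' Decodes a bottleneck map against explicitly supplied skip feature maps
#' (finest first), applying attention gates if the model was built with them.
#'
#' @param model a [build_model()] result
#' @param state list with element `bottleneck` (array), as returned by
#'   [encoder_forward()]
#' @param skips list of skip arrays, finest first, spatially aligned with the
#'   encoder stages
#' @param train use batch statistics in batch-norm layers
#' @return probability map array `c(N, H, W, 1)` with values in (0, 1)
#' @export
decoder_forward <- function(model, state, skips, train = FALSE) {
  tape <- ag_tape()
  bott <- ag_leaf(tape, fm_wrap(state$bottleneck))
  skipn <- lapply(skips, function(s) ag_leaf(tape, fm_wrap(s)))
  fm_unwrap(model_decode(model, tape, bott, skipn, train)$value)
}

#' Full forward pass to a probability map
#'
#' @param model a [build_model()] result
#' @param image array `c(N, H, W, C)` or a single `H x W` matrix
#' @param train use batch statistics in batch-norm layers
#' @return probability array `c(N, H, W, 1)`
#' @export
model_predict <- function(model, image, train = FALSE) {
  image <- if (is.matrix(image)) {
    fm_from_image(image)
  } else if (is.null(attr(image, "fmd"))) {
    fm_wrap(image)
  } else image
  tape <- ag_tape()
  fm_unwrap(model_forward(model, tape, ag_leaf(tape, image), train)$value)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution and dense weights and
#' biases, batch-norm gains and shifts; running statistics excluded).
#'
#' @param model a [build_model()] result or any `mares_module`
#' @return integer count
#' @export
count_parameters <- function(model) {
  root <- if (inherits(model, "mares_model")) model$modules else model
  sum(vapply(collect_params(root), function(p) length(p$value), 1))
}

#' @export
print.mares_model <- function(x, ...) {
  n <- count_parameters(x)
  cat(sprintf("%s  (base width %d, depth %d, %d input channel%s)\n",
              variant_name(x$config), x$config$base_width, x$config$depth,
              x$config$in_channels, if (x$config$in_channels > 1) "s" else ""))
  cat(sprintf("trainable parameters: %d (%.2f M)\n", n, n / 1e6))
  invisible(x)
}
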
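# Network modules.  A module is a list with class "mares_module" carrying
#   $params   named list of parameter environments (each with $value)
#   $children named list of sub-modules
#   $forward  function(tape, x, train) -> node  (signature varies per module)
# Parameter environments also hold Adam moments once training starts.

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p
}

# He-normal initialisation for a convolution weight matrix (k*k*Cin) x Cout.
init_conv_weight <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  matrix(stats::rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout)
}

init_fc_weight <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  matrix(stats::rnorm(cin * cout, 0, sd), cin, cout)
}

new_module <- function(type, params = list(), children = list(), forward,
                       extra = list()) {
  mod <- c(list(type = type, params = params, children = children,
                forward = forward), extra)
  class(mod) <- "mares_module"
  mod
}

# Run a module's forward pass on a plain array outside any training loop.
#
# @param module a module built by one of the `nn_*` constructors
# @param x input feature map, array with dim c(N, H, W, C)
# @param train logical; use batch statistics in batch-norm layers
# @param ... further inputs for multi-input modules (e.g. the skip map of an
#   attention gate)
# @return the output array
#' Apply a network module to a feature map
#'
#' Runs the forward pass of a module built by one of the `nn_*` constructors
#' on a plain numeric array with dim `c(N, H, W, C)` and returns the resulting
#' array. Gradients are not retained; use [train_model()] for fitting.
#'
#' @param module a `mares_module`
#' @param x input array `c(N, H, W, C)` (additional inputs via `...`)
#' @param ... further positional inputs for multi-input modules
#' @param train logical; if `TRUE` batch-norm layers use batch statistics
#' @return output array
#' @export
module_forward <- function(module, x, ..., train = FALSE) {
  stopifnot(inherits(module, "mares_module"))
  tape <- ag_tape()
  wrap_in <- function(v) {
    if (is.list(v)) return(lapply(v, wrap_in))
    if (is.array(v) && length(dim(v)) == 4L) v <- fm_wrap(v)
    ag_leaf(tape, v)
  }
  ins <- lapply(c(list(x), list(...)), wrap_in)
  out <- do.call(module$forward, c(list(tape), ins, list(train = train)))
  unwrap_out <- function(o) {
    v <- o$value
    if (!is.null(attr(v, "fmd"))) fm_unwrap(v) else v
  }
  if (is.list(out) && !inherits(out, "environment") && is.null(out$value)) {
    lapply(out, unwrap_out)
  } else {
    unwrap_out(out)
  }
}

# Depth-first collection of parameter environments, named by path.
collect_params <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$params)) {
    out[[paste0(prefix, nm)]] <- module$params[[nm]]
  }
  for (nm in names(module$children)) {
    out <- c(out, collect_params(module$children[[nm]],
                                 paste0(prefix, nm, ".")))
  }
  out
}

# Batch-norm layers carry running statistics outside the parameter list.
collect_bn_states <- function(module, prefix = "") {
  out <- list()
  if (identical(module$type, "batch_norm")) out[[prefix]] <- module$state
  for (nm in names(module$children)) {
    out <- c(out, collect_bn_states(module$children[[nm]],
                                    paste0(prefix, nm, ".")))
  }
  out
}

# ---- elementary modules ----------------------------------------------------

#' 2-D convolution module
#'
#' Shape-preserving `k x k` convolution (zero padding `dilation*(k-1)/2`)
#' with optional bias. Weights are stored as a `(k*k*in_channels) x
#' out_channels` matrix whose row order matches the R flattening of an array
#' `dim = c(k, k, in_channels, out_channels)`.
#'
#' @param in_channels,out_channels channel counts
#' @param k kernel size (odd)
#' @param dilation dilation (atrous) rate
#' @param bias include an additive bias
#' @return a `mares_module`
#' @export
nn_conv2d <- function(in_channels, out_channels, k = 3L, dilation = 1L,
                      bias = TRUE) {
  if (out_channels < 1L) stop("out_channels must be positive")
  params <- list(w = new_param(init_conv_weight(k, in_channels, out_channels)))
  if (bias) params$b <- new_param(numeric(out_channels))
  new_module("conv2d", params = params,
             forward = function(tape, x, train = FALSE) {
               w <- ag_leaf(tape, params$w$value)
               params$w$node <- w
               b <- NULL
               if (bias) {
                 b <- ag_leaf(tape, params$b$value)
                 params$b$node <- b
               }
               op_conv(tape, x, w, b, k = k, dilation = dilation)
             },
             extra = list(k = k, dilation = dilation,
                          in_channels = in_channels,
                          out_channels = out_channels))
}

#' Batch normalisation module
#'
#' Per-channel batch normalisation with learnable gain and shift; batch
#' statistics in training mode, exponential running statistics at inference.
#'
#' @param channels number of channels
#' @param momentum running-statistics update rate
#' @param eps variance floor
#' @return a `mares_module`
#' @export
nn_batch_norm <- function(channels, momentum = 0.1, eps = 1e-5) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(channels)
  state$running_var <- rep(1, channels)
  state$momentum <- momentum
  state$eps <- eps
  params <- list(gamma = new_param(rep(1, channels)),
                 beta = new_param(numeric(channels)))
  new_module("batch_norm", params = params,
             forward = function(tape, x, train = FALSE) {
               g <- ag_leaf(tape, params$gamma$value); params$gamma$node <- g
               b <- ag_leaf(tape, params$beta$value); params$beta$node <- b
               op_batch_norm(tape, x, g, b, state, train)
             },
             extra = list(state = state, channels = channels))
}

# conv -> BN -> (ReLU) stage, the standard stage used throughout the network
nn_conv_bn <- function(in_channels, out_channels, k = 3L, dilation = 1L,
                       relu = TRUE) {
  conv <- nn_conv2d(in_channels, out_channels, k = k, dilation = dilation)
  bn <- nn_batch_norm(out_channels)
  new_module("conv_bn", children = list(conv = conv, bn = bn),
             forward = function(tape, x, train = FALSE) {
               h <- conv$forward(tape, x, train)
               h <- bn$forward(tape, h, train)
               if (relu) op_relu(tape, h) else h
             },
             extra = list(relu = relu))
}

# 2x2 stride-2 transposed convolution (learnable upsampling)
nn_upconv2 <- function(in_channels, out_channels) {
  arr <- array(stats::rnorm(4 * in_channels * out_channels, 0,
                            sqrt(2 / (4 * in_channels))),
               dim = c(2L, 2L, in_channels, out_channels))
  params <- list(w = new_param(conv_transpose_weight(arr)),
                 b = new_param(numeric(out_channels)))
  new_module("upconv2", params = params,
             forward = function(tape, x, train = FALSE) {
               w <- ag_leaf(tape, params$w$value); params$w$node <- w
               b <- ag_leaf(tape, params$b$value); params$b$node <- b
               op_conv_transpose2(tape, x, w, b)
             },
             extra = list(in_channels = in_channels,
                          out_channels = out_channels))
}

#' Residual (or plain) double-convolution block
#'
#' Two `3x3` conv - batch-norm - ReLU stages. With `residual = TRUE` the block
#' computes `y = f(x) + shortcut(x)`, where `f` is the two-stage path and the
#' shortcut is the identity when channel counts match, else a `1x1`
#' convolution + batch-norm projection. With all weights zeroed the residual
#' form reproduces its input exactly (the `f(x) = 0` limit).
#'
#' @param in_channels,out_channels channel counts
#' @param residual include the shortcut path
#' @return a `mares_module`
#' @export
nn_residual_block <- function(in_channels, out_channels, residual = TRUE) {
  if (out_channels < 1L) stop("out_channels must be positive")
  children <- list(
    conv1 = nn_conv_bn(in_channels, out_channels),
    conv2 = nn_conv_bn(out_channels, out_channels)
  )
  project <- residual && in_channels != out_channels
  if (project) {
    children$shortcut <- nn_conv_bn(in_channels, out_channels, k = 1L,
                                    relu = FALSE)
  }
  new_module("residual_block", children = children,
             forward = function(tape, x, train = FALSE) {
               h <- children$conv1$forward(tape, x, train)
               h <- children$conv2$forward(tape, h, train)
               if (!residual) return(h)
               sc <- if (project) {
                 children$shortcut$forward(tape, x, train)
               } else x
               op_add(tape, h, sc)
             },
             extra = list(residual = residual, in_channels = in_channels,
                          out_channels = out_channels))
}
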
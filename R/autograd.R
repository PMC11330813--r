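#' @useDynLib maresnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Reverse-mode automatic differentiation on a linear tape.
#
# Every operation appends one node holding its value, references to its parent
# nodes, and a backward closure mapping the node's output gradient to a list of
# gradients, one per parent.  Because nodes are appended in execution order,
# visiting them in reverse id order is a valid topological order for
# backpropagation.

ag_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 64L)
  tape$n <- 0L
  tape
}

ag_node <- function(tape, value, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ag_leaf <- function(tape, value) ag_node(tape, value)

# Backpropagate from `loss` (a scalar node) through the whole tape.
ag_backward <- function(tape, loss, seed_grad = 1) {
  loss$grad <- seed_grad
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    # consumers of this node have all been processed, so its activation,
    # gradient and closure (with everything it captured) can be released
    nd$grad <- NULL
    nd$value <- NULL
    nd$backward <- NULL
    nd$parents <- NULL
  }
  invisible(NULL)
}

# ---- feature-map representation --------------------------------------------
#
# Internally a feature map with dims c(N, H, W, C) is stored as an
# (N*H*W) x C matrix (sample index fastest down the rows, then h, then w)
# carrying its dims in attribute "fmd".  This makes channel-wise linear
# algebra allocation-free; the public interface converts from/to plain 4-D
# arrays at the module boundary.

fm_dims <- function(x) {
  d <- attr(x, "fmd")
  if (is.null(d)) stop("not a feature map (missing dims)")
  d
}

# Attach feature-map dims to a freshly computed matrix/vector.  The
# attributes are set in place (no copy); only ever used on results this
# package just computed.
fm_new <- function(x, dims) {
  cpp_set_fmd(x, as.integer(dims))
}

# from a 4-D array c(N, H, W, C); the flattening order already matches
fm_wrap <- function(arr) {
  d <- dim(arr)
  stopifnot(length(d) == 4L)
  fm_new(as.vector(arr), as.integer(d))
}

# back to a 4-D array
fm_unwrap <- function(x) {
  d <- fm_dims(x)
  array(as.vector(x), dim = d)
}

# Wrap a single H x W image (matrix) as a 1 x H x W x 1 feature map.
fm_from_image <- function(img) {
  stopifnot(is.matrix(img))
  fm_new(as.vector(img), c(1L, nrow(img), ncol(img), 1L))
}
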
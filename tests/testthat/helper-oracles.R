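# Independent oracles used across the suite.  These are deliberately naive
# (nested loops, direct sums) and share no code with the package internals.

# direct 2-D convolution with dilation, zero padding dil*(k-1)/2,
# x: array c(N,H,W,Cin); warr: array c(k,k,Cin,Cout)
naive_conv <- function(x, warr, bias = NULL, dil = 1) {
  d <- dim(x); k <- dim(warr)[1]; cin <- dim(warr)[3]; cout <- dim(warr)[4]
  if (is.null(bias)) bias <- numeric(cout)
  pad <- dil * (k - 1) / 2
  y <- array(0, c(d[1], d[2], d[3], cout))
  for (n in seq_len(d[1])) for (h in seq_len(d[2])) for (w in seq_len(d[3]))
    for (co in seq_len(cout)) {
      acc <- bias[co]
      for (kh in seq_len(k)) for (kw in seq_len(k)) for (ci in seq_len(cin)) {
        hh <- h + dil * (kh - 1) - pad
        ww <- w + dil * (kw - 1) - pad
        if (hh >= 1 && hh <= d[2] && ww >= 1 && ww <= d[3]) {
          acc <- acc + x[n, hh, ww, ci] * warr[kh, kw, ci, co]
        }
      }
      y[n, h, w, co] <- acc
    }
  y
}

# exhaustive per-pixel confusion tally
naive_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else if (truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# direct-sum smoothed Dice loss
naive_dice <- function(p, g, eps = 1) {
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

# set every parameter of a module tree to zero
zero_params <- function(mod) {
  for (p in maresnet:::collect_params(mod)) p$value[] <- 0
  invisible(mod)
}

# set batch-norm layers of a module tree to exact pass-through at inference
# (eps = 0, running mean 0, running var 1, gamma 1, beta 0 are the defaults;
# only eps needs forcing)
neutral_bn <- function(mod) {
  for (st in maresnet:::collect_bn_states(mod)) st$eps <- 0
  invisible(mod)
}

# Otsu threshold from an 8-bit histogram; used by the baseline segmenter
otsu_threshold <- function(img) {
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  best <- 0; thr <- 127
  for (t in 1:254) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(levels[1:(t + 1)] * p[1:(t + 1)]) / w0
    m1 <- sum(levels[(t + 2):256] * p[(t + 2):256]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- t }
  }
  thr
}

# dark-region Otsu baseline: lesion = pixels below the Otsu threshold
otsu_iou <- function(samples) {
  mean(vapply(samples, function(s) {
    pred <- (s$image < otsu_threshold(s$image)) * 1
    iou(confusion_counts(pred, s$mask))
  }, 1))
}

# Layer-by-layer trainable-parameter tally computed from first principles
# (conv k*k*cin*cout + cout; BN 2c; transposed conv 4*cin*cout + cout; FC
# cin*cout + cout), independent of how the package stores parameters.
tally_conv <- function(k, cin, cout, bias = TRUE) k * k * cin * cout + if (bias) cout else 0
tally_bn <- function(c) 2 * c
tally_conv_bn <- function(k, cin, cout) tally_conv(k, cin, cout) + tally_bn(cout)

tally_block <- function(cin, cout, residual) {
  n <- tally_conv_bn(3, cin, cout) + tally_conv_bn(3, cout, cout)
  if (residual && cin != cout) n <- n + tally_conv_bn(1, cin, cout)
  n
}

tally_se <- function(c, reduction = 16) {
  h <- max(c %/% reduction, 4)
  c * h + h + h * c + c
}

tally_cbam <- function(c) tally_se(c) + tally_conv(7, 2, 1)

tally_sfem <- function(c) {
  3 * tally_conv_bn(3, c, c) +          # dilated branches
    2 * tally_conv_bn(3, 2 * c, 2 * c) + # pairwise fusion convs
    2 * tally_cbam(4 * c) +             # attention refinement
    tally_conv_bn(1, 9 * c, c)          # output projection
}

tally_mcem <- function(widths) {
  n <- 0
  for (c in widths) {
    n <- n + tally_conv_bn(3, c, c) + tally_se(c) + tally_conv_bn(1, c, c)
  }
  for (i in seq_len(length(widths) - 1)) {
    n <- n + tally_conv_bn(1, widths[i + 1], widths[i]) +
      tally_conv_bn(3, widths[i], widths[i])
  }
  n
}

tally_gate <- function(c) {
  i <- c %/% 2
  2 * (tally_conv(1, c, i) + tally_bn(i)) + tally_conv(1, i, 1) + tally_bn(1)
}

tally_model <- function(cfg) {
  widths <- cfg$base_width * 2^(seq_len(cfg$depth) - 1)
  bott <- cfg$base_width * 2^cfg$depth
  n <- 0
  cin <- cfg$in_channels
  for (w in widths) {
    n <- n + tally_block(cin, w, cfg$use_residual)
    cin <- w
  }
  n <- n + tally_block(widths[cfg$depth], bott, cfg$use_residual)
  if (cfg$use_sfem) for (w in widths) n <- n + tally_sfem(w)
  if (cfg$use_mcem) n <- n + tally_mcem(widths)
  cup <- bott
  for (i in rev(seq_len(cfg$depth))) {
    n <- n + 4 * cup * widths[i] + widths[i]        # transposed conv
    if (cfg$use_ag) n <- n + tally_gate(widths[i])
    n <- n + tally_block(2 * widths[i], widths[i], cfg$use_residual)
    cup <- widths[i]
  }
  n + tally_conv(1, widths[1], 1)
}
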
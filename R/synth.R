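# Synthetic radiograph-like lesion images with exact ground-truth masks.
#
# Jaw cysts appear on radiographs as radiolucent (dark) fluid-filled regions
# with smooth boundaries, over textured bone at varying exposure.  The
# generator emulates that regime: a low-frequency textured background with an
# intensity gradient, 1-3 darkened elliptical lesions with Gaussian-blurred
# borders (overlaps give irregular shapes), bright elliptical distractor
# structures that are NOT part of the mask, and pixel noise.  The mask is the
# exact pre-blur lesion union, so labels are noise-free by construction.

#' Parameters of the synthetic lesion-image generator
#'
#' Defaults define the package's reference study conditions; the `"easy"`
#' preset raises contrast and lowers blur/noise to give a regime a small
#' model can segment almost perfectly (used for capability checks).
#'
#' @param size image side in pixels (divisible by 16)
#' @param n_lesions inclusive range of lesion counts per image
#' @param radius range of ellipse semi-axes in pixels; the default scales
#'   with the image (12-48 at size 256)
#' @param contrast range of the fractional intensity drop inside lesions
#' @param edge_blur range of the Gaussian sigma (pixels) applied to lesion
#'   borders
#' @param texture_scale correlation length (pixels) of the background texture
#' @param noise_sd pixel noise standard deviation, 8-bit intensity units
#' @param n_distractors number of bright elliptical structures outside the mask
#' @param preset `"default"` or `"easy"`
#' @return list of class `synth_params`
#' @export
synth_params <- function(size = 256L, n_lesions = c(1L, 3L),
                         radius = c(12, 48), contrast = c(0.2, 0.5),
                         edge_blur = c(2, 6), texture_scale = 32,
                         noise_sd = 6, n_distractors = 3L,
                         preset = c("default", "easy")) {
  preset <- match.arg(preset)
  if (missing(radius)) radius <- size * c(12, 48) / 256  # scale with the image
  if (preset == "easy" && missing(contrast) && missing(edge_blur) &&
      missing(noise_sd) && missing(n_distractors)) {
    contrast <- c(0.45, 0.6)
    edge_blur <- c(1.5, 2.5)
    noise_sd <- 4
    n_distractors <- 2L
  }
  p <- list(size = as.integer(size), n_lesions = as.integer(n_lesions),
            radius = as.numeric(radius), contrast = as.numeric(contrast),
            edge_blur = as.numeric(edge_blur),
            texture_scale = as.numeric(texture_scale),
            noise_sd = as.numeric(noise_sd),
            n_distractors = as.integer(n_distractors), preset = preset)
  if (p$size %% 16L != 0L) stop("size must be divisible by 16")
  if (any(p$radius <= 0) || any(p$contrast <= 0) || any(p$edge_blur <= 0)) {
    stop("radius, contrast and edge_blur ranges must be positive")
  }
  if (max(p$radius) >= p$size / 2) {
    stop("lesion radius must be smaller than half the image size")
  }
  class(p) <- "synth_params"
  p
}

# separable Gaussian blur of a matrix (reflected borders)
gaussian_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(x) {  # along rows
    n <- nrow(x)
    idx <- function(i) {       # reflect
      i <- abs(i - 1L) + 1L
      over <- i > n
      i[over] <- 2L * n - i[over]
      i
    }
    out <- 0
    for (j in seq_along(k)) {
      out <- out + k[j] * x[idx(seq_len(n) + j - r - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_axis(t(blur_axis(m))))
}

# exact rasterisation of a rotated ellipse; returns a 0/1 matrix
rasterize_ellipse <- function(size, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size)  # row index
  dx <- xs - cx
  dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u^2 / a^2 + v^2 / b^2 <= 1) * 1
}

runifr <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

# bilinear upscale of a coarse grid to size x size (used for textures)
upscale_bilinear <- function(coarse, size) {
  n <- nrow(coarse)
  pos <- seq(1, n, length.out = size)
  i0 <- pmin(floor(pos), n - 1L)
  f <- pos - i0
  rows <- coarse[i0, , drop = FALSE] * (1 - f) + coarse[i0 + 1L, , drop = FALSE] * f
  t(t(rows[, i0, drop = FALSE]) * (1 - f) + t(rows[, i0 + 1L, drop = FALSE]) * f)
}

#' Generate one synthetic lesion image with its exact mask
#'
#' Deterministic for a fixed `(params, seed)` pair.
#'
#' @param params a [synth_params()]
#' @param seed integer seed
#' @return list of class `image_sample` with `image` (H x W matrix, 8-bit
#'   values 0-255), `mask` (binary H x W matrix), `source_id`, `lineage`,
#'   `seed`, and `pre_noise` / `lesion_free` renders for auditing
#' @export
generate_sample <- function(params, seed) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(seed, {
    s <- params$size

    # background: smooth texture + directional exposure gradient
    ncoarse <- max(4L, as.integer(ceiling(s / params$texture_scale)) + 2L)
    texture <- upscale_bilinear(matrix(stats::rnorm(ncoarse^2, 0, 25),
                                       ncoarse), s)
    ang <- stats::runif(1, 0, 2 * pi)
    xs <- matrix(rep(seq_len(s), each = s), s) / s - 0.5
    ys <- matrix(rep(seq_len(s), times = s), s) / s - 0.5
    grad <- 30 * (xs * cos(ang) + ys * sin(ang))
    bg <- 150 + texture + grad

    # bright distractor structures (never in the mask)
    if (params$n_distractors > 0L) {
      for (i in seq_len(params$n_distractors)) {
        a <- runifr(params$radius * 0.5)
        b <- a * stats::runif(1, 0.3, 0.8)
        cx <- stats::runif(1, 1, s)
        cy <- stats::runif(1, 1, s)
        th <- stats::runif(1, 0, pi)
        soft <- gaussian_blur(rasterize_ellipse(s, cx, cy, a, b, th), 2)
        bg <- bg * (1 + stats::runif(1, 0.15, 0.3) * soft)
      }
    }
    bg <- pmax(bg, 30)
    lesion_free <- bg

    # lesions: union of random ellipses, darkened with blurred borders
    nles <- if (params$n_lesions[1] >= params$n_lesions[2]) {
      params$n_lesions[1]
    } else {
      sample(params$n_lesions[1]:params$n_lesions[2], 1L)
    }
    mask <- matrix(0, s, s)
    if (nles > 0L) {
      margin <- max(params$radius)
      for (i in seq_len(nles)) {
        a <- runifr(params$radius)
        b <- runifr(params$radius)
        cx <- stats::runif(1, 1 + margin, s - margin)
        cy <- stats::runif(1, 1 + margin, s - margin)
        th <- stats::runif(1, 0, pi)
        mask <- pmax(mask, rasterize_ellipse(s, cx, cy, a, b, th))
      }
    }
    contrast <- runifr(params$contrast)
    sigma <- runifr(params$edge_blur)
    soft <- if (any(mask > 0)) gaussian_blur(mask, sigma) else mask
    pre_noise <- lesion_free * (1 - contrast * soft)

    img <- pre_noise + stats::rnorm(s * s, 0, params$noise_sd)
    img <- matrix(pmin(pmax(round(img), 0), 255), s, s)

    structure(list(image = img, mask = mask,
                   source_id = sprintf("synth_%d", seed),
                   lineage = "original", seed = as.integer(seed),
                   pre_noise = pre_noise, lesion_free = lesion_free),
              class = "image_sample")
  })
}

#' Generate a dataset of synthetic samples on disk
#'
#' Writes `images/<id>.png` and `masks/<id>.png` (masks as 0/255) plus a JSON
#' manifest, in the layout read by [load_pairs()]. Two runs with the same seed
#' produce identical directory trees.
#'
#' @param n number of samples
#' @param params a [synth_params()]
#' @param seed integer master seed; per-sample seeds are derived from it
#' @param out_dir target directory (refused if non-empty unless `force`)
#' @param force overwrite a non-empty target directory
#' @return the manifest, invisibly
#' @export
generate_dataset <- function(n, params, seed, out_dir, force = FALSE) {
  stopifnot(n >= 1)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("target directory ", out_dir, " is not empty (use force = TRUE)")
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  seeds <- derive_seeds(seed, n)
  ids <- sprintf("sample_%04d", seq_len(n))
  for (i in seq_len(n)) {
    smp <- generate_sample(params, seeds[i])
    png::writePNG(smp$image / 255, file.path(out_dir, "images",
                                             paste0(ids[i], ".png")))
    png::writePNG(smp$mask, file.path(out_dir, "masks",
                                      paste0(ids[i], ".png")))
  }
  manifest <- list(n = n, seed = seed, ids = ids, seeds = seeds,
                   params = unclass(params))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a dataset of synthetic samples in memory
#'
#' @inheritParams generate_dataset
#' @return list of `image_sample`
#' @export
generate_samples <- function(n, params, seed) {
  seeds <- derive_seeds(seed, n)
  lapply(seeds, function(s) generate_sample(params, s))
}

# distinct reproducible sub-seeds below 2^31
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629)
}
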
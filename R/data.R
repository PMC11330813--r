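# Paired image/mask input-output, dataset splitting, and the geometric
# augmentation recipe (flips, rotation, scaling, translation, elastic
# deformation), applied identically to image and mask.

read_gray <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    img <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", path, " (PNG or TIFF expected)")
  }
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  img * 255
}

#' Load paired images and masks from two directories
#'
#' Files are matched by filename. Masks are binarised at 127/255; shapes are
#' checked per pair.
#'
#' @param image_dir,mask_dir directories of PNG (or TIFF) files with matching
#'   names
#' @return list of `image_sample` (elements `image`, `mask`, `source_id`,
#'   `lineage`, `seed`)
#' @export
load_pairs <- function(image_dir, mask_dir) {
  pat <- "\\.(png|tiff?)$"
  imgs <- sort(dir(image_dir, pattern = pat, ignore.case = TRUE))
  msks <- sort(dir(mask_dir, pattern = pat, ignore.case = TRUE))
  key <- function(f) sub(pat, "", f, ignore.case = TRUE)
  orphan_i <- setdiff(key(imgs), key(msks))
  orphan_m <- setdiff(key(msks), key(imgs))
  if (length(orphan_i) || length(orphan_m)) {
    stop("unmatched files - images without mask: [",
         paste(orphan_i, collapse = ", "), "]; masks without image: [",
         paste(orphan_m, collapse = ", "), "]")
  }
  lapply(seq_along(imgs), function(i) {
    img <- read_gray(file.path(image_dir, imgs[i]))
    msk <- read_gray(file.path(mask_dir, msks[i]))
    if (!identical(dim(img), dim(msk))) {
      stop(sprintf("%s: image is %dx%d but mask is %dx%d", imgs[i],
                   nrow(img), ncol(img), nrow(msk), ncol(msk)))
    }
    structure(list(image = round(img), mask = (msk > 127) * 1,
                   source_id = key(imgs[i]), lineage = "original",
                   seed = NA_integer_),
              class = "image_sample")
  })
}

#' Split samples into train/validation/test sets
#'
#' Seeded shuffle followed by a contiguous partition. Validation and test
#' sizes are `floor(n * ratio)`; the remainder goes to the training set.
#'
#' @param samples list of samples (or a vector of ids)
#' @param ratios length-3 fractions (train, validation, test) summing to 1
#' @param seed integer seed
#' @return list of class `split_manifest` with id vectors `train`,
#'   `validation`, `test`, plus `seed` and `ratios`
#' @export
split_dataset <- function(samples, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three non-negative fractions summing to 1")
  }
  ids <- if (is.character(samples)) {
    samples
  } else {
    vapply(samples, function(s) s$source_id, "")
  }
  n <- length(ids)
  if (n < 3L) stop("need at least 3 samples to split")
  perm <- with_seed(seed, sample.int(n))
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  n_train <- n - n_val - n_test
  structure(list(train = ids[perm[seq_len(n_train)]],
                 validation = ids[perm[n_train + seq_len(n_val)]],
                 test = ids[perm[n_train + n_val + seq_len(n_test)]],
                 seed = as.integer(seed), ratios = ratios),
            class = "split_manifest")
}

#' Geometric augmentation recipe
#'
#' Each copy applies, in order: horizontal flip (with probability `flip_p`),
#' rotation, isotropic scaling, translation, and grid-based elastic
#' deformation ("local stretching"). The image is resampled bilinearly with
#' reflected borders; the mask with nearest-neighbour and zero borders, then
#' re-binarised. Defaults give `copies = 2` new samples per original, i.e. a
#' three-fold dataset including the originals.
#'
#' @param flip_p horizontal flip probability
#' @param rotation maximum absolute rotation, degrees
#' @param scale scaling factor range
#' @param translation maximum absolute shift as a fraction of width/height
#' @param elastic_spacing control-grid spacing of the elastic field, pixels
#' @param elastic_magnitude displacement standard deviation, pixels
#' @param copies augmented copies per original
#' @return list of class `augmentation_spec`
#' @export
augmentation_spec <- function(flip_p = 0.5, rotation = 15,
                              scale = c(0.9, 1.1), translation = 0.1,
                              elastic_spacing = 32, elastic_magnitude = 8,
                              copies = 2L) {
  if (rotation < 0 || translation < 0 || elastic_magnitude < 0 || copies < 0) {
    stop("augmentation ranges and copies must be non-negative")
  }
  structure(list(flip_p = flip_p, rotation = rotation, scale = scale,
                 translation = translation,
                 elastic_spacing = elastic_spacing,
                 elastic_magnitude = elastic_magnitude,
                 copies = as.integer(copies)),
            class = "augmentation_spec")
}

# Apply one explicit geometric transform to an image/mask pair.  The forward
# transform maps source to target as: flip, rotate by `angle` (degrees),
# scale, then translate by (dx, dy) pixels; resampling uses the inverse map.
transform_pair <- function(image, mask, flip = FALSE, angle = 0, scale = 1,
                           dx = 0, dy = 0, elastic = NULL) {
  h <- nrow(image); w <- ncol(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ty <- matrix(rep(seq_len(h), times = w), h)   # target row coords
  tx <- matrix(rep(seq_len(w), each = h), h)    # target col coords
  # inverse affine: undo translation, scaling, rotation, then flip
  py <- ty - dy - cy
  px <- tx - dx - cx
  py <- py / scale
  px <- px / scale
  th <- -angle * pi / 180
  sy <- py * cos(th) + px * sin(th)
  sx <- -py * sin(th) + px * cos(th)
  if (flip) sx <- -sx
  sy <- sy + cy
  sx <- sx + cx
  if (!is.null(elastic)) {
    sy <- sy + elastic$dy
    sx <- sx + elastic$dx
  }
  img <- cpp_warp(image, sy, sx, method = 1L, border = 1L, fill = 0)
  msk <- cpp_warp(mask, sy, sx, method = 0L, border = 0L, fill = 0)
  list(image = round(pmin(pmax(img, 0), 255)), mask = (msk > 0.5) * 1)
}

# smooth random displacement field from a coarse control grid
elastic_field <- function(h, w, spacing, magnitude) {
  nc <- max(3L, as.integer(ceiling(max(h, w) / spacing)) + 2L)
  up <- function() {
    g <- upscale_bilinear(matrix(stats::rnorm(nc^2, 0, magnitude), nc),
                          max(h, w))
    g[seq_len(h), seq_len(w), drop = FALSE]
  }
  list(dy = up(), dx = up())
}

#' Augment one sample
#'
#' Produces `spec$copies` transformed copies of `sample`; draws are
#' deterministic per `(seed, copy index)`. The originals are not included
#' (see [augment_dataset()]).
#'
#' @param sample an `image_sample`
#' @param spec an [augmentation_spec()]
#' @param seed integer seed
#' @return list of `image_sample` copies with lineage annotations
#' @export
augment <- function(sample, spec, seed) {
  stopifnot(inherits(spec, "augmentation_spec"))
  lapply(seq_len(spec$copies), function(k) {
    sub <- derive_seeds(seed, k)[k]
    with_seed(sub, {
      flip <- stats::runif(1) < spec$flip_p
      angle <- stats::runif(1, -spec$rotation, spec$rotation)
      sc <- runifr(spec$scale)
      dx <- stats::runif(1, -spec$translation, spec$translation) * ncol(sample$image)
      dy <- stats::runif(1, -spec$translation, spec$translation) * nrow(sample$image)
      el <- if (spec$elastic_magnitude > 0) {
        elastic_field(nrow(sample$image), ncol(sample$image),
                      spec$elastic_spacing, spec$elastic_magnitude)
      }
      out <- transform_pair(sample$image, sample$mask, flip, angle, sc,
                            dx, dy, el)
      structure(list(image = out$image, mask = out$mask,
                     source_id = sample$source_id,
                     lineage = sprintf("%s|aug%d(flip=%d,rot=%.1f,scale=%.2f,dx=%.1f,dy=%.1f)",
                                       sample$lineage, k, flip, angle, sc, dx, dy),
                     seed = sub),
                class = "image_sample")
    })
  })
}

#' Augment a whole sample list, retaining the originals
#'
#' @param samples list of `image_sample`
#' @param spec an [augmentation_spec()]
#' @param seed integer master seed; per-sample seeds are derived from it
#' @return list of `(1 + copies) * length(samples)` samples
#' @export
augment_dataset <- function(samples, spec, seed) {
  seeds <- derive_seeds(seed, length(samples))
  out <- list()
  for (i in seq_along(samples)) {
    out <- c(out, list(samples[[i]]), augment(samples[[i]], spec, seeds[i]))
  }
  out
}
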
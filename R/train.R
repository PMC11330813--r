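# Training loop (Adam + Dice loss), prediction, checkpointing, and the
# ablation harness.

#' Training configuration
#'
#' Defaults mirror the reference protocol: Adam, learning rate 0.001, batch
#' size 4, Dice loss, 200 epochs.
#'
#' @param model a [model_config()]
#' @param epochs number of epochs
#' @param batch_size images per gradient step
#' @param lr Adam learning rate
#' @param optimizer only `"adam"` is provided
#' @param loss only `"dice"` is provided
#' @param seed integer seed for data order (initialisation is seeded by
#'   `model$seed`)
#' @param data_dir optional dataset directory (`images/` + `masks/`)
#' @param val_dir optional validation dataset directory
#' @param checkpoint_path optional path for the best-validation checkpoint
#' @param log_path optional path for structured per-epoch log lines
#' @return list of class `train_config`
#' @export
train_config <- function(model = model_config(), epochs = 200L,
                         batch_size = 4L, lr = 0.001,
                         optimizer = "adam", loss = "dice", seed = 1L,
                         data_dir = NULL, val_dir = NULL,
                         checkpoint_path = NULL, log_path = NULL) {
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "dice")
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  if (lr < 0) stop("learning rate must be non-negative")
  structure(list(model = model, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 optimizer = optimizer, loss = loss, seed = as.integer(seed),
                 data_dir = data_dir, val_dir = val_dir,
                 checkpoint_path = checkpoint_path, log_path = log_path),
            class = "train_config")
}

# one Adam step over all parameter environments (grads read from $node$grad)
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    g <- p$node$grad
    if (is.null(g)) next
    g <- as.numeric(g)
    if (is.null(p$m)) {
      p$m <- numeric(length(g))
      p$v <- numeric(length(g))
    }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    dim(upd) <- dim(p$value)
    p$value <- p$value - upd
  }
}

samples_to_batch <- function(samples, idx) {
  h <- nrow(samples[[idx[1]]]$image)
  w <- ncol(samples[[idx[1]]]$image)
  n <- length(idx)
  x <- matrix(0, n * h * w, 1L)
  g <- matrix(0, n * h * w, 1L)
  for (j in seq_along(idx)) {
    rows <- seq.int(j, by = n, length.out = h * w)
    x[rows, 1L] <- as.vector(samples[[idx[j]]]$image) / 255
    g[rows, 1L] <- as.vector(samples[[idx[j]]]$mask)
  }
  list(x = fm_new(x, c(n, h, w, 1L)), g = fm_new(g, c(n, h, w, 1L)))
}

#' Train a segmentation model
#'
#' Minimises the smoothed Dice loss with Adam. Fully deterministic for fixed
#' seeds; the checkpoint with the best validation IoU is retained. Training
#' can be resumed from a checkpoint.
#'
#' @param config a [train_config()]
#' @param train_samples list of `image_sample`; if `NULL`, loaded from
#'   `config$data_dir`
#' @param val_samples optional validation samples (or `config$val_dir`)
#' @param resume_from optional checkpoint path or object to resume from
#' @param verbose print one line per epoch
#' @return list of class `train_result` with `model`, `log` (one row per
#'   epoch), `best` (best-validation checkpoint) and `config`
#' @export
train_model <- function(config, train_samples = NULL, val_samples = NULL,
                        resume_from = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(train_samples)) {
    if (is.null(config$data_dir)) stop("no training data given")
    train_samples <- load_pairs(file.path(config$data_dir, "images"),
                                file.path(config$data_dir, "masks"))
  }
  if (length(train_samples) == 0L) stop("empty training set")
  if (is.null(val_samples) && !is.null(config$val_dir)) {
    val_samples <- load_pairs(file.path(config$val_dir, "images"),
                              file.path(config$val_dir, "masks"))
  }

  model <- build_model(config$model)
  params <- collect_params(model$modules)
  start_epoch <- 1L
  step <- 0L
  if (!is.null(resume_from)) {
    ck <- if (is.character(resume_from)) load_checkpoint(resume_from) else resume_from
    restore_checkpoint_into(model, ck)
    for (nm in names(ck$adam$m)) {
      params[[nm]]$m <- ck$adam$m[[nm]]
      params[[nm]]$v <- ck$adam$v[[nm]]
    }
    start_epoch <- ck$epoch + 1L
    step <- ck$step
  }

  n <- length(train_samples)
  log <- NULL
  best <- NULL
  best_iou <- -Inf
  for (epoch in seq.int(start_epoch, config$epochs)) {
    order <- with_seed(config$seed + 131071L * epoch, sample.int(n))
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    losses <- numeric(length(batches))
    accs <- numeric(length(batches))
    for (b in seq_along(batches)) {
      batch <- samples_to_batch(train_samples, batches[[b]])
      tape <- ag_tape()
      x <- ag_leaf(tape, batch$x)
      prob <- model_forward(model, tape, x, train = TRUE)
      loss <- op_dice_loss(tape, prob, batch$g)
      if (!is.finite(loss$value)) {
        stop(sprintf("NaN/Inf loss at epoch %d batch %d - aborting", epoch, b))
      }
      losses[b] <- loss$value
      accs[b] <- mean(((prob$value >= 0.5) * 1) == batch$g)
      ag_backward(tape, loss)
      step <- step + 1L
      adam_step(params, config$lr, step)
    }
    val_loss <- NA_real_
    val <- list(precision = NA_real_, recall = NA_real_, iou = NA_real_,
                f1 = NA_real_)
    if (!is.null(val_samples) && length(val_samples)) {
      ev <- evaluate_dataset(model, val_samples)
      val <- ev
      val_loss <- mean(vapply(val_samples, function(s) {
        dice_loss(model_predict(model, s$image), s$mask)
      }, 1))
      if (ev$iou > best_iou) {
        best_iou <- ev$iou
        best <- make_checkpoint(model, params, epoch, step)
        if (!is.null(config$checkpoint_path)) {
          save_checkpoint(best, config$checkpoint_path)
        }
      }
    }
    row <- data.frame(epoch = epoch, train_loss = mean(losses),
                      train_acc = mean(accs), val_loss = val_loss,
                      val_precision = val$precision, val_recall = val$recall,
                      val_iou = val$iou, val_f1 = val$f1)
    log <- rbind(log, row)
    line <- sprintf(
      "epoch %3d  train_loss %.4f  train_acc %.4f  val_loss %s  val_iou %s",
      epoch, row$train_loss, row$train_acc,
      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
      ifelse(is.na(val$iou), "-", sprintf("%.4f", val$iou)))
    if (verbose) message(line)
    if (!is.null(config$log_path)) {
      cat(line, "\n", file = config$log_path, append = TRUE)
    }
  }
  if (is.null(best)) {
    best <- make_checkpoint(model, params, config$epochs, step)
    if (!is.null(config$checkpoint_path)) {
      save_checkpoint(best, config$checkpoint_path)
    }
  }
  structure(list(model = model, log = log, best = best, config = config),
            class = "train_result")
}

# ---- checkpoints -----------------------------------------------------------

make_checkpoint <- function(model, params, epoch, step) {
  bn <- collect_bn_states(model$modules)
  list(config = model$config,
       values = lapply(params, function(p) p$value),
       bn = lapply(bn, function(s) list(mean = s$running_mean,
                                        var = s$running_var)),
       adam = list(m = lapply(params, function(p) p$m),
                   v = lapply(params, function(p) p$v)),
       epoch = epoch, step = step)
}

restore_checkpoint_into <- function(model, ck) {
  params <- collect_params(model$modules)
  stopifnot(identical(sort(names(params)), sort(names(ck$values))))
  for (nm in names(ck$values)) params[[nm]]$value <- ck$values[[nm]]
  bn <- collect_bn_states(model$modules)
  for (nm in names(ck$bn)) {
    bn[[nm]]$running_mean <- ck$bn[[nm]]$mean
    bn[[nm]]$running_var <- ck$bn[[nm]]$var
  }
  invisible(model)
}

#' Save / load / restore model checkpoints
#'
#' Checkpoints embed the [model_config()], all parameter values, batch-norm
#' running statistics and optimiser state, so `load -> predict` is
#' bit-identical to predicting before saving.
#'
#' @param ck a checkpoint (from a `train_result$best` or [make_checkpoint])
#' @param path file path (RDS)
#' @return `load_checkpoint` returns the checkpoint;
#'   `model_from_checkpoint` a rebuilt `mares_model`
#' @export
save_checkpoint <- function(ck, path) {
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' @rdname save_checkpoint
#' @export
model_from_checkpoint <- function(ck) {
  if (is.character(ck)) ck <- load_checkpoint(ck)
  model <- build_model(ck$config)
  restore_checkpoint_into(model, ck)
  model
}

# ---- prediction ------------------------------------------------------------

reflect_pad <- function(img, to_h, to_w) {
  h <- nrow(img); w <- ncol(img)
  ri <- c(seq_len(h), seq.int(h, by = -1L, length.out = to_h - h))
  ci <- c(seq_len(w), seq.int(w, by = -1L, length.out = to_w - w))
  img[ri, ci, drop = FALSE]
}

#' Predict a lesion probability map and binary mask for one image
#'
#' Images whose size is not divisible by `2^depth` are reflect-padded up to
#' the next multiple and the outputs cropped back.
#'
#' @param model a `mares_model` (or checkpoint via [model_from_checkpoint()])
#' @param image `H x W` matrix with values in 0-255 (or 0-1)
#' @param threshold binarisation threshold
#' @return list with `prob` (H x W matrix in (0, 1)) and `mask` (binary)
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  stopifnot(is.matrix(image))
  if (max(image) > 1) image <- image / 255
  f <- 2L^model$config$depth
  h <- nrow(image); w <- ncol(image)
  hp <- as.integer(ceiling(h / f) * f)
  wp <- as.integer(ceiling(w / f) * f)
  padded <- if (hp != h || wp != w) reflect_pad(image, hp, wp) else image
  prob <- model_predict(model, padded)[1, , , 1]
  prob <- prob[seq_len(h), seq_len(w), drop = FALSE]
  list(prob = prob, mask = (prob >= threshold) * 1)
}

#' Predict masks for a set of images and write PNG outputs
#'
#' Writes `<id>_prob.png` (8-bit scaled probabilities) and `<id>_mask.png`
#' (0/255) per image.
#'
#' @param model a `mares_model`
#' @param samples list of `image_sample` (or matrices)
#' @param out_dir output directory
#' @param threshold binarisation threshold
#' @return invisibly, the ids written
#' @export
predict_to_dir <- function(model, samples, out_dir, threshold = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    img <- if (is.matrix(s)) s else s$image
    ids[i] <- if (is.matrix(s)) sprintf("image_%04d", i) else s$source_id
    pr <- predict_mask(model, img, threshold)
    png::writePNG(pr$prob, file.path(out_dir, paste0(ids[i], "_prob.png")))
    png::writePNG(pr$mask, file.path(out_dir, paste0(ids[i], "_mask.png")))
  }
  invisible(ids)
}

# ---- ablation harness ------------------------------------------------------

#' Train and compare architecture variants on a shared dataset
#'
#' @param configs list of [train_config()]s (sharing data via the arguments)
#' @param train_samples,val_samples,test_samples shared sample lists
#' @param verbose print progress
#' @return data.frame with one row per variant and the four metrics (%)
#' @export
run_ablation <- function(configs, train_samples, val_samples = NULL,
                         test_samples, verbose = FALSE) {
  rows <- lapply(configs, function(cf) {
    fit <- train_model(cf, train_samples, val_samples, verbose = verbose)
    model <- model_from_checkpoint(fit$best)
    ev <- evaluate_dataset(model, test_samples)
    data.frame(variant = variant_name(cf$model),
               precision = 100 * ev$precision, recall = 100 * ev$recall,
               iou = 100 * ev$iou, f1 = 100 * ev$f1)
  })
  do.call(rbind, rows)
}
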
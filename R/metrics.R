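# Segmentation metrics on pixel confusion counts, and the Dice training loss.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary masks (0/1) of identical shape
#' @return list of class `confusion_counts` with TP, FP, FN, TN
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("pred and truth must have identical shape")
  }
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("masks must be binary (values 0 or 1)")
  }
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

# Shared degenerate-denominator convention: when neither mask contains a
# positive pixel (TP + FP + FN == 0) every metric is 1; otherwise a zero
# denominator (or TP == 0 for F1) yields 0.
.metric_ratio <- function(num, den, c) {
  if (c$TP + c$FP + c$FN == 0) return(1)
  if (den == 0) return(0)
  num / den
}

#' @rdname segmentation_metrics
#' @export
precision <- function(c) .metric_ratio(c$TP, c$TP + c$FP, c)

#' @rdname segmentation_metrics
#' @export
recall <- function(c) .metric_ratio(c$TP, c$TP + c$FN, c)

#' @rdname segmentation_metrics
#' @export
iou <- function(c) .metric_ratio(c$TP, c$TP + c$FP + c$FN, c)

#' Segmentation metrics from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `iou = TP/(TP+FP+FN)` and
#' `f1_score = 2PR/(P+R)`. When both masks are empty (TP+FP+FN = 0) all four
#' return 1; any other degenerate denominator returns 0.
#'
#' @param c a [confusion_counts()] result
#' @return fraction in `[0, 1]`
#' @name segmentation_metrics
#' @export
f1_score <- function(c) {
  if (c$TP + c$FP + c$FN == 0) return(1)
  p <- precision(c)
  r <- recall(c)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Smoothed Dice loss
#'
#' `1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)` with smoothing
#' `eps = 1`, computed over all pixels of one probability map against its
#' binary ground truth.
#'
#' @param prob probability map in `[0, 1]`
#' @param truth binary mask of the same shape
#' @param eps smoothing constant
#' @return scalar loss in `[0, 1)`
#' @export
dice_loss <- function(prob, truth, eps = 1) {
  dp <- dim(prob); dt <- dim(truth)
  if (!identical(as.integer(dp), as.integer(dt)) ||
      length(prob) != length(truth)) {
    stop("prob and truth must have identical shape")
  }
  1 - (2 * sum(prob * truth) + eps) / (sum(prob) + sum(truth) + eps)
}

metric_row <- function(c) {
  data.frame(precision = precision(c), recall = recall(c), iou = iou(c),
             f1 = f1_score(c))
}

#' Evaluate a model over a set of image/mask samples
#'
#' Predicts each image, binarises the probability map at `threshold` and
#' reports precision, recall, IoU and F1. With `aggregation = "per_image_mean"`
#' (default) metrics are computed per image and averaged; with
#' `"global_pool"` confusion counts are pooled over all pixels first, in which
#' case `f1 == 2PR/(P+R)` holds exactly on the reported values.
#'
#' @param model a `mares_model`, or a function mapping an `H x W` image matrix
#'   to a probability map
#' @param samples list of samples, each with elements `image` (`H x W` matrix)
#'   and `mask` (binary `H x W` matrix)
#' @param threshold binarisation threshold in (0, 1)
#' @param aggregation `"per_image_mean"` or `"global_pool"`
#' @return list of class `metrics_report` with the four metrics, `n_images`
#'   and `aggregation`
#' @export
evaluate_dataset <- function(model, samples, threshold = 0.5,
                             aggregation = c("per_image_mean", "global_pool")) {
  aggregation <- match.arg(aggregation)
  if (length(samples) == 0L) stop("empty sample list")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  predict_one <- if (is.function(model)) {
    model
  } else {
    function(img) predict_mask(model, img)$prob
  }
  counts <- lapply(samples, function(s) {
    prob <- predict_one(s$image)
    pred <- (as.vector(prob) >= threshold) * 1
    dim(pred) <- dim(s$mask)
    confusion_counts(pred, s$mask)
  })
  if (aggregation == "per_image_mean") {
    rows <- do.call(rbind, lapply(counts, metric_row))
    res <- colMeans(rows)
  } else {
    tot <- structure(list(TP = sum(vapply(counts, `[[`, 1, "TP")),
                          FP = sum(vapply(counts, `[[`, 1, "FP")),
                          FN = sum(vapply(counts, `[[`, 1, "FN")),
                          TN = sum(vapply(counts, `[[`, 1, "TN"))),
                     class = "confusion_counts")
    res <- unlist(metric_row(tot))
  }
  structure(list(precision = unname(res["precision"]),
                 recall = unname(res["recall"]),
                 iou = unname(res["iou"]),
                 f1 = unname(res["f1"]),
                 n_images = length(samples),
                 aggregation = aggregation),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d images (%s)\n", x$n_images, x$aggregation))
  cat(sprintf("precision %.2f%%  recall %.2f%%  IoU %.2f%%  F1 %.2f%%\n",
              100 * x$precision, 100 * x$recall, 100 * x$iou, 100 * x$f1))
  invisible(x)
}

#' Write a metrics report to CSV or JSON
#'
#' Percentages are written with two decimals.
#'
#' @param report a [evaluate_dataset()] result
#' @param path output file; format chosen by extension (.csv or .json)
#' @return `path`, invisibly
#' @export
write_metrics_report <- function(report, path) {
  vals <- list(precision = round(100 * report$precision, 2),
               recall = round(100 * report$recall, 2),
               iou = round(100 * report$iou, 2),
               f1 = round(100 * report$f1, 2),
               n_images = report$n_images,
               aggregation = report$aggregation)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(vals), path, row.names = FALSE)
  }
  invisible(path)
}
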
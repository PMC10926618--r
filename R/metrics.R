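#' Confusion-matrix segmentation metrics
#'
#' Pixel-level evaluation of multi-class segmentations through a C x C
#' confusion matrix. All per-class indices are one-vs-rest marginals:
#' `TP_c = counts[c, c]`, `FP_c = colSum - TP`, `FN_c = rowSum - TP`.
#' Ratios with empty denominators use the `0/0 = 1` convention so that a
#' class absent from both maps scores perfectly; `miou()` and
#' `mean_dice()` can alternatively exclude such classes from the average.
#'
#' @name metrics
NULL

#' Build a confusion matrix from a prediction and a ground truth
#'
#' @param pred,truth Integer label maps of identical shape, 0-based class
#'   indices smaller than `num_classes`.
#' @param num_classes Number of classes `C`.
#' @return `sono_confusion` object: list with `counts` (C x C integer
#'   matrix, rows = truth, columns = prediction) and `num_classes`.
#' @export
confusion_matrix <- function(pred, truth, num_classes) {
  p <- flatten_labels(pred); g <- flatten_labels(truth)
  if (length(p) != length(g)) stop("pred and truth differ in shape")
  if (length(p) && (min(p, g) < 0L || max(p, g) >= num_classes)) {
    stop("label outside [0, num_classes)")
  }
  counts <- matrix(tabulate(g * num_classes + p + 1L, nbins = num_classes^2),
                   nrow = num_classes, byrow = TRUE)
  dimnames(counts) <- if (num_classes == length(sono_classes())) {
    list(truth = sono_classes(), pred = sono_classes())
  } else NULL
  structure(list(counts = counts, num_classes = num_classes),
            class = "sono_confusion")
}

class_marginals <- function(cm, class_index) {
  k <- class_index + 1L
  tp <- cm$counts[k, k]
  fp <- sum(cm$counts[, k]) - tp
  fn <- sum(cm$counts[k, ]) - tp
  tn <- sum(cm$counts) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

ratio01 <- function(num, den) if (den == 0) 1 else num / den

#' Dice coefficient of one class
#'
#' `2 TP / (2 TP + FP + FN)`; 1 when the class is absent from both maps.
#'
#' @param cm A `sono_confusion`.
#' @param class_index 0-based class.
#' @export
dice <- function(cm, class_index) {
  m <- class_marginals(cm, class_index)
  ratio01(2 * m$tp, 2 * m$tp + m$fp + m$fn)
}

#' Intersection over union of one class
#'
#' `TP / (TP + FP + FN)`; 1 when the class is absent from both maps.
#' @inheritParams dice
#' @export
iou <- function(cm, class_index) {
  m <- class_marginals(cm, class_index)
  ratio01(m$tp, m$tp + m$fp + m$fn)
}

#' Mean IOU over classes
#'
#' Unweighted mean of per-class IOU. `average = "all"` includes every class
#' (background too); `"present"` drops classes absent from both maps.
#' @param cm A `sono_confusion`.
#' @param average `"all"` or `"present"`.
#' @export
miou <- function(cm, average = c("all", "present")) {
  average <- match.arg(average)
  cls <- which(class_present(cm, average)) - 1L
  mean(vapply(cls, function(c) iou(cm, c), 0.0))
}

#' Mean Dice over classes
#' @inheritParams miou
#' @export
mean_dice <- function(cm, average = c("all", "present")) {
  average <- match.arg(average)
  cls <- which(class_present(cm, average)) - 1L
  mean(vapply(cls, function(c) dice(cm, c), 0.0))
}

class_present <- function(cm, average) {
  if (average == "all") rep(TRUE, cm$num_classes)
  else (rowSums(cm$counts) + colSums(cm$counts)) > 0
}

#' Overall pixel accuracy
#'
#' Fraction of correctly labelled pixels, `trace / total`; reduces to
#' `(TP + TN) / (TP + TN + FP + FN)` in the two-class case.
#' @param cm A `sono_confusion`.
#' @export
pixel_accuracy <- function(cm) {
  tot <- sum(cm$counts)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm$counts)) / tot
}

#' Category pixel accuracy (per-class precision)
#'
#' `TP / (TP + FP)`: of pixels predicted as class `c`, the fraction whose
#' truth is `c`; 1 when the class is never predicted.
#' @inheritParams dice
#' @export
cpa <- function(cm, class_index) {
  m <- class_marginals(cm, class_index)
  ratio01(m$tp, m$tp + m$fp)
}

#' Full metrics report
#'
#' Per-class Dice/IOU/CPA plus aggregate mean Dice, mIOU and pixel
#' accuracy.
#'
#' @param cm A `sono_confusion`.
#' @param average Aggregation rule for mean Dice and mIOU.
#' @return `sono_metrics_report`: list with `per_class` (data frame) and
#'   `aggregate` (named numeric vector), plus the confusion matrix.
#' @export
metrics_report <- function(cm, average = c("all", "present")) {
  average <- match.arg(average)
  C <- cm$num_classes
  nm <- if (C == length(sono_classes())) sono_classes() else paste0("class", 0:(C - 1L))
  per <- data.frame(
    class_index = 0:(C - 1L),
    name = nm,
    dice = vapply(0:(C - 1L), function(c) dice(cm, c), 0.0),
    iou = vapply(0:(C - 1L), function(c) iou(cm, c), 0.0),
    cpa = vapply(0:(C - 1L), function(c) cpa(cm, c), 0.0)
  )
  agg <- c(dice = mean_dice(cm, average), miou = miou(cm, average),
           pa = pixel_accuracy(cm))
  structure(list(per_class = per, aggregate = agg, confusion = cm,
                 average = average),
            class = "sono_metrics_report")
}

#' @export
print.sono_metrics_report <- function(x, ...) {
  cat("Segmentation metrics (class average:", x$average, ")\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("mean Dice %.4f | mIOU %.4f | PA %.4f\n",
              x$aggregate["dice"], x$aggregate["miou"], x$aggregate["pa"]))
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' @param report A `sono_metrics_report`.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.csv` (per-class table) and `<prefix>.json` (everything,
#'   including the confusion matrix).
#' @export
write_metrics_report <- function(report, path_prefix) {
  write.csv(report$per_class, paste0(path_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(per_class = report$per_class,
         aggregate = as.list(report$aggregate),
         confusion = report$confusion$counts),
    paste0(path_prefix, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(path_prefix, c(".csv", ".json")))
}
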
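#' Lovasz-Softmax loss and its building blocks
#'
#' The per-class Jaccard loss `1 - |P_c intersect G_c| / |P_c union G_c|` is
#' a submodular set function of the mispredicted pixel set, so its Lovasz
#' extension is its tight convex closure on `[0,1]^p`: a piecewise-linear
#' function that agrees with the discrete loss on every vertex of the
#' hypercube and can be minimised with first-order methods. The
#' Lovasz-Softmax loss applies this extension to the per-class pixel error
#' vectors built from softmax probabilities and averages over classes.
#'
#' @name lovasz
NULL

# normalize label inputs: accept integer matrix/vector, return integer vector
flatten_labels <- function(x) {
  v <- as.integer(round(as.vector(x)))
  if (anyNA(v)) stop("label map contains NA")
  v
}

#' Numerically stable softmax over per-pixel class scores
#'
#' Maps unnormalised scores `F_i(c)` to probabilities
#' `f_i(c) = exp(F_i(c)) / sum_c' exp(F_i(c'))`, subtracting the per-pixel
#' maximum before exponentiating.
#'
#' @param scores Numeric matrix (pixels x classes) or array `(H, W, C)`.
#' @return Probability matrix of the same pixel count, rows summing to 1.
#'   For array input the `(H, W, C)` shape is preserved.
#' @export
softmax_scores <- function(scores) {
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores contain NA or non-finite values")
  }
  d <- dim(scores)
  arr3 <- !is.null(d) && length(d) == 3L
  m <- if (arr3) matrix(scores, ncol = d[3]) else as.matrix(scores)
  m <- m - m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m)
  p <- e / rowSums(e)
  if (arr3) array(p, d) else p
}

#' Discrete Jaccard loss of one class
#'
#' `1 - |{Y=c} intersect {Y*=c}| / |{Y=c} union {Y*=c}|`, with the `0/0 = 1`
#' convention for the index, so the loss is 0 when the class is absent from
#' both maps.
#'
#' @param pred,truth Integer label maps of identical shape (classes 0-based).
#' @param class_index 0-based class.
#' @return Loss in `[0, 1]`.
#' @export
jaccard_loss_discrete <- function(pred, truth, class_index) {
  p <- flatten_labels(pred); g <- flatten_labels(truth)
  if (length(p) != length(g)) stop("pred and truth differ in size")
  inter <- sum(p == class_index & g == class_index)
  uni <- sum(p == class_index | g == class_index)
  if (uni == 0L) return(0)
  1 - inter / uni
}

#' Per-class pixel error vector
#'
#' `E_i(c) = 1 - f_i(c)` on pixels whose ground truth is `c`, and `f_i(c)`
#' elsewhere: the amount of probability mass placed on the wrong side.
#'
#' @param probs Probability matrix (pixels x classes), rows summing to 1,
#'   or an `(H, W, C)` array.
#' @param truth Integer label map with `length == nrow(probs)` pixels.
#' @param class_index 0-based class.
#' @return An object of class `sono_error_vector`: list with `values`
#'   (length-p errors in `[0,1]`), `gt_mask` (0/1 indicator of `{Y=c}`) and
#'   `class_index`.
#' @export
error_vector <- function(probs, truth, class_index) {
  d <- dim(probs)
  m <- if (!is.null(d) && length(d) == 3L) matrix(probs, ncol = d[3]) else as.matrix(probs)
  g <- flatten_labels(truth)
  if (length(g) != nrow(m)) stop("probs and truth pixel counts differ")
  if (max(abs(rowSums(m) - 1)) > 1e-6) stop("probability rows must sum to 1")
  fc <- m[, class_index + 1L]
  gt <- as.numeric(g == class_index)
  structure(
    list(values = gt * (1 - fc) + (1 - gt) * fc,
         gt_mask = gt, class_index = class_index),
    class = "sono_error_vector"
  )
}

#' Gradient vector of the Lovasz extension of the Jaccard loss
#'
#' Given the ground-truth indicator permuted by the descending-error order,
#' returns the forward differences of the discrete Jaccard loss over the
#' growing prefix sets, computed in O(p) with cumulative intersection and
#' union counts.
#'
#' @param sorted_gt 0/1 vector: the `{Y=c}` indicator sorted by descending
#'   error.
#' @return Numeric vector `g` with `g_i = Delta({pi_1..pi_i}) -
#'   Delta({pi_1..pi_{i-1}})`.
#' @export
lovasz_grad <- function(sorted_gt) {
  p <- length(sorted_gt)
  if (p == 0L) return(numeric(0))
  gts <- sum(sorted_gt)
  intersection <- gts - cumsum(sorted_gt)
  union <- gts + cumsum(1 - sorted_gt)
  jacc <- 1 - intersection / union      # union_i >= max(i, gts) >= 1
  g <- jacc
  if (p > 1L) g[2:p] <- jacc[2:p] - jacc[1:(p - 1L)]
  g
}

#' Lovasz extension of the Jaccard loss at an error vector
#'
#' Sorts the errors in descending order (ties broken by ascending pixel
#' index, which selects one valid subgradient), and returns the inner
#' product of the sorted errors with [lovasz_grad()]. On binary error
#' vectors the value equals the discrete Jaccard loss.
#'
#' @param err A `sono_error_vector`, or a numeric error vector (then
#'   `gt_mask` must be given).
#' @param gt_mask Optional 0/1 ground-truth indicator when `err` is a bare
#'   numeric vector.
#' @return Scalar extension value.
#' @export
lovasz_extension <- function(err, gt_mask = NULL) {
  if (inherits(err, "sono_error_vector")) {
    e <- err$values; gt <- err$gt_mask
  } else {
    e <- as.numeric(err); gt <- gt_mask
    if (is.null(gt)) stop("gt_mask required for bare error vectors")
  }
  if (length(e) == 0L) return(0)
  perm <- order(e, decreasing = TRUE)   # stable: ties keep ascending index
  sum(e[perm] * lovasz_grad(gt[perm]))
}

#' Lovasz-Softmax loss
#'
#' Mean over classes of the Lovasz extension applied to each class's pixel
#' error vector. With `class_average = "all"` the mean runs over all `C`
#' classes; `"present"` restricts it to classes occurring in the truth or
#' the prediction argmax, which is useful for mini-batches that lack rare
#' classes.
#'
#' @param probs Probability matrix (pixels x classes) or `(H, W, C)` array.
#' @param truth Integer label map, 0-based classes.
#' @param class_average `"all"` (default) or `"present"`.
#' @return Scalar loss in `[0, 1]`.
#' @export
lovasz_softmax_loss <- function(probs, truth, class_average = c("all", "present")) {
  class_average <- match.arg(class_average)
  d <- dim(probs)
  m <- if (!is.null(d) && length(d) == 3L) matrix(probs, ncol = d[3]) else as.matrix(probs)
  if (nrow(m) == 0L) stop("empty probability map")
  g <- flatten_labels(truth)
  C <- ncol(m)
  cls <- 0:(C - 1L)
  if (class_average == "present") {
    pred <- max.col(m, ties.method = "first") - 1L
    cls <- sort(unique(c(g, pred)))
  }
  vals <- vapply(cls, function(c) lovasz_extension(error_vector(m, g, c)), 0.0)
  mean(vals)
}

# Loss and gradient of the (class-averaged) Lovasz-Softmax loss with
# respect to the pre-softmax scores in one pass, derived analytically: for
# each class the extension is locally linear in the error vector with
# coefficients g (in sorted order); dE/df flips sign on ground-truth
# pixels; the softmax Jacobian follows. Internal; exercised by
# finite-difference tests.
lovasz_softmax_loss_grad <- function(probs, truth,
                                     class_average = c("all", "present")) {
  class_average <- match.arg(class_average)
  m <- as.matrix(probs)
  g <- flatten_labels(truth)
  C <- ncol(m)
  cls <- 0:(C - 1L)
  if (class_average == "present") {
    pred <- max.col(m, ties.method = "first") - 1L
    cls <- sort(unique(c(g, pred)))
  }
  dLdf <- matrix(0, nrow(m), C)
  loss <- 0
  for (c in cls) {
    gt <- as.numeric(g == c)
    fc <- m[, c + 1L]
    e <- gt * (1 - fc) + (1 - gt) * fc
    perm <- order(e, decreasing = TRUE)
    gr <- lovasz_grad(gt[perm])
    loss <- loss + sum(e[perm] * gr)
    de <- numeric(length(e)); de[perm] <- gr
    dLdf[, c + 1L] <- de * (1 - 2 * gt)
  }
  dLdf <- dLdf / length(cls)
  # chain through softmax: dL/dF = f * (dL/df - sum_c dL/df_c * f_c)
  list(loss = loss / length(cls),
       dscores = m * (dLdf - rowSums(dLdf * m)))
}

lovasz_softmax_dscores <- function(probs, truth,
                                   class_average = c("all", "present")) {
  lovasz_softmax_loss_grad(probs, truth, class_average)$dscores
}
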
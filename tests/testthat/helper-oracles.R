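# Independent oracles used across the suite. These deliberately avoid the
# package's fast paths: set-based Jaccard evaluation, literal prefix-set
# Lovasz gradients, per-pixel metric loops.

# discrete Jaccard loss evaluated from explicit pixel sets
oracle_jaccard_loss_set <- function(gt_set, err_set, p) {
  # Delta(E) = |E| / |{Y=c} union E| with Delta(empty) = 0
  if (length(err_set) == 0L) return(0)
  length(err_set) / length(union(gt_set, err_set))
}

# literal evaluation of the prefix-set gradient: g_i =
# Delta({pi_1..pi_i}) - Delta({pi_1..pi_{i-1}}) where the mispredicted set
# grows one sorted pixel at a time
oracle_lovasz_grad <- function(sorted_gt) {
  p <- length(sorted_gt)
  gt_set <- which(sorted_gt == 1)
  prev <- 0
  g <- numeric(p)
  for (i in seq_len(p)) {
    cur <- oracle_jaccard_loss_set(gt_set, seq_len(i), p)
    g[i] <- cur - prev
    prev <- cur
  }
  g
}

# Lovasz extension by its definition: sort, then weighted sum
oracle_lovasz_extension <- function(e, gt) {
  perm <- order(e, decreasing = TRUE)
  sum(e[perm] * oracle_lovasz_grad(gt[perm]))
}

# per-pixel double-loop confusion matrix
oracle_confusion <- function(pred, truth, C) {
  counts <- matrix(0L, C, C)
  for (i in seq_along(pred)) {
    t <- truth[i] + 1L; p <- pred[i] + 1L
    counts[t, p] <- counts[t, p] + 1L
  }
  counts
}

# enumerate all labelings of p pixels over C classes as a matrix of rows
enumerate_labelings <- function(p, C) {
  as.matrix(expand.grid(rep(list(0:(C - 1L)), p)))
}

# one-hot probability rows for a labeling
one_hot_probs <- function(labels, C) {
  m <- matrix(0, length(labels), C)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

tiny_cfg <- function(...) {
  model_config(encoder_widths = c(2L, 3L, 4L, 5L, 8L),
               ppm_bins = c(1L, 2L), ...)
}

small_phantom_set <- function(n, size = 32L, seed = 1L) {
  phantom_dataset(n, phantom_spec(image_size = size), seed = seed)
}
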
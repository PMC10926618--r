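#' Frame preparation and training-time augmentation
#'
#' Frames are optionally cropped to a configured region of interest,
#' resized to the network input size, rescaled to `[0, 1]` and (optionally)
#' denoised with a non-local-means filter. Augmentation applies one random
#' geometric transform (flip, rotation, zoom, crop-rescale) identically to
#' the image (bilinear) and the label map (nearest-neighbour, so labels are
#' never interpolated into new classes).
#'
#' @name preprocessing
NULL

#' Non-local means denoising
#'
#' Each pixel is replaced by a weighted average of pixels whose local
#' patches look similar; weights are `exp(-d2 / h^2)` with `d2` the
#' Gaussian-weighted squared patch distance. Effective on multiplicative
#' speckle while preserving edges.
#'
#' @param image `H x W` matrix in `[0, 1]`.
#' @param patch_size Odd patch width (default 5).
#' @param search_window Odd search window width (default 11); must be at
#'   least `patch_size`.
#' @param h Filtering strength (default 0.1, image units).
#' @return Denoised matrix in `[0, 1]`.
#' @export
nlm_denoise <- function(image, patch_size = 5L, search_window = 11L, h = 0.1) {
  if (search_window < patch_size) stop("search window smaller than patch")
  if (patch_size %% 2L == 0L || search_window %% 2L == 0L) {
    stop("patch_size and search_window must be odd")
  }
  out <- .nlm_cpp(as.matrix(image), (patch_size - 1L) %/% 2L,
                  (search_window - 1L) %/% 2L, h)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Augmentation configuration
#'
#' @param flip_prob Probability of a horizontal flip.
#' @param rotate_range Max absolute rotation in degrees (uniform in
#'   `[-r, r]`).
#' @param crop_scale_range Range of the retained side fraction for a random
#'   crop-and-rescale (1 = no crop).
#' @param zoom_range Range of the isotropic zoom factor.
#' @return An `sono_augment_config`.
#' @export
augment_config <- function(flip_prob = 0.5, rotate_range = 15,
                           crop_scale_range = c(0.9, 1), zoom_range = c(0.9, 1.1)) {
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must be in [0, 1]")
  if (crop_scale_range[1] > crop_scale_range[2] ||
      zoom_range[1] > zoom_range[2]) stop("ranges must be ordered")
  structure(list(flip_prob = flip_prob, rotate_range = rotate_range,
                 crop_scale_range = crop_scale_range, zoom_range = zoom_range),
            class = "sono_augment_config")
}

# inverse-mapped affine sampling; `interp` is "bilinear" or "nearest"
warp_affine <- function(m, theta, scale, shift_r, shift_c, flip, interp) {
  H <- nrow(m); W <- ncol(m)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  dst_r <- matrix(rep(seq_len(H), W), H, W) - cr
  dst_c <- matrix(rep(seq_len(W), each = H), H, W) - cc
  if (flip) dst_c <- -dst_c
  # inverse transform: rotate by -theta, divide by scale
  ct <- cos(-theta); st <- sin(-theta)
  src_r <- (ct * dst_r - st * dst_c) / scale + cr + shift_r
  src_c <- (st * dst_r + ct * dst_c) / scale + cc + shift_c
  if (interp == "nearest") {
    ri <- pmin(pmax(round(src_r), 1), H)
    ci <- pmin(pmax(round(src_c), 1), W)
    matrix(m[cbind(as.vector(ri), as.vector(ci))], H, W)
  } else {
    r0 <- pmin(pmax(floor(src_r), 1), H); r1 <- pmin(r0 + 1, H)
    c0 <- pmin(pmax(floor(src_c), 1), W); c1 <- pmin(c0 + 1, W)
    fr <- pmin(pmax(src_r - r0, 0), 1); fc <- pmin(pmax(src_c - c0, 0), 1)
    v00 <- m[cbind(as.vector(r0), as.vector(c0))]
    v01 <- m[cbind(as.vector(r0), as.vector(c1))]
    v10 <- m[cbind(as.vector(r1), as.vector(c0))]
    v11 <- m[cbind(as.vector(r1), as.vector(c1))]
    matrix((1 - fr) * ((1 - fc) * v00 + fc * v01) +
             fr * ((1 - fc) * v10 + fc * v11), H, W)
  }
}

#' Apply one seeded random augmentation to an image/label pair
#'
#' The same geometric transform is applied to both inputs; the image is
#' bilinearly interpolated, the label map uses nearest-neighbour sampling.
#' Deterministic given `(cfg, seed)`.
#'
#' @param image `H x W` matrix.
#' @param labels `H x W` integer label matrix of the same shape.
#' @param cfg An [augment_config()].
#' @param seed Integer seed.
#' @return List with transformed `image` and `labels`.
#' @export
augment <- function(image, labels, cfg = augment_config(), seed = 0L) {
  stopifnot(inherits(cfg, "sono_augment_config"))
  if (!all(dim(image) == dim(labels))) stop("image/labels shape mismatch")
  prm <- with_seed(derive_seed(seed, 13L), list(
    flip = runif(1) < cfg$flip_prob,
    theta = runif(1, -cfg$rotate_range, cfg$rotate_range) * pi / 180,
    zoom = runif(1, cfg$zoom_range[1], cfg$zoom_range[2]),
    crop = runif(1, cfg$crop_scale_range[1], cfg$crop_scale_range[2]),
    off = runif(2, -1, 1)
  ))
  scale <- prm$zoom / prm$crop           # crop-and-rescale = extra zoom-in
  margin_r <- nrow(image) * (1 - prm$crop) / 2
  margin_c <- ncol(image) * (1 - prm$crop) / 2
  identityish <- !prm$flip && abs(prm$theta) < 1e-12 && abs(scale - 1) < 1e-12 &&
    margin_r < 1e-9 && margin_c < 1e-9
  if (identityish) return(list(image = image, labels = labels))
  list(
    image = warp_affine(image, prm$theta, scale, prm$off[1] * margin_r,
                        prm$off[2] * margin_c, prm$flip, "bilinear"),
    labels = matrix(as.integer(warp_affine(labels, prm$theta, scale,
                                           prm$off[1] * margin_r,
                                           prm$off[2] * margin_c,
                                           prm$flip, "nearest")),
                    nrow(labels), ncol(labels))
  )
}

#' Prepare a raw frame for the network
#'
#' Optional ROI crop, bilinear resize to `target_size x target_size`, and
#' rescale to `[0, 1]` (8-bit inputs are divided by 255).
#'
#' @param image Numeric matrix (any size; values in `[0, 1]` or 0-255).
#' @param target_size Output side length (default 256).
#' @param roi Optional crop `c(row0, col0, height, width)`, 1-based.
#' @return `target_size x target_size` matrix in `[0, 1]`.
#' @export
prepare_frame <- function(image, target_size = 256L, roi = NULL) {
  m <- as.matrix(image)
  if (max(m) > 1) m <- m / 255
  if (!is.null(roi)) {
    r1 <- roi[1]; c1 <- roi[2]; r2 <- r1 + roi[3] - 1L; c2 <- c1 + roi[4] - 1L
    if (r1 < 1 || c1 < 1 || r2 > nrow(m) || c2 > ncol(m)) {
      stop("ROI outside image bounds")
    }
    m <- m[r1:r2, c1:c2, drop = FALSE]
  }
  if (nrow(m) != target_size || ncol(m) != target_size) {
    a <- array(m, c(nrow(m), ncol(m), 1L, 1L))
    m <- .resize_bilinear_fwd(a, as.integer(target_size),
                              as.integer(target_size))[, , 1L, 1L]
  }
  m[m < 0] <- 0; m[m > 1] <- 1
  m
}

#' Split a dataset into training and test partitions
#'
#' Default 9:1. With `level = "sweep"` the split is made between groups
#' (e.g. frames of the same video stay together, avoiding adjacent-frame
#' leakage); `level = "frame"` splits individual frames.
#'
#' @param items List of samples.
#' @param groups Optional group id per item (required for sweep-level
#'   splitting).
#' @param ratio Training fraction (default 0.9).
#' @param level `"sweep"` or `"frame"`.
#' @param seed Integer seed.
#' @return List with `train` and `test` item lists.
#' @export
split_dataset <- function(items, groups = NULL, ratio = 0.9,
                          level = c("sweep", "frame"), seed = 0L) {
  level <- match.arg(level)
  n <- length(items)
  if (level == "sweep" && !is.null(groups)) {
    ug <- unique(groups)
    tr_g <- with_seed(derive_seed(seed, 17L),
                      sample(ug, max(1L, round(ratio * length(ug)))))
    tr <- which(groups %in% tr_g)
  } else {
    tr <- with_seed(derive_seed(seed, 17L),
                    sample(n, max(1L, round(ratio * n))))
  }
  list(train = items[tr], test = items[setdiff(seq_len(n), tr)])
}

#' Write / read a dataset manifest
#'
#' CSV with columns `image`, `label`, `split`.
#'
#' @param manifest Data frame with those columns.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("image", "label", "split") %in% names(manifest)))
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) read.csv(path, stringsAsFactors = FALSE)
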
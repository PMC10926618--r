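#' Synthetic speckled neck-phantom generator
#'
#' Generates 2-D grayscale "ultrasound-like" cross sections of the neck
#' with paired 6-class label maps, plus ordered multi-frame sweeps cut from
#' 3-D ellipsoids, so the whole pipeline can be exercised without clinical
#' data. The phantom is synthetic, not anatomical: a bright thyroid
#' crescent wrapping an anechoic trachea with a bright rim, 1-3 hypoechoic
#' nodule-or-vessel (NoV) ellipses strictly inside the thyroid, a small
#' esophagus disc beside the trachea, and an anechoic carotid disc.
#' Texture follows the fully-developed-speckle approximation: the
#' piecewise-constant echogenicity map is multiplied by i.i.d. mean-1
#' gamma noise and blurred with a Gaussian point-spread function.
#'
#' @name phantom
NULL

#' Phantom specification
#'
#' @param image_size Square frame size in pixels (default 256).
#' @param echogenicity Named mean reflectivities in `[0, 1]` for the six
#'   classes (plus the tracheal `rim` highlight).
#' @param speckle_shape Gamma shape `k` of the multiplicative speckle
#'   (mean 1, variance `1/k`); `Inf` disables noise.
#' @param psf_sigma Gaussian point-spread sigma in pixels; 0 disables blur.
#' @param geometry Per-structure centre/radius parameters as fractions of
#'   the image size; see defaults. Each entry is `c(min, max)` and is
#'   sampled uniformly per phantom.
#' @return A validated `sono_phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L,
                         echogenicity = c(background = 0.35, thyroid = 0.65,
                                          trachea = 0.06, NoV = 0.22,
                                          esophagus = 0.48, carotid = 0.10,
                                          rim = 0.92),
                         speckle_shape = 4,
                         psf_sigma = 1.5,
                         geometry = default_phantom_geometry()) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) stop("image_size must be at least 32")
  if (any(echogenicity < 0 | echogenicity > 1)) {
    stop("echogenicity values must lie in [0, 1]")
  }
  need <- c(sono_classes(), "rim")
  if (!all(need %in% names(echogenicity))) {
    stop("echogenicity must name: ", paste(need, collapse = ", "))
  }
  if (speckle_shape <= 0) stop("speckle_shape must be positive")
  if (psf_sigma < 0) stop("psf_sigma must be >= 0")
  g <- geometry
  rmax <- max(g$trachea_r[2], g$thyroid_a[2] / 2, g$carotid_r[2],
              g$esophagus_r[2], g$nov_r[2])
  if (rmax >= 0.5) stop("structure radius must be below half the image size")
  structure(list(image_size = image_size, class_set = sono_classes(),
                 echogenicity = echogenicity, speckle_shape = speckle_shape,
                 psf_sigma = psf_sigma, geometry = g),
            class = "sono_phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_geometry <- function() {
  list(
    thyroid_cx = c(0.48, 0.52), thyroid_cy = c(0.40, 0.44),
    thyroid_a = c(0.30, 0.34), thyroid_b = c(0.18, 0.22),
    trachea_cx = c(0.48, 0.52), trachea_cy = c(0.60, 0.64),
    trachea_r = c(0.10, 0.13), rim_width = c(0.015, 0.025),
    nov_n = c(1, 3), nov_r = c(0.03, 0.06),
    esophagus_r = c(0.04, 0.05),
    carotid_r = c(0.05, 0.06), carotid_cy = c(0.42, 0.48)
  )
}

runif1 <- function(rng) runif(1, rng[1], rng[2])

disc_mask <- function(xx, yy, cx, cy, rx, ry = rx) {
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}

# raster masks for one phantom; label painting order is fixed:
# background -> thyroid -> NoV -> trachea -> esophagus -> carotid
phantom_masks <- function(spec) {
  s <- spec$image_size
  g <- spec$geometry
  xx <- matrix(rep((seq_len(s) - 0.5) / s, each = s), s, s)   # column coord
  yy <- matrix(rep((seq_len(s) - 0.5) / s, times = s), s, s)  # row coord
  tcx <- runif1(g$trachea_cx); tcy <- runif1(g$trachea_cy)
  tr <- runif1(g$trachea_r); rimw <- runif1(g$rim_width)
  thx <- runif1(g$thyroid_cx); thy <- runif1(g$thyroid_cy)
  tha <- runif1(g$thyroid_a); thb <- runif1(g$thyroid_b)
  thyroid <- disc_mask(yy, xx, thy, thx, thb, tha) &
    !disc_mask(yy, xx, tcy, tcx, tr * 1.25 + rimw, tr * 1.25 + rimw)
  trachea <- disc_mask(yy, xx, tcy, tcx, tr, tr)
  rim <- disc_mask(yy, xx, tcy, tcx, tr + rimw, tr + rimw) & !trachea
  n_nov <- sample(seq(g$nov_n[1], g$nov_n[2]), 1L)
  nov <- matrix(FALSE, s, s)
  th_idx <- which(thyroid)
  for (k in seq_len(n_nov)) {
    ctr <- th_idx[sample(length(th_idx), 1L)]
    cyk <- ((ctr - 1L) %% s + 0.5) / s
    cxk <- ((ctr - 1L) %/% s + 0.5) / s
    rk <- runif1(g$nov_r)
    ek <- runif(1, 0.7, 1.3)
    nov <- nov | (disc_mask(yy, xx, cyk, cxk, rk, rk * ek) & thyroid)
  }
  er <- runif1(g$esophagus_r)
  ang <- runif(1, 200, 235) * pi / 180   # lower-left of the trachea
  ecx <- tcx + (tr + er * 1.3) * cos(ang)
  ecy <- tcy - (tr + er * 1.3) * sin(ang)
  esoph <- disc_mask(yy, xx, ecy, ecx, er, er)
  cr <- runif1(g$carotid_r)
  side <- sample(c(-1, 1), 1L)
  ccx <- 0.5 + side * 0.36
  ccy <- runif1(g$carotid_cy)
  carotid <- disc_mask(yy, xx, ccy, ccx, cr, cr)
  list(thyroid = thyroid, nov = nov, trachea = trachea, rim = rim,
       esophagus = esoph, carotid = carotid)
}

paint_labels <- function(masks, s) {
  lab <- matrix(0L, s, s)
  lab[masks$thyroid] <- 1L
  lab[masks$nov] <- 3L
  lab[masks$trachea] <- 2L
  lab[masks$esophagus] <- 4L
  lab[masks$carotid] <- 5L
  lab
}

# multiplicative mean-1 gamma speckle field
speckle_field <- function(spec, seed, n_pixels = NULL) {
  n <- n_pixels %||% spec$image_size^2
  if (is.infinite(spec$speckle_shape)) return(rep(1, n))
  with_seed(derive_seed(seed, 7L),
            rgamma(n, shape = spec$speckle_shape, rate = spec$speckle_shape))
}

# separable Gaussian blur via banded row-normalised kernel matrices
gauss_blur_mat <- function(n, sigma) {
  if (sigma <= 0) return(NULL)
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1L, pmin(n, i + (-r:r)))
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + k[t]
  }
  K / rowSums(K)
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Kh <- gauss_blur_mat(nrow(m), sigma)
  Kw <- gauss_blur_mat(ncol(m), sigma)
  Kh %*% m %*% t(Kw)
}

#' Generate one phantom frame
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; the output is deterministic given
#'   `(spec, seed)`.
#' @return List with `image` (`H x W` matrix in `[0, 1]`) and `labels`
#'   (`H x W` integer matrix, classes 0-5).
#' @export
generate_phantom <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "sono_phantom_spec"))
  s <- spec$image_size
  masks <- with_seed(derive_seed(seed, 3L), phantom_masks(spec))
  labels <- paint_labels(masks, s)
  present <- sort(unique(as.vector(labels)))
  if (!identical(present, 0:5)) {
    stop("phantom geometry left a class empty: ",
         paste(setdiff(0:5, present), collapse = ","))
  }
  e <- spec$echogenicity
  refl <- matrix(e[["background"]], s, s)
  refl[masks$rim] <- e[["rim"]]
  refl[labels == 1L] <- e[["thyroid"]]
  refl[labels == 3L] <- e[["NoV"]]
  refl[labels == 2L] <- e[["trachea"]]
  refl[labels == 4L] <- e[["esophagus"]]
  refl[labels == 5L] <- e[["carotid"]]
  sp <- matrix(speckle_field(spec, seed), s, s)
  img <- gauss_blur(refl * sp, spec$psf_sigma)
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, labels = labels)
}

#' Sweep specification: 3-D ellipsoid structures cut into ordered frames
#'
#' Frame `k` is the `z = (k - 1) * slice_spacing` cross-section of a set of
#' 3-D ellipsoids, one or more per class, in the same pixel units as the
#' frame plane. Structures appear and disappear smoothly along the sweep.
#'
#' @param n_frames Number of frames (>= 2).
#' @param slice_spacing Inter-frame distance in pixel-equivalent units.
#' @param structures Data frame with columns `class_index`, `cx`, `cy`,
#'   `cz`, `a`, `b`, `c` (centres and semi-axes, pixel units). `NULL` uses
#'   a default neck-like arrangement built for the given phantom size.
#' @param image_size Frame size in pixels.
#' @return A `sono_sweep_spec`.
#' @export
sweep_spec <- function(n_frames, slice_spacing, structures = NULL,
                       image_size = 256L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (slice_spacing <= 0) stop("slice_spacing must be positive")
  if (is.null(structures)) {
    structures <- default_sweep_structures(image_size, n_frames, slice_spacing)
  }
  need <- c("class_index", "cx", "cy", "cz", "a", "b", "c")
  if (!all(need %in% names(structures))) {
    stop("structures needs columns: ", paste(need, collapse = ", "))
  }
  structure(list(n_frames = n_frames, slice_spacing = slice_spacing,
                 structures = structures, image_size = as.integer(image_size)),
            class = "sono_sweep_spec")
}

#' @rdname sweep_spec
#' @export
default_sweep_structures <- function(image_size = 256L, n_frames = 32L,
                                     slice_spacing = 4) {
  s <- image_size
  zmid <- (n_frames - 1) * slice_spacing / 2
  zlen <- (n_frames - 1) * slice_spacing
  data.frame(
    class_index = c(1L, 3L, 2L, 4L, 5L),
    cx = s * c(0.50, 0.40, 0.50, 0.38, 0.85),
    cy = s * c(0.42, 0.40, 0.62, 0.70, 0.45),
    cz = c(zmid, zmid * 0.9, zmid, zmid, zmid),
    a = s * c(0.32, 0.05, 0.115, 0.045, 0.055),
    b = s * c(0.20, 0.04, 0.115, 0.045, 0.055),
    c = c(zlen * 0.42, zlen * 0.18, zlen * 2, zlen * 0.45, zlen * 2)
  )
}

sweep_label_frame <- function(spec, z) {
  s <- spec$image_size
  xx <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)
  yy <- matrix(rep(seq_len(s) - 0.5, times = s), s, s)
  lab <- matrix(0L, s, s)
  masks <- list()
  for (r in seq_len(nrow(spec$structures))) {
    st <- spec$structures[r, ]
    dz2 <- 1 - ((z - st$cz) / st$c)^2
    key <- as.character(st$class_index)
    m <- if (dz2 <= 0) matrix(FALSE, s, s) else {
      f <- sqrt(dz2)
      disc_mask(yy, xx, st$cy, st$cx, st$b * f, st$a * f)
    }
    masks[[key]] <- if (is.null(masks[[key]])) m else masks[[key]] | m
  }
  # same priority order as 2-D phantoms; NoV constrained inside thyroid
  thy <- masks[["1"]] %||% matrix(FALSE, s, s)
  lab[thy] <- 1L
  if (!is.null(masks[["3"]])) lab[masks[["3"]] & thy] <- 3L
  for (k in c("2", "4", "5")) if (!is.null(masks[[k]])) lab[masks[[k]]] <- as.integer(k)
  lab
}

#' Generate an ordered frame sweep
#'
#' @param spec A [sweep_spec()].
#' @param phantom_spec A [phantom_spec()] providing echogenicity, speckle
#'   and PSF parameters (its `image_size` must match).
#' @param seed Integer seed.
#' @return List with `frames` (list of `H x W` images), `label_frames`
#'   (list of label matrices) and `slice_spacing`.
#' @export
generate_sweep <- function(spec, phantom_spec, seed = 0L) {
  stopifnot(inherits(spec, "sono_sweep_spec"),
            inherits(phantom_spec, "sono_phantom_spec"))
  if (spec$image_size != phantom_spec$image_size) {
    stop("sweep and phantom image sizes differ")
  }
  zmax <- (spec$n_frames - 1L) * spec$slice_spacing
  lohi <- cbind(spec$structures$cz - spec$structures$c,
                spec$structures$cz + spec$structures$c)
  out_of_range <- lohi[, 2] < 0 | lohi[, 1] > zmax
  if (any(out_of_range)) {
    warning("structure(s) entirely outside the sampled z-range: class ",
            paste(spec$structures$class_index[out_of_range], collapse = ","))
  }
  e <- phantom_spec$echogenicity
  lut <- c(e[["background"]], e[["thyroid"]], e[["trachea"]], e[["NoV"]],
           e[["esophagus"]], e[["carotid"]])
  frames <- vector("list", spec$n_frames)
  label_frames <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    lab <- sweep_label_frame(spec, (k - 1L) * spec$slice_spacing)
    refl <- matrix(lut[lab + 1L], spec$image_size, spec$image_size)
    sp <- matrix(speckle_field(phantom_spec, derive_seed(seed, 100L + k)),
                 spec$image_size, spec$image_size)
    img <- gauss_blur(refl * sp, phantom_spec$psf_sigma)
    img[img < 0] <- 0; img[img > 1] <- 1
    frames[[k]] <- img
    label_frames[[k]] <- lab
  }
  list(frames = frames, label_frames = label_frames,
       slice_spacing = spec$slice_spacing)
}

#' Generate a phantom training set
#'
#' Convenience wrapper producing `n` independent phantom frames.
#'
#' @param n Number of frames.
#' @param spec A [phantom_spec()].
#' @param seed Base seed; frame `k` uses a derived child seed.
#' @return List of `list(image, labels)` samples.
#' @export
phantom_dataset <- function(n, spec = phantom_spec(), seed = 0L) {
  lapply(seq_len(n), function(k) generate_phantom(spec, derive_seed(seed, k)))
}

#' Write sweep frames and labels as PNG files
#'
#' Images become 8-bit grayscale PNGs, label maps 8-bit PNGs storing the
#' raw class index per pixel.
#'
#' @param frames,label_frames Lists as produced by [generate_sweep()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, label_frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in seq_along(frames)) {
    fi <- file.path(dir, sprintf("frame_%04d.png", k))
    fl <- file.path(dir, sprintf("label_%04d.png", k))
    png::writePNG(frames[[k]], fi)
    png::writePNG(label_frames[[k]] / 255, fl)
    paths <- c(paths, fi, fl)
  }
  invisible(paths)
}

#' Read back label PNGs written by [write_frames()]
#' @param paths PNG file paths.
#' @return List of integer label matrices.
#' @export
read_label_frames <- function(paths) {
  lapply(paths, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
}
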
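#' Model configuration for the attention-pyramid nested U-Net
#'
#' The segmentation backbone is a nested U-Net (U-Net++): an encoder of five
#' depths with a dense grid of decoder nodes `X[i, j]`, where every node
#' receives all same-depth predecessors `X[i, 0..j-1]` plus the upsampled
#' deeper node `X[i+1, j-1]`. Two additions target ultrasound imagery:
#' a pyramid pooling module (PPM) on the deepest encoder feature injects
#' multi-scale global context, and attention gates (AG) on the decoder skip
#' bundles learn per-pixel coefficients that suppress background responses.
#'
#' @param in_channels Image channels (grayscale ultrasound: 1).
#' @param num_classes Output classes (default 6).
#' @param encoder_widths Five channel widths for depths 0-4. The default
#'   `(32, 64, 128, 256, 512)` is a standard choice; the reduced preset
#'   `tiny_widths()` keeps CPU experiments fast.
#' @param ppm_bins Strictly increasing pooling grid sizes; each bin must fit
#'   the deepest feature map (input size / 16). Default `(1, 2, 3, 6)`.
#' @param ppm_enabled,ag_enabled Toggles for the two modules; both `FALSE`
#'   recovers a plain U-Net++.
#' @param decode_mode `"L2"`, `"L3"`, `"L4"` (single-depth decoding at that
#'   nested column) or `"DS"` (deep supervision: all four heads).
#' @param ds_head_combine How DS predictions are fused at inference:
#'   `"mean"` of the four softmax outputs or `"last"` (the L4 head alone).
#' @param ag_full_grid Gate every nested node's skip bundle instead of only
#'   the outermost decoder column.
#' @return A validated `sono_model_config`.
#' @export
model_config <- function(in_channels = 1L, num_classes = 6L,
                         encoder_widths = c(32L, 64L, 128L, 256L, 512L),
                         ppm_bins = c(1L, 2L, 3L, 6L),
                         ppm_enabled = TRUE, ag_enabled = TRUE,
                         decode_mode = c("DS", "L2", "L3", "L4"),
                         ds_head_combine = c("mean", "last"),
                         ag_full_grid = FALSE) {
  decode_mode <- match.arg(decode_mode)
  ds_head_combine <- match.arg(ds_head_combine)
  encoder_widths <- as.integer(encoder_widths)
  ppm_bins <- as.integer(ppm_bins)
  if (length(encoder_widths) != 5L || any(encoder_widths <= 0L)) {
    stop("encoder_widths must be 5 positive integers")
  }
  if (any(diff(ppm_bins) <= 0L) || any(ppm_bins <= 0L)) {
    stop("ppm_bins must be strictly increasing positive integers")
  }
  if (ppm_enabled && encoder_widths[5] %% length(ppm_bins) != 0L) {
    stop("deepest width must be divisible by the number of PPM bins")
  }
  structure(list(
    in_channels = as.integer(in_channels), num_classes = as.integer(num_classes),
    encoder_widths = encoder_widths, ppm_bins = ppm_bins,
    ppm_enabled = isTRUE(ppm_enabled), ag_enabled = isTRUE(ag_enabled),
    decode_mode = decode_mode, ds_head_combine = ds_head_combine,
    ag_full_grid = isTRUE(ag_full_grid)
  ), class = "sono_model_config")
}

#' Reduced encoder widths for CPU-scale experiments
#' @export
tiny_widths <- function() c(8L, 16L, 32L, 64L, 128L)

# ---- parameter construction ----------------------------------------------

he_conv <- function(kh, kw, cin, cout) {
  w <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(w = new_param(w), b = new_param(numeric(cout)))
}

bn_params <- function(C) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(C); st$var <- rep(1, C)
  list(gamma = new_param(rep(1, C)), beta = new_param(numeric(C)), state = st)
}

conv_block_params <- function(cin, cout) {
  list(c1 = he_conv(3L, 3L, cin, cout), bn1 = bn_params(cout),
       c2 = he_conv(3L, 3L, cout, cout), bn2 = bn_params(cout))
}

ag_params <- function(c_skip, c_gate, c_int) {
  list(theta_x = he_conv(1L, 1L, c_skip, c_int), bn_x = bn_params(c_int),
       theta_g = he_conv(1L, 1L, c_gate, c_int), bn_g = bn_params(c_int),
       psi = he_conv(1L, 1L, c_int, 1L), bn_psi = bn_params(1L))
}

ppm_params <- function(C, bins) {
  red <- C %/% length(bins)
  br <- lapply(bins, function(b) {
    list(conv = he_conv(1L, 1L, C, red), bn = bn_params(red))
  })
  list(branches = br,
       fuse = he_conv(3L, 3L, 2L * C, C), fuse_bn = bn_params(C))
}

node_gated <- function(cfg, i, j) {
  cfg$ag_enabled && j >= 1L && (i == 0L || cfg$ag_full_grid)
}

#' Build the segmentation model
#'
#' Constructs the nested node grid with He-initialised convolutions
#' (two 3x3 conv + BN + ReLU per node), 2x2 max-pool downsampling,
#' bilinear + 1x1-conv upsampling, optional PPM after the deepest encoder
#' node and optional attention gates on decoder skip bundles, plus 1x1
#' prediction heads on `X[0, 1..4]`.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `sono_model`: list with `cfg` and the parameter tree.
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "sono_model_config"))
  w <- cfg$encoder_widths
  with_seed(derive_seed(seed, 1L), {
    enc <- lapply(0:4, function(i) {
      cin <- if (i == 0L) cfg$in_channels else w[i]
      conv_block_params(cin, w[i + 1L])
    })
    up <- list(); dec <- list(); ag <- list()
    for (j in 1:4) for (i in 0:(4 - j)) {
      key <- paste(i, j, sep = ".")
      up[[key]] <- he_conv(1L, 1L, w[i + 2L], w[i + 1L])
      dec[[key]] <- conv_block_params((j + 1L) * w[i + 1L], w[i + 1L])
      if (node_gated(cfg, i, j)) {
        ag[[key]] <- ag_params(j * w[i + 1L], w[i + 1L], w[i + 1L])
      }
    }
    ppm <- if (cfg$ppm_enabled) ppm_params(w[5], cfg$ppm_bins) else NULL
    heads <- lapply(1:4, function(j) he_conv(1L, 1L, w[1], cfg$num_classes))
    structure(list(cfg = cfg,
                   params = list(enc = enc, up = up, dec = dec, ag = ag,
                                 ppm = ppm, heads = heads)),
              class = "sono_model")
  })
}

# flatten every trainable parameter environment into one list
collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is.environment(v)) {
      if (!is.null(v$value)) out[[length(out) + 1L]] <<- v
    } else if (is.list(v)) {
      for (e in v) walk(e)
    }
  }
  walk(x$params)
  out
}

#' Total number of trainable parameters
#' @param model A `sono_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$value), 0))
}

# ---- forward building blocks ---------------------------------------------

run_conv_block <- function(tape, x, bp, training) {
  h <- op_conv(tape, x, bp$c1$w, bp$c1$b, 3L, 3L, 1L)
  h <- op_bn(tape, h, bp$bn1$gamma, bp$bn1$beta, bp$bn1$state, training)
  h <- op_relu(tape, h)
  h <- op_conv(tape, h, bp$c2$w, bp$c2$b, 3L, 3L, 1L)
  h <- op_bn(tape, h, bp$bn2$gamma, bp$bn2$beta, bp$bn2$state, training)
  op_relu(tape, h)
}

run_ppm <- function(tape, x, pp, bins, training) {
  d <- dim(x$value)
  if (max(bins) > min(d[1], d[2])) {
    stop("PPM bin larger than the deepest feature map; reduce ppm_bins ",
         "or increase the input size")
  }
  branches <- lapply(seq_along(bins), function(k) {
    br <- pp$branches[[k]]
    h <- op_adapt_avgpool(tape, x, bins[k])
    h <- op_conv(tape, h, br$conv$w, br$conv$b, 1L, 1L, 0L)
    h <- op_bn(tape, h, br$bn$gamma, br$bn$beta, br$bn$state, training)
    h <- op_relu(tape, h)
    op_resize(tape, h, d[1], d[2])
  })
  op_concat(tape, c(list(x), branches))
}

run_ag <- function(tape, x_skip, gate, agp, training) {
  a <- op_conv(tape, x_skip, agp$theta_x$w, agp$theta_x$b, 1L, 1L, 0L)
  a <- op_bn(tape, a, agp$bn_x$gamma, agp$bn_x$beta, agp$bn_x$state, training)
  g <- op_conv(tape, gate, agp$theta_g$w, agp$theta_g$b, 1L, 1L, 0L)
  g <- op_bn(tape, g, agp$bn_g$gamma, agp$bn_g$beta, agp$bn_g$state, training)
  s <- op_relu(tape, op_add(tape, a, g))
  q <- op_conv(tape, s, agp$psi$w, agp$psi$b, 1L, 1L, 0L)
  q <- op_bn(tape, q, agp$bn_psi$gamma, agp$bn_psi$beta, agp$bn_psi$state,
             training)
  q <- op_sigmoid(tape, q)
  d <- dim(x_skip$value)
  q <- op_resize(tape, q, d[1], d[2])
  op_gate(tape, x_skip, q)
}

# Full forward pass. Returns the list of head score nodes (pre-softmax,
# one per decoding column used by `mode`).
model_forward <- function(model, x, training = FALSE, tape = NULL,
                          mode = NULL) {
  cfg <- model$cfg
  pr <- model$params
  mode <- mode %||% cfg$decode_mode
  maxj <- switch(mode, L2 = 2L, L3 = 3L, L4 = 4L, DS = 4L,
                 stop("invalid decode_mode"))
  d <- dim(x)
  if (length(d) != 4L || d[3] != cfg$in_channels) {
    stop("input must be (H, W, ", cfg$in_channels, ", N)")
  }
  if (d[1] %% 2^maxj != 0L || d[2] %% 2^maxj != 0L) {
    stop("input spatial dims must be divisible by ", 2^maxj)
  }
  X <- lapply(0:4, function(i) vector("list", 5L))
  inp <- op_input(tape, x)
  for (i in 0:maxj) {
    src <- if (i == 0L) inp else op_maxpool2(tape, X[[i]][[1L]])
    h <- run_conv_block(tape, src, pr$enc[[i + 1L]], training)
    if (i == 4L && cfg$ppm_enabled) {
      h <- run_ppm(tape, h, pr$ppm, cfg$ppm_bins, training)
      h <- op_conv(tape, h, pr$ppm$fuse$w, pr$ppm$fuse$b, 3L, 3L, 1L)
      h <- op_bn(tape, h, pr$ppm$fuse_bn$gamma, pr$ppm$fuse_bn$beta,
                 pr$ppm$fuse_bn$state, training)
      h <- op_relu(tape, h)
    }
    X[[i + 1L]][[1L]] <- h
  }
  for (j in 1:maxj) {
    for (i in 0:(maxj - j)) {
      key <- paste(i, j, sep = ".")
      below <- X[[i + 2L]][[j]]
      dn <- dim(X[[i + 1L]][[1L]]$value)
      upf <- op_resize(tape, below, dn[1], dn[2])
      upf <- op_conv(tape, upf, pr$up[[key]]$w, pr$up[[key]]$b, 1L, 1L, 0L)
      skips <- X[[i + 1L]][seq_len(j)]
      bundle <- op_concat(tape, skips)
      if (node_gated(cfg, i, j)) {
        bundle <- run_ag(tape, bundle, upf, pr$ag[[key]], training)
      }
      joined <- op_concat(tape, list(bundle, upf))
      X[[i + 1L]][[j + 1L]] <- run_conv_block(tape, joined, pr$dec[[key]],
                                              training)
    }
  }
  if (mode == "DS") {
    lapply(1:4, function(j) {
      op_conv(tape, X[[1L]][[j + 1L]], pr$heads[[j]]$w, pr$heads[[j]]$b,
              1L, 1L, 0L)
    })
  } else {
    j <- maxj
    list(op_conv(tape, X[[1L]][[j + 1L]], pr$heads[[j]]$w, pr$heads[[j]]$b,
                 1L, 1L, 0L))
  }
}

#' Predict class probabilities and labels for a batch of images
#'
#' Runs the model in inference mode (batch-norm running statistics). In DS
#' mode the four head outputs are combined according to
#' `cfg$ds_head_combine`: the mean of the softmax probabilities (default)
#' or the deepest (L4) head alone. Argmax ties resolve to the lower class
#' index.
#'
#' @param model A `sono_model`.
#' @param image A single `H x W` matrix in `[0, 1]` or an `(H, W, C, N)`
#'   array.
#' @return List with `probs` (`(H, W, C_classes, N)` array, rows summing to
#'   1 per pixel) and `labels` (`(H, W, N)` integer array, 0-based; a
#'   matrix when `N = 1`).
#' @export
forward_predict <- function(model, image) {
  x <- as_batch(image, model$cfg$in_channels)
  heads <- model_forward(model, x, training = FALSE, tape = NULL)
  d <- dim(heads[[1L]]$value)
  np <- d[1] * d[2]; C <- d[3]; N <- d[4]
  soft <- lapply(heads, function(h) {
    arr <- h$value
    out <- array(0, d)
    for (n in seq_len(N)) {
      out[, , , n] <- array(softmax_scores(matrix(arr[, , , n], ncol = C)), d[1:3])
    }
    out
  })
  probs <- if (model$cfg$decode_mode == "DS" &&
               model$cfg$ds_head_combine == "mean") {
    Reduce(`+`, soft) / length(soft)
  } else {
    soft[[length(soft)]]
  }
  labels <- array(0L, c(d[1], d[2], N))
  for (n in seq_len(N)) {
    labels[, , n] <- matrix(
      max.col(matrix(probs[, , , n], ncol = C), ties.method = "first") - 1L,
      d[1], d[2])
  }
  if (N == 1L) labels <- labels[, , 1L]
  list(probs = probs, labels = labels)
}

as_batch <- function(image, in_channels = 1L) {
  if (is.matrix(image)) {
    array(image, c(nrow(image), ncol(image), 1L, 1L))
  } else if (length(dim(image)) == 4L) {
    image
  } else if (length(dim(image)) == 3L) {
    array(image, c(dim(image)[1:2], in_channels, dim(image)[3] / in_channels))
  } else stop("image must be a matrix or a 4-D array")
}

# ---- standalone functional forms of the two module operations ------------

#' Pyramid pooling module applied to a feature map
#'
#' For each bin size `b` the input is adaptively average-pooled to `b x b`
#' (kernel and stride chosen so that `O = (I - K)/S + 1 = b`), reduced to
#' `C / N` channels with a 1x1 convolution (BN + ReLU), bilinearly
#' upsampled back, and concatenated with the input, doubling the channel
#' count while preserving the spatial size.
#'
#' @param x `(H, W, C, N)` feature array.
#' @param bins Pooling grid sizes (default `(1, 2, 3, 6)`); `C` must be
#'   divisible by `length(bins)` and `max(bins)` must fit the input.
#' @param weights Optional parameter set from a built model; if `NULL`,
#'   He-initialised weights with `seed` are used.
#' @param seed Seed for ad-hoc weights.
#' @return `(H, W, 2C, N)` array.
#' @export
ppm_forward <- function(x, bins = c(1L, 2L, 3L, 6L), weights = NULL,
                        seed = 0L) {
  d <- dim(x)
  if (length(d) != 4L) stop("x must be (H, W, C, N)")
  if (max(bins) > min(d[1], d[2])) {
    stop("PPM bin larger than input spatial size")
  }
  if (d[3] %% length(bins) != 0L) {
    stop("channel count must be divisible by the number of bins")
  }
  pp <- weights %||% with_seed(seed, ppm_params(d[3], as.integer(bins)))
  run_ppm(NULL, op_input(NULL, x), pp, as.integer(bins), FALSE)$value
}

#' Attention gate applied to a feature map
#'
#' Computes the attention coefficient
#' `Q = sigmoid(BN(conv1x1(ReLU(BN(conv1x1(x)) + BN(conv1x1(g))))))`,
#' resampled to `x`'s spatial size, and returns `x * Q`. `x` is the feature
#' bundle being gated (skip connections) and `g` the gating signal (the
#' upsampled deeper decoder feature).
#'
#' @param x `(H, W, Cx, N)` feature array to be gated.
#' @param g `(H, W, Cg, N)` gating feature (same spatial size).
#' @param weights Optional `ag_params()` set; He-initialised with `seed`
#'   when `NULL`.
#' @param seed Seed for ad-hoc weights.
#' @param return_coefficients Also return the gate map `Q`.
#' @return The gated array, or a list `(gated, q)` when
#'   `return_coefficients` is `TRUE`.
#' @export
attention_gate <- function(x, g, weights = NULL, seed = 0L,
                           return_coefficients = FALSE) {
  dx <- dim(x); dg <- dim(g)
  if (length(dx) != 4L || length(dg) != 4L) stop("inputs must be 4-D")
  if (any(dx[c(1, 2, 4)] != dg[c(1, 2, 4)])) {
    stop("x and g must share spatial size and batch size")
  }
  agp <- weights %||% with_seed(seed, ag_params(dx[3], dg[3], max(dx[3], 1L)))
  out <- run_ag(NULL, op_input(NULL, x), op_input(NULL, g), agp, FALSE)
  if (!return_coefficients) return(out$value)
  # recompute the coefficient map for inspection
  a <- run_ag_q(agp, x, g)
  list(gated = out$value, q = a)
}

run_ag_q <- function(agp, x, g) {
  a <- op_conv(NULL, op_input(NULL, x), agp$theta_x$w, agp$theta_x$b, 1L, 1L, 0L)
  a <- op_bn(NULL, a, agp$bn_x$gamma, agp$bn_x$beta, agp$bn_x$state, FALSE)
  b <- op_conv(NULL, op_input(NULL, g), agp$theta_g$w, agp$theta_g$b, 1L, 1L, 0L)
  b <- op_bn(NULL, b, agp$bn_g$gamma, agp$bn_g$beta, agp$bn_g$state, FALSE)
  s <- op_relu(NULL, op_add(NULL, a, b))
  q <- op_conv(NULL, s, agp$psi$w, agp$psi$b, 1L, 1L, 0L)
  q <- op_bn(NULL, q, agp$bn_psi$gamma, agp$bn_psi$beta, agp$bn_psi$state, FALSE)
  op_sigmoid(NULL, q)$value
}

# ---- checkpoints ----------------------------------------------------------

# parameters + BN running stats as plain nested lists of arrays
model_state <- function(model) {
  strip <- function(v) {
    if (is.environment(v)) {
      if (!is.null(v$value)) list(.param = v$value)
      else list(.bnstate = list(mean = v$mean, var = v$var))
    } else if (is.list(v)) lapply(v, strip)
    else v
  }
  strip(model$params)
}

restore_state <- function(model, state) {
  fill <- function(v, s) {
    if (is.environment(v)) {
      if (!is.null(v$value)) v$value <- s$.param
      else { v$mean <- s$.bnstate$mean; v$var <- s$.bnstate$var }
    } else if (is.list(v)) for (k in seq_along(v)) fill(v[[k]], s[[k]])
    invisible(NULL)
  }
  fill(model$params, state)
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is written in R's native serialization with a JSON config
#' sidecar (`<path>.json`) from which the architecture is reproducible.
#'
#' @param model A `sono_model`.
#' @param path Checkpoint file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), state = model_state(model)), path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$cfg[setdiff(names(ck$cfg), character(0))])
  model <- build_model(cfg, seed = 0L)
  restore_state(model, ck$state)
}
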
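# Minimal reverse-mode autodiff over 4-D (H, W, C, N) arrays.
#
# A "node" is an environment with $value (array), $grad (NULL until the
# backward sweep reaches it) and $backward (closure propagating $grad to
# the node's inputs). Recording order on the tape is a topological order,
# so the backward sweep is a single reverse pass. Trainable parameters are
# environments with $value/$grad that live outside the tape and accumulate
# gradients across the sweep.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_record <- function(tape, node) {
  if (is.null(tape)) return(node)
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- node
  node
}

new_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape_record(tape, nd)
}

accum_grad <- function(x, g) {
  x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p
}

# Seed the given root nodes with gradients and sweep the tape backwards.
backward_run <- function(tape, roots, seeds) {
  for (k in seq_along(roots)) accum_grad(roots[[k]], seeds[[k]])
  if (tape$n == 0L) return(invisible(NULL))
  for (i in tape$n:1L) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

op_input <- function(tape, value) new_node(tape, value)

op_conv <- function(tape, x, w, b, kh = 3L, kw = 3L, pad = 1L) {
  val <- .conv2d_fwd(x$value, w$value, b$value, kh, kw, pad)
  new_node(tape, val, backward = function(g) {
    gr <- .conv2d_bwd(x$value, w$value, g, kh, kw, pad)
    accum_grad(x, gr$dx); accum_grad(w, gr$dw); accum_grad(b, gr$db)
  })
}

op_relu <- function(tape, x) {
  mask <- x$value > 0
  new_node(tape, x$value * mask,
           backward = function(g) accum_grad(x, g * mask))
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  new_node(tape, y, backward = function(g) accum_grad(x, g * y * (1 - y)))
}

op_add <- function(tape, x, y) {
  new_node(tape, x$value + y$value, backward = function(g) {
    accum_grad(x, g); accum_grad(y, g)
  })
}

op_maxpool2 <- function(tape, x) {
  f <- .maxpool2_fwd(x$value)
  ind <- dim(x$value)
  new_node(tape, f$y, backward = function(g) {
    accum_grad(x, .maxpool2_bwd(g, f$idx, ind))
  })
}

op_resize <- function(tape, x, h, w) {
  d <- dim(x$value)
  if (d[1] == h && d[2] == w) return(x)
  new_node(tape, .resize_bilinear_fwd(x$value, h, w), backward = function(g) {
    accum_grad(x, .resize_bilinear_bwd(g, d[1], d[2]))
  })
}

op_adapt_avgpool <- function(tape, x, bin) {
  d <- dim(x$value)
  new_node(tape, .adapt_avgpool_fwd(x$value, bin), backward = function(g) {
    accum_grad(x, .adapt_avgpool_bwd(g, d[1], d[2]))
  })
}

# channel concatenation
op_concat <- function(tape, xs) {
  if (length(xs) == 1L) return(xs[[1L]])
  chans <- vapply(xs, function(x) dim(x$value)[3], 0L)
  new_node(tape, .concat_c(lapply(xs, function(x) x$value)),
           backward = function(g) {
    parts <- .split_c(g, chans)
    for (k in seq_along(xs)) accum_grad(xs[[k]], parts[[k]])
  })
}

# multiply a (H, W, C, N) feature map by a single-channel (H, W, 1, N) gate
op_gate <- function(tape, x, q) {
  new_node(tape, .gate_fwd(x$value, q$value), backward = function(g) {
    gr <- .gate_bwd(g, x$value, q$value)
    accum_grad(x, gr$dx); accum_grad(q, gr$dq)
  })
}

# Batch normalisation over (H, W, N) per channel. `state` carries running
# statistics for inference; training mode uses batch statistics and
# backpropagates through them.
op_bn <- function(tape, x, gamma, beta, state, training,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mo <- .chan_moments(x$value)
    mu <- mo$mean
    va <- mo$msq - mo$mean^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va * m / max(1, m - 1)
  } else {
    mu <- state$mean
    va <- state$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- .chan_affine(x$value, invstd, -mu * invstd)
  y <- .chan_affine(xhat, gamma$value, beta$value)
  new_node(tape, y, backward = function(g) {
    dots <- .chan_dots(g, xhat)
    accum_grad(gamma, dots$sum_gh); accum_grad(beta, dots$sum_g)
    if (training) {
      dx <- .bn_dx(g, xhat, gamma$value * invstd,
                   dots$sum_g / m, dots$sum_gh / m)
    } else {
      dx <- .chan_affine(g, gamma$value * invstd, numeric(d[3]))
    }
    accum_grad(x, dx)
  })
}

# ---- Adam optimiser over a flat list of parameter environments ----------

adam_state <- function(params) {
  lapply(params, function(p) {
    list(m = array(0, dim(p$value) %||% length(p$value)),
         v = array(0, dim(p$value) %||% length(p$value)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[k]] <- st
    p$value <- p$value - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
  }
  state
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
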
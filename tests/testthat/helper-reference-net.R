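# Independent plain U-Net++ reference forward pass, written with naive R
# loops and its own pooling/upsampling code. Used to check that the built
# model with PPM and AG disabled computes the same function when given the
# same weights (inference mode).

ref_conv3 <- function(x, w, b) {
  d <- dim(x)  # (H, W, Cin)
  cout <- dim(w)[4]
  H <- d[1]; W <- d[2]
  xp <- array(0, c(H + 2, W + 2, d[3]))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(d[3])) {
      for (dh in 1:3) for (dw in 1:3) {
        acc <- acc + xp[(dh):(dh + H - 1), (dw):(dw + W - 1), ci] *
          w[dh, dw, ci, co]
      }
    }
    y[, , co] <- acc
  }
  y
}

ref_conv1 <- function(x, w, b) {
  d <- dim(x); cout <- dim(w)[4]
  y <- array(0, c(d[1], d[2], cout))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], d[1], d[2])
    for (ci in seq_len(d[3])) acc <- acc + x[, , ci] * w[1, 1, ci, co]
    y[, , co] <- acc
  }
  y
}

# inference-mode batch norm with running stats
ref_bn <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- gamma[c] * (x[, , c] - mean[c]) / sqrt(var[c] + eps) + beta[c]
  }
  x
}

ref_relu <- function(x) pmax(x, 0)

ref_maxpool2 <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (c in seq_len(d[3])) {
    m <- x[, , c]
    y[, , c] <- pmax(m[seq(1, d[1], 2), seq(2, d[2], 2)],
                     m[seq(1, d[1], 2), seq(1, d[2], 2)],
                     m[seq(2, d[1], 2), seq(1, d[2], 2)],
                     m[seq(2, d[1], 2), seq(2, d[2], 2)])
  }
  y
}

# bilinear 2x upsample, half-pixel centres, clamped edges
ref_upsample2 <- function(x) {
  d <- dim(x)
  Ho <- 2 * d[1]; Wo <- 2 * d[2]
  src <- function(i, n) {
    s <- (i + 0.5) / 2 - 0.5
    s <- pmin(pmax(s, 0), n - 1)
    i0 <- floor(s); i1 <- pmin(i0 + 1, n - 1)
    list(i0 = i0 + 1, i1 = i1 + 1, f = s - i0)
  }
  rh <- src(0:(Ho - 1), d[1]); rw <- src(0:(Wo - 1), d[2])
  y <- array(0, c(Ho, Wo, d[3]))
  for (c in seq_len(d[3])) {
    m <- matrix(x[, , c], d[1], d[2])
    a <- m[rh$i0, rw$i0, drop = FALSE] * (1 - rh$f) +
      m[rh$i1, rw$i0, drop = FALSE] * rh$f
    b <- m[rh$i0, rw$i1, drop = FALSE] * (1 - rh$f) +
      m[rh$i1, rw$i1, drop = FALSE] * rh$f
    y[, , c] <- a * matrix(1 - rw$f, Ho, Wo, byrow = TRUE) +
      b * matrix(rw$f, Ho, Wo, byrow = TRUE)
  }
  y
}

ref_block <- function(x, bp) {
  h <- ref_conv3(x, bp$c1$w$value, bp$c1$b$value)
  h <- ref_bn(h, bp$bn1$gamma$value, bp$bn1$beta$value,
              bp$bn1$state$mean, bp$bn1$state$var)
  h <- ref_relu(h)
  h <- ref_conv3(h, bp$c2$w$value, bp$c2$b$value)
  h <- ref_bn(h, bp$bn2$gamma$value, bp$bn2$beta$value,
              bp$bn2$state$mean, bp$bn2$state$var)
  ref_relu(h)
}

ref_cat <- function(xs) {
  d <- dim(xs[[1]])
  array(unlist(lapply(xs, as.vector)), c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], 0))))
}

# full plain U-Net++ forward with the package model's weights; returns the
# per-head score arrays (H, W, C) for heads 1..4
ref_unetpp_forward <- function(model, img) {
  pr <- model$params
  X <- lapply(1:5, function(i) vector("list", 5))
  cur <- array(img, c(dim(img), 1))
  for (i in 0:4) {
    src <- if (i == 0) cur else ref_maxpool2(X[[i]][[1]])
    X[[i + 1]][[1]] <- ref_block(src, pr$enc[[i + 1]])
  }
  for (j in 1:4) for (i in 0:(4 - j)) {
    key <- paste(i, j, sep = ".")
    up <- ref_upsample2(X[[i + 2]][[j]])
    up <- ref_conv1(up, pr$up[[key]]$w$value, pr$up[[key]]$b$value)
    joined <- ref_cat(c(X[[i + 1]][seq_len(j)], list(up)))
    X[[i + 1]][[j + 1]] <- ref_block(joined, pr$dec[[key]])
  }
  lapply(1:4, function(j) {
    ref_conv1(X[[1]][[j + 1]], pr$heads[[j]]$w$value, pr$heads[[j]]$b$value)
  })
}
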
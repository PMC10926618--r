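test_that("model config validates its invariants", {
  expect_error(model_config(encoder_widths = c(8, 16, 32)), "5 positive")
  expect_error(model_config(ppm_bins = c(1, 3, 2)), "increasing")
  expect_error(model_config(encoder_widths = c(2, 4, 8, 16, 30),
                            ppm_bins = c(1, 2, 3, 6)), "divisible")
  cfg <- model_config(decode_mode = "L3", ppm_enabled = FALSE)
  expect_s3_class(cfg, "sono_model_config")
})

test_that("pooled output size follows the kernel/stride arithmetic", {
  # O = (I - K)/S + 1: an 8-wide map pooled with K = S = 2 gives 4
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  p <- sonoseg:::.adapt_avgpool_fwd(x, 4L)
  expect_equal(dim(p), c(4L, 4L, 2L, 1L))
  expect_equal(p[1, 1, 1, 1], mean(x[1:2, 1:2, 1, 1]))
  # constant input: every pooled branch is the same constant
  xc <- array(3.5, c(12, 12, 4, 1))
  for (b in c(1L, 2L, 3L, 6L)) {
    expect_equal(as.vector(sonoseg:::.adapt_avgpool_fwd(xc, b)),
                 rep(3.5, b * b * 4), tolerance = 1e-12)
  }
})

test_that("PPM doubles channels, preserves spatial size and rejects bad bins", {
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 2))
  y <- ppm_forward(x, bins = c(1, 2, 3, 6), seed = 1)
  expect_equal(dim(y), c(16L, 16L, 16L, 2L))
  expect_error(ppm_forward(array(rnorm(4 * 4 * 8), c(4, 4, 8, 1)),
                           bins = c(1, 2, 3, 6)), "bin larger")
  expect_error(ppm_forward(x, bins = c(1, 2, 3)), "divisible")
  # the first block of channels is the untouched input
  expect_equal(y[, , 1:8, ], x[, , 1:8, ], tolerance = 1e-12)
})

test_that("attention gate obeys the sigmoid-coefficient contract", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  g <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  agp <- sonoseg:::with_seed(1, sonoseg:::ag_params(4L, 3L, 4L))
  out <- attention_gate(x, g, weights = agp, return_coefficients = TRUE)
  expect_true(all(out$q > 0 & out$q < 1))
  expect_equal(dim(out$gated), dim(x))
  # zeroed weights force Q = sigmoid(0) = 0.5, so the output is x / 2
  for (p in sonoseg:::collect_params(list(params = agp))) {
    p$value <- p$value * 0
  }
  # restore BN gammas to 1 so the zero conv output stays zero after BN
  agp$bn_x$gamma$value[] <- 1; agp$bn_g$gamma$value[] <- 1
  agp$bn_psi$gamma$value[] <- 1
  out0 <- attention_gate(x, g, weights = agp)
  expect_equal(out0, x / 2, tolerance = 1e-12)
  # gating is multiplicative: zero input stays zero
  expect_equal(attention_gate(x * 0, g, weights = agp), x * 0)
})

test_that("decode modes produce the contracted head shapes", {
  cfg <- tiny_cfg(decode_mode = "DS")
  m <- build_model(cfg, seed = 1)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  heads <- sonoseg:::model_forward(m, x)
  expect_length(heads, 4)
  for (h in heads) expect_equal(dim(h$value), c(32L, 32L, 6L, 2L))
  for (mode in c("L2", "L3", "L4")) {
    hm <- sonoseg:::model_forward(m, x, mode = mode)
    expect_length(hm, 1)
    expect_equal(dim(hm[[1]]$value), c(32L, 32L, 6L, 2L))
  }
  # L4's head equals the DS fourth head given identical weights
  h4 <- sonoseg:::model_forward(m, x, mode = "L4")
  expect_equal(h4[[1]]$value, heads[[4]]$value, tolerance = 1e-12)
})

test_that("enabling PPM and AG strictly increases the parameter count", {
  base <- build_model(tiny_cfg(ppm_enabled = FALSE, ag_enabled = FALSE), 1)
  p <- build_model(tiny_cfg(ppm_enabled = TRUE, ag_enabled = FALSE), 1)
  a <- build_model(tiny_cfg(ppm_enabled = FALSE, ag_enabled = TRUE), 1)
  both <- build_model(tiny_cfg(), 1)
  expect_gt(n_parameters(p), n_parameters(base))
  expect_gt(n_parameters(a), n_parameters(base))
  expect_gt(n_parameters(both), n_parameters(p))
  full <- build_model(tiny_cfg(ag_full_grid = TRUE), 1)
  expect_gt(n_parameters(full), n_parameters(both))
})

test_that("disabled-module model equals an independent plain U-Net++ reference", {
  cfg <- tiny_cfg(ppm_enabled = FALSE, ag_enabled = FALSE, decode_mode = "DS")
  m <- build_model(cfg, seed = 7)
  img <- matrix(runif(16 * 16), 16, 16)
  heads <- sonoseg:::model_forward(m, array(img, c(16, 16, 1, 1)))
  ref <- ref_unetpp_forward(m, img)
  for (j in 1:4) {
    expect_equal(heads[[j]]$value[, , , 1], ref[[j]], tolerance = 1e-8)
  }
})

test_that("predictions are proper probabilities with deterministic argmax", {
  m <- build_model(tiny_cfg(), seed = 2)
  img <- matrix(runif(32 * 32), 32, 32)
  out <- forward_predict(m, img)
  sums <- apply(out$probs[, , , 1], c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, 32 * 32), tolerance = 1e-9)
  expect_true(all(out$labels %in% 0:5))
  out2 <- forward_predict(m, img)
  expect_identical(out, out2)
  # ds_head_combine = "last" reproduces the L4 head
  m$cfg$ds_head_combine <- "last"
  out_last <- forward_predict(m, img)
  h4 <- sonoseg:::model_forward(m, array(img, c(32, 32, 1, 1)), mode = "L4")
  p4 <- softmax_scores(matrix(h4[[1]]$value[, , , 1], ncol = 6))
  expect_equal(matrix(out_last$probs[, , , 1], ncol = 6), p4, tolerance = 1e-12)
})

test_that("autodiff gradients through the full network match finite differences", {
  cfg <- tiny_cfg(decode_mode = "L2")   # small but crosses conv/bn/ag/up ops
  m <- build_model(cfg, seed = 3)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  g <- matrix(sample(0:5, 256, replace = TRUE), 16, 16)
  loss_of <- function() {
    h <- sonoseg:::model_forward(m, x, training = TRUE)
    sc <- matrix(aperm(h[[1]]$value, c(1, 2, 4, 3)), ncol = 6)
    lovasz_softmax_loss(softmax_scores(sc), as.vector(g))
  }
  tape <- sonoseg:::new_tape()
  h <- sonoseg:::model_forward(m, x, training = TRUE, tape = tape)
  sc <- matrix(aperm(h[[1]]$value, c(1, 2, 4, 3)), ncol = 6)
  lg <- sonoseg:::lovasz_softmax_loss_grad(softmax_scores(sc), as.vector(g))
  seed_arr <- aperm(array(lg$dscores, c(16, 16, 1, 6)), c(1, 2, 4, 3))
  params <- sonoseg:::collect_params(m)
  sonoseg:::zero_grads(params)
  sonoseg:::backward_run(tape, h, list(seed_arr))
  # probe a few parameters spread over the tree
  set.seed(4)
  probed <- 0
  h0 <- 1e-5
  used <- Filter(function(p) !is.null(p$grad), params)
  for (p in sample(used, min(12, length(used)))) {
    k <- sample(length(p$value), 1)
    if (abs(p$grad[k]) < 1e-9) next
    orig <- p$value[k]
    p$value[k] <- orig + h0; lp <- loss_of()
    p$value[k] <- orig - h0; lm <- loss_of()
    p$value[k] <- orig
    expect_equal(p$grad[k], (lp - lm) / (2 * h0), tolerance = 5e-3)
    probed <- probed + 1
  }
  expect_gte(probed, 4)
})

test_that("checkpoints round-trip to identical predictions", {
  m <- build_model(tiny_cfg(), seed = 9)
  img <- matrix(runif(32 * 32), 32, 32)
  before <- forward_predict(m, img)
  td <- withr::local_tempdir()
  ck <- file.path(td, "model.rds")
  save_checkpoint(m, ck)
  expect_true(file.exists(paste0(ck, ".json")))
  m2 <- load_checkpoint(ck)
  expect_identical(forward_predict(m2, img), before)
  side <- jsonlite::read_json(paste0(ck, ".json"), simplifyVector = TRUE)
  expect_equal(side$decode_mode, "DS")
})
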
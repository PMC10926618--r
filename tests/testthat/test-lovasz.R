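test_that("softmax is a proper, shift-invariant probability map", {
  set.seed(42)
  F <- matrix(rnorm(40 * 6, sd = 3), 40, 6)
  p <- softmax_scores(F)
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(softmax_scores(F + 5), p, tolerance = 1e-12)
  expect_equal(softmax_scores(matrix(0, 3, 6)),
               matrix(1 / 6, 3, 6), tolerance = 1e-12)
  expect_error(softmax_scores(matrix(c(1, NA), 1, 2)), "NA")
})

test_that("discrete Jaccard loss matches hand set counts and conventions", {
  expect_equal(jaccard_loss_discrete(c(0, 1, 1), c(0, 0, 1), 1), 0.5)
  truth <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
  for (c in 0:5) expect_equal(jaccard_loss_discrete(truth, truth, c), 0)
  # class absent from both maps: 0/0 = 1 index, zero loss
  expect_equal(jaccard_loss_discrete(c(0, 0), c(0, 0), 3), 0)
})

test_that("error vector implements the signed-probability rule", {
  probs <- matrix(c(0.7, 0.4, 0.3, 0.6), 2, 2)
  e <- error_vector(probs, c(0, 1), 1)
  expect_equal(e$values, c(0.3, 0.4))
  expect_equal(e$gt_mask, c(0, 1))
  # perfectly one-hot correct prediction: zero error
  oh <- one_hot_probs(c(0, 2, 1), 3)
  for (c in 0:2) expect_equal(error_vector(oh, c(0, 2, 1), c)$values, rep(0, 3))
  # range closure under random valid probability rows
  set.seed(7)
  for (rep in 1:20) {
    m <- softmax_scores(matrix(rnorm(12 * 4, sd = 4), 12, 4))
    g <- sample(0:3, 12, replace = TRUE)
    v <- error_vector(m, g, sample(0:3, 1))$values
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("cumulative-sum Lovasz gradient equals literal prefix-set evaluation", {
  expect_equal(lovasz_grad(c(1)), 1)  # single true pixel in error
  # hand case, sorted_gt = (0, 1): prefix mispredicted sets {pi1} and
  # {pi1, pi2} have Jaccard losses 1/2 and 1, so g = (1/2, 1/2)
  expect_equal(lovasz_grad(c(0, 1)), c(0.5, 0.5))
  expect_equal(oracle_lovasz_grad(c(0, 1)), c(0.5, 0.5))
  set.seed(123)
  for (rep in 1:300) {
    p <- sample(1:8, 1)
    gt <- sample(0:1, p, replace = TRUE)
    expect_equal(lovasz_grad(gt), oracle_lovasz_grad(gt), tolerance = 1e-12)
  }
  expect_identical(lovasz_grad(numeric(0)), numeric(0))
})

test_that("extension agrees with the discrete loss on hypercube vertices", {
  set.seed(5)
  for (rep in 1:50) {
    p <- sample(2:8, 1)
    gt <- sample(0:1, p, replace = TRUE)
    err <- sample(0:1, p, replace = TRUE)  # binary indicator of mispredictions
    gt_set <- which(gt == 1)
    ext <- lovasz_extension(err, gt)
    expect_equal(ext, oracle_jaccard_loss_set(gt_set, which(err == 1), p),
                 tolerance = 1e-12)
  }
})

test_that("worked two-pixel case evaluates exactly", {
  probs <- matrix(c(0.7, 0.4, 0.3, 0.6), 2, 2)
  truth <- c(0, 1)
  e1 <- error_vector(probs, truth, 1)
  e0 <- error_vector(probs, truth, 0)
  expect_equal(lovasz_extension(e1), 0.4)
  expect_equal(lovasz_extension(e0), 0.35)
  expect_equal(lovasz_softmax_loss(probs, truth), 0.375)
  # cross-check against the independent definition-based oracle
  expect_equal(oracle_lovasz_extension(e1$values, e1$gt_mask), 0.4)
  expect_equal(oracle_lovasz_extension(e0$values, e0$gt_mask), 0.35)
})

test_that("loss is zero for perfect one-hot predictions and bounded in [0,1]", {
  set.seed(9)
  for (rep in 1:10) {
    g <- sample(0:5, 30, replace = TRUE)
    expect_equal(lovasz_softmax_loss(one_hot_probs(g, 6), g), 0)
    m <- softmax_scores(matrix(rnorm(30 * 6, sd = 3), 30, 6))
    l <- lovasz_softmax_loss(m, g)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  expect_error(lovasz_softmax_loss(matrix(numeric(0), 0, 2), integer(0)),
               "empty")
})

test_that("extension is monotone, convex and pixel-permutation symmetric", {
  set.seed(31)
  for (rep in 1:60) {
    p <- sample(3:10, 1)
    gt <- sample(0:1, p, replace = TRUE)
    e <- runif(p)
    v <- lovasz_extension(e, gt)
    # monotone: increasing one error never decreases the value
    i <- sample(p, 1)
    e2 <- e; e2[i] <- min(1, e2[i] + runif(1, 0, 1 - e2[i]))
    expect_gte(lovasz_extension(e2, gt) + 1e-12, v)
    # convex along a random segment
    eb <- runif(p); lam <- runif(1)
    expect_lte(lovasz_extension(lam * e + (1 - lam) * eb, gt),
               lam * v + (1 - lam) * lovasz_extension(eb, gt) + 1e-12)
    # symmetric under simultaneous permutation
    pr <- sample(p)
    expect_equal(lovasz_extension(e[pr], gt[pr]), v, tolerance = 1e-12)
  }
})

test_that("class averaging can be restricted to present classes", {
  probs <- softmax_scores(matrix(rnorm(20 * 4), 20, 4))
  g <- sample(0:1, 20, replace = TRUE)   # classes 2, 3 absent from truth
  all_avg <- lovasz_softmax_loss(probs, g, "all")
  pres <- lovasz_softmax_loss(probs, g, "present")
  expect_true(is.finite(all_avg) && is.finite(pres))
  # with one-hot probs on present classes only, absent classes contribute 0
  oh <- one_hot_probs(g, 4)
  expect_equal(lovasz_softmax_loss(oh, g, "all"), 0)
})

test_that("analytic score gradient matches finite differences", {
  set.seed(77)
  p <- 12; C <- 4
  F <- matrix(rnorm(p * C), p, C)
  g <- sample(0:(C - 1), p, replace = TRUE)
  probs <- softmax_scores(F)
  grad <- sonoseg:::lovasz_softmax_dscores(probs, g)
  h <- 1e-6
  for (k in sample(p * C, 10)) {
    Fp <- F; Fp[k] <- Fp[k] + h
    Fm <- F; Fm[k] <- Fm[k] - h
    num <- (lovasz_softmax_loss(softmax_scores(Fp), g) -
            lovasz_softmax_loss(softmax_scores(Fm), g)) / (2 * h)
    expect_equal(grad[k], num, tolerance = 1e-4)
  }
})
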
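test_that("confusion matrix matches hand counts and the brute-force loop", {
  cm <- confusion_matrix(c(0, 1, 1, 1), c(0, 0, 1, 1), 2)
  expect_equal(unname(cm$counts), matrix(c(1, 0, 1, 2), 2, 2))
  set.seed(11)
  for (rep in 1:20) {
    truth <- matrix(sample(0:5, 256, replace = TRUE), 16, 16)
    pred <- matrix(sample(0:5, 256, replace = TRUE), 16, 16)
    cm <- confusion_matrix(pred, truth, 6)
    expect_identical(unname(cm$counts), oracle_confusion(pred, truth, 6))
  }
  expect_error(confusion_matrix(c(0, 1), c(0, 1, 2), 3), "shape")
  expect_error(confusion_matrix(c(0, 7), c(0, 1), 6), "outside")
})

test_that("identity prediction gives a diagonal matrix and perfect scores", {
  truth <- matrix(sample(0:5, 400, replace = TRUE), 20, 20)
  cm <- confusion_matrix(truth, truth, 6)
  expect_true(all(cm$counts[upper.tri(cm$counts)] == 0))
  expect_true(all(cm$counts[lower.tri(cm$counts)] == 0))
  expect_equal(unname(diag(cm$counts)), unname(tabulate(truth + 1, 6)))
  expect_equal(miou(cm), 1)
  expect_equal(mean_dice(cm), 1)
  expect_equal(pixel_accuracy(cm), 1)
})

test_that("dice, iou, cpa follow the marginal formulas and 0/0 convention", {
  # TP=2, FP=1, FN=1 for class 1
  cm <- confusion_matrix(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 0), 2)
  expect_equal(dice(cm, 1), 4 / 6)
  expect_equal(iou(cm, 1), 0.5)
  # class absent from both maps scores 1 under the 0/0 convention
  cm2 <- confusion_matrix(c(0, 0), c(0, 0), 6)
  for (c in 1:5) {
    expect_equal(dice(cm2, c), 1)
    expect_equal(iou(cm2, c), 1)
    expect_equal(cpa(cm2, c), 1)
  }
  # "present" averaging drops those classes
  expect_equal(miou(cm2, "present"), 1)
  expect_equal(mean_dice(cm2, "present"), 1)
})

test_that("PA and CPA match direct pixel counting", {
  pred <- c(0, 1, 1, 1); truth <- c(0, 0, 1, 1)
  cm <- confusion_matrix(pred, truth, 2)
  expect_equal(pixel_accuracy(cm), 3 / 4)
  expect_equal(cpa(cm, 1), 2 / 3)
  set.seed(13)
  for (rep in 1:10) {
    truth <- sample(0:5, 300, replace = TRUE)
    pred <- sample(0:5, 300, replace = TRUE)
    cm <- confusion_matrix(pred, truth, 6)
    expect_equal(pixel_accuracy(cm), mean(pred == truth))
  }
  expect_error(pixel_accuracy(confusion_matrix(integer(0), integer(0), 2)),
               "empty")
})

test_that("Dice and IOU satisfy Dice = 2 IOU / (1 + IOU) per class", {
  set.seed(17)
  for (rep in 1:10) {
    truth <- sample(0:5, 500, replace = TRUE)
    pred <- sample(0:5, 500, replace = TRUE)
    cm <- confusion_matrix(pred, truth, 6)
    for (c in 0:5) {
      i <- iou(cm, c)
      expect_equal(dice(cm, c), 2 * i / (1 + i), tolerance = 1e-12)
      expect_gte(dice(cm, c), i)
    }
  }
})

test_that("per-class marginals are consistent and scores permutation-equivariant", {
  set.seed(19)
  truth <- sample(0:5, 600, replace = TRUE)
  pred <- sample(0:5, 600, replace = TRUE)
  cm <- confusion_matrix(pred, truth, 6)
  tps <- vapply(0:5, function(c) sonoseg:::class_marginals(cm, c)$tp, 0)
  expect_equal(sum(tps), sum(diag(cm$counts)))
  for (c in 0:5) {
    m <- sonoseg:::class_marginals(cm, c)
    expect_equal(m$tp + m$fp + m$fn + m$tn, sum(cm$counts))
  }
  # relabelling classes permutes the per-class scores
  perm <- sample(0:5)
  cm_p <- confusion_matrix(perm[pred + 1], perm[truth + 1], 6)
  for (c in 0:5) {
    expect_equal(iou(cm_p, perm[c + 1]), iou(cm, c))
    expect_equal(cpa(cm_p, perm[c + 1]), cpa(cm, c))
  }
  expect_equal(miou(cm_p), miou(cm))
})

test_that("metrics report aggregates correctly and round-trips to disk", {
  truth <- matrix(sample(0:5, 256, replace = TRUE), 16, 16)
  pred <- matrix(sample(0:5, 256, replace = TRUE), 16, 16)
  cm <- confusion_matrix(pred, truth, 6)
  rep <- metrics_report(cm)
  expect_equal(nrow(rep$per_class), 6)
  expect_equal(rep$aggregate[["miou"]], mean(rep$per_class$iou))
  expect_equal(rep$aggregate[["dice"]], mean(rep$per_class$dice))
  td <- withr::local_tempdir()
  paths <- write_metrics_report(rep, file.path(td, "m"))
  back <- read.csv(paths[1])
  expect_equal(back$dice, rep$per_class$dice, tolerance = 1e-12)
  js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(js$aggregate$pa, rep$aggregate[["pa"]], tolerance = 1e-12)
})
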
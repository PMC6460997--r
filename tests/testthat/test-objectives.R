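test_that("confusion counts and Dice match enumerated examples", {
  pred <- array(c(1, 1, 1, 0), dim = c(4, 1, 1))
  truth <- array(c(1, 0, 1, 1), dim = c(4, 1, 1))
  cc <- confusion_counts(pred == 1, truth == 1)
  expect_equal(cc, list(TP = 2L, FP = 1L, FN = 1L, TN = 0L))
  expect_equal(dice_score(pred == 1, truth == 1), 2 * 2 / (1 + 4 + 1))
  # identical and disjoint masks
  expect_equal(dice_score(truth == 1, truth == 1), 1)
  expect_equal(dice_score(truth == 1, truth == 0), 0)
  # both-empty convention
  z <- array(FALSE, dim = c(2, 2, 1))
  expect_equal(dice_score(z, z), 1)
  # counts always partition the grid
  set.seed(1)
  a <- array(runif(60) > 0.5, dim = c(5, 4, 3))
  b <- array(runif(60) > 0.5, dim = c(5, 4, 3))
  cc2 <- confusion_counts(a, b)
  expect_equal(cc2$TP + cc2$FP + cc2$FN + cc2$TN, 60L)
  expect_error(confusion_counts(a, b[1:4, , ]), "differ")
})

test_that("single-voxel hand values for the losses are reproduced", {
  q <- array(c(0.25, 0.25, 0.25, 0.25), dim = c(1, 1, 1, 4))
  mk <- function(true_class) {
    p <- array(0, dim = c(1, 1, 1, 4)); p[1, 1, 1, true_class] <- 1
    probability_field(q, p)
  }
  expect_equal(cross_entropy(mk(1)), -log(0.25), tolerance = 1e-4)   # 1.3863
  expect_equal(weighted_cross_entropy(mk(3), class_weights(c(1, 1, 2, 1))),
               2 * -log(0.25), tolerance = 1e-4)                     # 2.7726
  expect_equal(weighted_cross_entropy(mk(1), class_weights(c(1, 1, 1, 1))),
               cross_entropy(mk(1)))
  # focal: q_true = 0.5, gamma 2 -> 0.25 * ln 2 = 0.1733
  q2 <- array(c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3), dim = c(1, 1, 1, 4))
  p2 <- array(c(1, 0, 0, 0), dim = c(1, 1, 1, 4))
  f2 <- probability_field(q2, p2)
  expect_equal(focal_loss(f2, gamma = 2), 0.25 * log(2), tolerance = 1e-4)
  expect_equal(focal_loss(f2, gamma = 0), cross_entropy(f2), tolerance = 1e-6)
  # perfect prediction: all losses (near) zero
  fp <- probability_field(p2, p2)
  expect_lt(cross_entropy(fp), 1e-6)
  expect_lt(focal_loss(fp), 1e-6)
  expect_lt(dice_loss(fp), 1e-4)
})

test_that("Dice loss matches hand arithmetic and the printed 1/N variant", {
  # 4 voxels, 2 classes, p = [A,A,B,B], q uniform 0.5
  q <- array(0.5, dim = c(4, 1, 1, 2))
  p <- array(0, dim = c(4, 1, 1, 2))
  p[1:2, 1, 1, 1] <- 1; p[3:4, 1, 1, 2] <- 1
  f <- probability_field(q, p)
  expect_equal(dice_loss(f, mode = "canonical"), 1 - 2 * 2 / (4 + 4),
               tolerance = 1e-5)
  # algebraic relation between the two modes
  overlap <- 1 - dice_loss(f, mode = "canonical")
  expect_equal(dice_loss(f, mode = "as_printed"), 1 - overlap / f$N,
               tolerance = 1e-10)
})

test_that("vectorized losses agree with scalar-loop oracles", {
  for (seed in 1:10) {
    f <- random_field(n_vox = 100L, classes = 4L, seed = seed)
    expect_equal(cross_entropy(f), oracle_ce(f), tolerance = 1e-6)
    w <- class_weights(c(1, 1, 2, 1))
    expect_equal(weighted_cross_entropy(f, w), oracle_ce(f, w),
                 tolerance = 1e-6)
    expect_equal(focal_loss(f), oracle_focal(f), tolerance = 1e-6)
    expect_equal(dice_loss(f), oracle_dice_loss(f), tolerance = 1e-6)
    expect_equal(dice_loss(f, mode = "as_printed"),
                 oracle_dice_loss(f, as_printed = TRUE), tolerance = 1e-6)
    # non-negativity
    expect_gte(cross_entropy(f), 0)
    expect_gte(focal_loss(f), 0)
    expect_gte(dice_loss(f), 0)
  }
})

test_that("each loss decreases as true-class probability increases", {
  # single voxel, 2 classes, truth = class 1; sweep q_true upward
  mk <- function(qt) probability_field(
    array(c(qt, 1 - qt), dim = c(1, 1, 1, 2)),
    array(c(1, 0), dim = c(1, 1, 1, 2)))
  for (fn in list(cross_entropy,
                  function(f) weighted_cross_entropy(f, class_weights(c(2, 1))),
                  focal_loss,
                  dice_loss)) {
    vals <- vapply(c(0.2, 0.4, 0.6, 0.8), function(qt) fn(mk(qt)), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  # and the analytic gradients point the same way (finite differences)
  f <- mk(0.3)
  for (loss in c("ce", "wce", "focal", "dice")) {
    g <- ndnseg:::loss_grad(f, loss, weights = class_weights(c(2, 1)))
    expect_lt(g[1, 1, 1, 1], 0)   # raising q_true lowers the loss
  }
})

test_that("per-class case evaluation matches confusion-count arithmetic", {
  set.seed(3)
  case <- generate_phantom(phantom_config())
  expect_equal(unname(evaluate_case(case$labels, case$labels)), c(1, 1, 1))
  # erode the edema shell by dropping one x-slab of its voxels
  lab2 <- case$labels$labels
  idx <- which(lab2 == 1L, arr.ind = TRUE)
  cut <- idx[idx[, 1] == min(idx[, 1]), , drop = FALSE]
  lab2[cut] <- 0L
  pred <- label_volume(lab2)
  d <- evaluate_case(pred, case$labels)
  cc <- confusion_counts(lab2 == 1L, case$labels$labels == 1L)
  expect_equal(unname(d["edema"]), 2 * cc$TP / (cc$FP + 2 * cc$TP + cc$FN))
  # benign both-empty convention for the enhancing class
  ben <- generate_phantom(phantom_config(benign = TRUE))
  d2 <- evaluate_case(ben$labels, ben$labels)
  expect_equal(unname(d2["enhancing"]), 1)
  expect_true(sum(ben$labels$labels == 3L) == 0)
})

test_that("probability fields reject malformed inputs", {
  q <- array(c(0.7, 0.4), dim = c(1, 1, 1, 2))   # sums to 1.1
  p <- array(c(1, 0), dim = c(1, 1, 1, 2))
  expect_error(probability_field(q, p), "sum to 1")
  expect_error(probability_field(array(c(0.5, 0.5), dim = c(1, 1, 1, 2)),
                                 array(c(0.5, 0.5), dim = c(1, 1, 1, 2))),
               "one-hot")
})
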
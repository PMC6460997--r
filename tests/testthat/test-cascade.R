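test_that("stage target masks implement the nested class sets", {
  lab <- array(0:3, dim = c(4, 1, 1))
  expect_equal(as.vector(stage_target_mask(lab, 1)), c(F, T, T, T))
  expect_equal(as.vector(stage_target_mask(lab, 2)), c(F, F, T, T))
  expect_equal(as.vector(stage_target_mask(lab, 3)), c(F, F, F, T))
  # nesting invariant
  s3 <- cascade_stage(3); s2 <- cascade_stage(2); s1 <- cascade_stage(1)
  expect_true(all(s3$targets %in% s2$targets))
  expect_true(all(s2$targets %in% s1$targets))
  expect_error(cascade_stage(4), "1, 2 or 3")
})

test_that("bounding boxes are tight half-open 0-based intervals", {
  m <- array(FALSE, dim = c(10, 10, 10))
  m[6, 7, 8] <- TRUE
  b <- bounding_box(m)
  expect_equal(b$lo, c(5L, 6L, 7L))
  expect_equal(b$hi, c(6L, 7L, 8L))
  m[2, 2, 2] <- TRUE   # voxels (1,1,1) and (5,6,7) 0-based
  b2 <- bounding_box(m)
  expect_equal(b2$lo, c(1L, 1L, 1L))
  expect_equal(b2$hi, c(6L, 7L, 8L))
  full <- array(TRUE, dim = c(4, 5, 6))
  bf <- bounding_box(full)
  expect_equal(bf$lo, c(0L, 0L, 0L))
  expect_equal(bf$hi, c(4L, 5L, 6L))
  expect_true(bounding_box(array(FALSE, dim = c(3, 3, 3)))$empty)
})

test_that("ROI extension adds the cascade margins with clamping", {
  roi <- structure(list(lo = c(40L, 50L, 20L), hi = c(80L, 90L, 30L),
                        shape = c(240L, 240L, 155L), empty = FALSE),
                   class = "roi")
  ext <- extend_roi(roi)
  expect_equal(ext$lo, c(8L, 18L, 12L))
  expect_equal(ext$hi, c(112L, 122L, 38L))
  # clamping at the low and high borders
  roi0 <- structure(list(lo = c(0L, 10L, 150L), hi = c(20L, 230L, 155L),
                         shape = c(240L, 240L, 155L), empty = FALSE),
                    class = "roi")
  ext0 <- extend_roi(roi0)
  expect_equal(ext0$lo, c(0L, 0L, 142L))
  expect_equal(ext0$hi, c(52L, 240L, 155L))
  # zero margins are the identity
  expect_equal(extend_roi(roi, margins = c(0, 0, 0))$lo, roi$lo)
  expect_equal(extend_roi(roi, margins = c(0, 0, 0))$hi, roi$hi)
})

test_that("stage training examples pair crops with exact binary targets", {
  set.seed(10)
  case <- generate_phantom(phantom_config())
  vol <- zscore_normalize(case$volume)
  for (stage in 1:3) {
    ex <- make_stage_training_example(vol, case$labels, stage,
                                      patch_size = c(32L, 32L, 16L))
    expect_identical(dim(ex$input), c(32L, 32L, 16L, 4L))
    # the target is exactly the stage mask of the label crop
    expect_identical(ex$target, stage_target_mask(ex$labels, stage))
    expect_true(any(ex$target))
  }
  # a benign case has no stage-3 targets and is skipped with a warning
  ben <- generate_phantom(phantom_config(benign = TRUE))
  expect_warning(
    out <- make_stage_training_example(zscore_normalize(ben$volume),
                                       ben$labels, 3,
                                       patch_size = c(32L, 32L, 16L)),
    "skipped")
  expect_null(out)
})

test_that("mask fusion applies the later-stage precedence rule", {
  row <- function(idx, n = 10) { m <- rep(FALSE, n); m[idx] <- TRUE
    array(m, dim = c(n, 1, 1)) }
  m1 <- row(2:9); m2 <- row(4:7); m3 <- row(5:6)
  fused <- fuse_stage_masks(m1, m2, m3)
  expect_equal(as.vector(fused$labels), c(0, 1, 1, 2, 3, 3, 2, 1, 1, 0))
  # all-empty masks give all background
  e <- row(integer(0))
  expect_true(all(fuse_stage_masks(e, e, e)$labels == 0L))
  # a stage-3 voxel outside stage 2 still wins
  odd <- fuse_stage_masks(e, e, row(1))
  expect_equal(odd$labels[1, 1, 1], 3L)
  # idempotent / order-independent under fixed precedence
  fused2 <- fuse_stage_masks(fused$labels > 0,
                             fused$labels >= 2, fused$labels == 3)
  expect_identical(fused2$labels, fused$labels)
})

test_that("oracle predictors drive the cascade to exact ground truth", {
  set.seed(20)
  margins <- c(32L, 32L, 8L)
  for (i in 1:3) {
    case <- generate_phantom(phantom_config())
    vol <- zscore_normalize(case$volume)
    truth <- case$labels$labels
    # oracle predictors return the ground-truth stage mask for the crop the
    # cascade hands them; with a perfect previous stage, that crop is the
    # extended ground-truth ROI, which the oracle reconstructs independently
    preds <- lapply(1:3, function(s) {
      function(crop) {
        d <- dim(crop)[1:3]
        if (identical(d, dim(truth))) {
          ref <- truth
        } else {
          prev <- stage_target_mask(truth, s - 1L)
          roi <- extend_roi(bounding_box(prev), margins, dim(truth))
          ref <- ndnseg:::crop_to_roi(truth, roi)
          stopifnot(identical(dim(ref), d))
        }
        array(as.numeric(ref %in% cascade_stage(s)$targets), dim = d)
      }
    })
    out <- run_cascade(preds, vol, margins = margins)
    expect_identical(out$labels$labels, truth)
    expect_equal(unname(evaluate_case(out$labels, case$labels)), c(1, 1, 1))
    # logged stage-2 box equals extend_roi(bounding_box(stage-1 mask))
    expected_roi <- extend_roi(bounding_box(out$masks[[1]]), margins,
                               dim(truth))
    expect_equal(out$rois[[2]]$lo, expected_roi$lo)
    expect_equal(out$rois[[2]]$hi, expected_roi$hi)
    # every stage crop contains its predecessor's positive voxels
    for (s in 2:3) {
      pos <- which(out$masks[[s - 1]], arr.ind = TRUE)
      roi <- out$rois[[s]]
      expect_true(all(pos[, 1] > roi$lo[1] & pos[, 1] <= roi$hi[1] &
                        pos[, 2] > roi$lo[2] & pos[, 2] <= roi$hi[2] &
                        pos[, 3] > roi$lo[3] & pos[, 3] <= roi$hi[3]))
    }
  }
})

test_that("empty stage masks short-circuit the cascade", {
  set.seed(21)
  case <- generate_phantom(phantom_config())
  vol <- zscore_normalize(case$volume)
  zero <- function(crop) array(0, dim = dim(crop)[1:3])
  one <- function(crop) array(1, dim = dim(crop)[1:3])
  out <- run_cascade(list(zero, one, one), vol)
  expect_true(all(out$labels$labels == 0L))
  expect_null(out$rois[[2]])
  # empty stage 2 skips stage 3
  out2 <- run_cascade(list(one, zero, one), vol)
  expect_true(all(out2$masks[[3]] == FALSE))
  expect_null(out2$rois[[3]])
})
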
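test_that("z-score normalization matches hand arithmetic and is idempotent", {
  # channel [1,2,3]: population sigma = sqrt(2/3)
  arr <- array(0, dim = c(3, 1, 1, 4))
  for (c in 1:4) arr[, 1, 1, c] <- c(1, 2, 3) * c
  v <- multimodal_volume(arr)
  out <- zscore_normalize(v)
  expect_equal(out$intensities[, 1, 1, 1], c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)
  # constant channel maps to zeros
  arr2 <- arr; arr2[, , , 2] <- 7
  out2 <- zscore_normalize(multimodal_volume(arr2))
  expect_true(all(out2$intensities[, , , 2] == 0))
  # definitional property + idempotence on a random volume
  v3 <- tiny_volume(c(6L, 5L, 4L), seed = 3)
  n1 <- zscore_normalize(v3)
  for (c in 1:4) {
    ch <- n1$intensities[, , , c]
    expect_lt(abs(mean(ch)), 1e-6)
    expect_lt(abs(sqrt(mean((ch - mean(ch))^2)) - 1), 1e-6)
  }
  n2 <- zscore_normalize(n1)
  expect_equal(n2$intensities, n1$intensities, tolerance = 1e-6)
})

test_that("black-border cropping finds the tight x/y box and leaves z alone", {
  arr <- array(0, dim = c(10, 10, 4, 4))
  arr[3:7, 4:9, , 1] <- 1          # nonzero in x in [2,7), y in [3,9) 0-based
  lab <- label_volume(array(rep(0:1, length.out = 400), dim = c(10, 10, 4)))
  out <- crop_black_borders(multimodal_volume(arr), lab)
  expect_identical(out$volume$shape, c(5L, 6L, 4L))
  expect_equal(out$report$box$x, c(2L, 7L))
  expect_equal(out$report$box$y, c(3L, 9L))
  expect_equal(out$report$box$z, c(0L, 4L))
  # labels cropped with the identical box
  expect_identical(out$labels$labels, lab$labels[3:7, 4:9, , drop = FALSE])
  # fully nonzero volume is unchanged
  full <- multimodal_volume(array(1, dim = c(4, 4, 2, 4)))
  out2 <- crop_black_borders(full)
  expect_identical(out2$volume$shape, c(4L, 4L, 2L))
  expect_error(crop_black_borders(
    multimodal_volume(array(0, dim = c(3, 3, 2, 4)))), "all-zero")
})

test_that("middle-slab selection keeps round(fraction*Z) centered slices", {
  mk <- function(Z) multimodal_volume(array(seq_len(4 * 4 * Z * 4),
                                            dim = c(4, 4, Z, 4)))
  out <- select_middle_slab(mk(100), fraction = 0.7)
  expect_equal(out$z_range, c(15, 85))
  expect_identical(out$volume$shape[3], 70L)
  out2 <- select_middle_slab(mk(10), fraction = 0.7)
  expect_equal(out2$z_range, c(1, 8))
  out3 <- select_middle_slab(mk(6), fraction = 1.0)
  expect_equal(out3$z_range, c(0, 6))
  expect_identical(out3$volume$intensities, mk(6)$intensities)
  expect_error(select_middle_slab(mk(4), fraction = 0.1), "empty")
})

test_that("patch sampling is tumor-centered, padded and deterministic", {
  set.seed(5)
  case <- generate_phantom(phantom_config())
  vol <- zscore_normalize(case$volume)
  for (i in 1:100) {
    p <- sample_patch(vol, case$labels, size = c(16L, 16L, 8L))
    expect_true(any(p$labels > 0))
    expect_identical(dim(p$labels), c(16L, 16L, 8L))
  }
  # undersized source gets zero-padded to the requested size
  small_vol <- multimodal_volume(array(1, dim = c(12, 12, 6, 4)))
  small_lab <- label_volume(array(c(rep(0L, 400), rep(1L, 464)),
                                  dim = c(12, 12, 6)))
  p <- sample_patch(small_vol, small_lab, size = c(24L, 24L, 12L))
  expect_identical(dim(p$intensities), c(24L, 24L, 12L, 4L))
  expect_true(any(p$intensities == 0))   # padding present
  # determinism under equal seeds
  set.seed(77); p1 <- sample_patch(vol, case$labels, size = c(16L, 16L, 8L))
  set.seed(77); p2 <- sample_patch(vol, case$labels, size = c(16L, 16L, 8L))
  expect_identical(p1$origin, p2$origin)
  expect_identical(p1$intensities, p2$intensities)
  # no tumor voxels is a hard error
  empty <- label_volume(array(0L, dim = c(12, 12, 6)))
  expect_error(sample_patch(small_vol, empty, c(8L, 8L, 4L)), "no tumor")
})

test_that("crop/slab/sample pipeline keeps labels aligned with intensities", {
  set.seed(8)
  case <- generate_phantom(phantom_config())
  crop <- crop_black_borders(case$volume, case$labels)
  slab <- select_middle_slab(crop$volume, crop$labels, fraction = 0.9)
  # tag each voxel with a unique intensity so alignment is checkable
  tag <- array(seq_len(prod(slab$volume$shape)), dim = slab$volume$shape)
  tagged <- slab$volume
  tagged$intensities[, , , 1] <- tag
  p <- sample_patch(tagged, slab$labels, size = c(24L, 24L, 12L))
  inside <- p$intensities[, , , 1] > 0
  src_idx <- p$intensities[, , , 1][inside]
  expect_identical(as.vector(p$labels[inside]),
                   as.vector(slab$labels$labels[src_idx]))
})
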
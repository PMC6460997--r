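test_that("connectivity semantics distinguish face, edge and corner contact", {
  m <- array(FALSE, dim = c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 1, 1] <- TRUE          # face contact
  expect_length(connected_components(m, 6)$sizes, 1)
  expect_length(connected_components(m, 26)$sizes, 1)
  m2 <- array(FALSE, dim = c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE        # corner-only contact
  expect_length(connected_components(m2, 6)$sizes, 2)
  expect_length(connected_components(m2, 18)$sizes, 2)
  expect_length(connected_components(m2, 26)$sizes, 1)
  m3 <- array(FALSE, dim = c(4, 4, 4))
  m3[1, 1, 1] <- TRUE; m3[2, 2, 1] <- TRUE        # edge contact
  expect_length(connected_components(m3, 6)$sizes, 2)
  expect_length(connected_components(m3, 18)$sizes, 1)
  empty <- connected_components(array(FALSE, dim = c(3, 3, 3)))
  expect_length(empty$sizes, 0)
  expect_true(all(empty$labels == 0L))
})

test_that("component labeling matches a naive flood-fill oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- array(runif(10 * 9 * 8) < 0.35, dim = c(10, 9, 8))
    for (conn in c(6L, 18L, 26L)) {
      got <- connected_components(m, conn)
      ref <- oracle_components(m, conn)
      # same partition (ids may in principle differ; compare co-membership
      # via sorted size multiset and voxelwise id remapping)
      expect_identical(sort(got$sizes), sort(as.vector(table(ref[ref > 0]))))
      remap <- got$labels[m]
      refm <- ref[m]
      expect_identical(as.vector(tapply(refm, remap,
                                        function(v) length(unique(v)))),
                       rep(1L, length(got$sizes)))
      expect_equal(sum(got$sizes), sum(m))
    }
  }
})

test_that("only the largest whole-tumor component survives", {
  lab <- array(0L, dim = c(20, 20, 10))
  lab[3:7, 3:7, 3:6] <- 1L                     # 100-voxel cluster
  lab[15, 15, 8] <- 2L                         # isolated small cluster
  lab[16, 15, 8] <- 3L
  out <- keep_largest_component(label_volume(lab))
  expect_true(all(out$labels[15:16, 15, 8] == 0L))
  expect_identical(out$labels[3:7, 3:7, 3:6], lab[3:7, 3:7, 3:6])
  # single cluster is untouched
  single <- label_volume(array(c(rep(0L, 50), rep(1L, 14)), dim = c(4, 4, 4)))
  expect_identical(keep_largest_component(single)$labels, single$labels)
  # equal sizes: the first-discovered (lowest linear index) survives
  tie <- array(0L, dim = c(10, 4, 4))
  tie[1:2, 1, 1] <- 1L
  tie[8:9, 1, 1] <- 1L
  out2 <- keep_largest_component(label_volume(tie))
  expect_identical(as.vector(which(out2$labels > 0L)), c(1L, 2L))
})

test_that("small enhancing clusters are relabeled without changing tumor extent", {
  lab <- array(0L, dim = c(24, 24, 12))
  lab[2:20, 2:20, 2:10] <- 1L
  lab[4:12, 4:12, 4:8] <- 3L                   # large enhancing block
  lab[17:18, 17, 7] <- 3L                      # 2-voxel speck inside tumor
  lv <- label_volume(lab)
  out <- remove_small_enhancing(lv, min_volume = 50)
  expect_identical(out$labels[17:18, 17, 7], c(2L, 2L))
  expect_identical(out$labels[4:12, 4:12, 4:8], lab[4:12, 4:12, 4:8])
  expect_equal(sum(out$labels > 0L), sum(lab > 0L))   # whole tumor unchanged
  # min_volume 0 and benign grids are identities
  expect_identical(remove_small_enhancing(lv, 0)$labels, lab)
  ben <- label_volume(array(c(rep(0L, 20), rep(2L, 44)), dim = c(4, 4, 4)))
  expect_identical(remove_small_enhancing(ben, 100)$labels, ben$labels)
  # delete mode clears instead of relabeling
  out2 <- remove_small_enhancing(lv, min_volume = 50, mode = "delete")
  expect_identical(out2$labels[17:18, 17, 7], c(0L, 0L))
})

test_that("the pipeline recovers artifact-injected phantoms exactly", {
  set.seed(30)
  for (i in 1:3) {
    case <- generate_phantom(phantom_config())
    injected <- inject_artifacts(case, phantom_config(), k_distractors = 3,
                                 speck_size = 5)
    cc <- connected_components(injected$labels$labels > 0L)
    expect_length(cc$sizes, 4L)   # main tumor + 3 distractors
    restored <- postprocess_pipeline(injected$labels, min_volume = 200)
    expect_identical(restored$labels, injected$truth$labels)
    # idempotence
    expect_identical(postprocess_pipeline(restored, min_volume = 200)$labels,
                     restored$labels)
  }
  # clean phantom passes through unchanged
  clean <- generate_phantom(phantom_config())
  expect_identical(postprocess_pipeline(clean$labels, min_volume = 200)$labels,
                   clean$labels$labels)
  # never adds foreground
  set.seed(31)
  noisy <- tiny_labels(c(10L, 10L, 6L))
  post <- postprocess_pipeline(noisy, min_volume = 4)
  expect_true(all(which(post$labels > 0L) %in% which(noisy$labels > 0L)))
})
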
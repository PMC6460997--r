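# Coarse-to-fine cascade: three nested binary segmentation problems.
# Stage 1 targets the whole tumor {1,2,3}, stage 2 the tumor core {2,3},
# stage 3 the enhancing tumor {3}. At test time each stage runs inside the
# previous stage's bounding box extended by fixed margins.

CASCADE_TARGETS <- list(`1` = c(1L, 2L, 3L), `2` = c(2L, 3L), `3` = 3L)

#' Cascade stage definition
#'
#' @param index Stage number 1, 2 or 3.
#' @return Object of class `cascade_stage` with the stage's target class
#'   set (nested: stage 3 within stage 2 within stage 1).
#' @export
cascade_stage <- function(index) {
  index <- as.integer(index)
  if (!index %in% 1:3) stop("stage index must be 1, 2 or 3")
  structure(list(index = index, targets = CASCADE_TARGETS[[index]]),
            class = "cascade_stage")
}

#' Binary target mask for a cascade stage
#'
#' @param labels A [label_volume()] or integer array.
#' @param stage A [cascade_stage()] or stage index.
#' @return Logical array: TRUE where the voxel label is in the stage's
#'   target set.
#' @export
stage_target_mask <- function(labels, stage) {
  if (!inherits(stage, "cascade_stage")) stage <- cascade_stage(stage)
  grid <- if (inherits(labels, "label_volume")) labels$labels else labels
  array(grid %in% stage$targets, dim = dim(grid))
}

#' Tight bounding box of a binary mask
#'
#' Boxes are half-open 0-based intervals per axis. An empty mask yields a
#' distinguished empty ROI (`empty = TRUE`), which [run_cascade()] treats as
#' an early exit.
#'
#' @param mask Logical 3-D array.
#' @return Object of class `roi` with `lo`, `hi` (0-based half-open) and
#'   `shape`.
#' @export
bounding_box <- function(mask) {
  d <- dim(mask)
  if (!any(mask))
    return(structure(list(lo = NULL, hi = NULL, shape = d, empty = TRUE),
                     class = "roi"))
  idx <- which(mask)
  co <- arrayInd(idx, d)
  structure(list(lo = apply(co, 2, min) - 1L, hi = apply(co, 2, max),
                 shape = d, empty = FALSE),
            class = "roi")
}

#' Extend an ROI by fixed margins, clamped to the volume
#'
#' The cascade extends each stage's box by 32 voxels along x and y and 8
#' slices along z before cropping the next stage's input.
#'
#' @param roi An [bounding_box()] result.
#' @param margins Integer length-3 margins, default c(32, 32, 8).
#' @param shape Volume shape used for clamping (default the ROI's own).
#' @return The extended `roi`.
#' @export
extend_roi <- function(roi, margins = c(32L, 32L, 8L), shape = roi$shape) {
  if (isTRUE(roi$empty)) return(roi)
  lo <- pmax(roi$lo - as.integer(margins), 0L)
  hi <- pmin(roi$hi + as.integer(margins), as.integer(shape))
  structure(list(lo = lo, hi = hi, shape = as.integer(shape), empty = FALSE),
            class = "roi")
}

roi_ranges <- function(roi) {
  lapply(1:3, function(ax) (roi$lo[ax] + 1L):roi$hi[ax])
}

crop_to_roi <- function(arr, roi) {
  r <- roi_ranges(roi)
  if (length(dim(arr)) == 4L)
    arr[r[[1]], r[[2]], r[[3]], , drop = FALSE]
  else
    arr[r[[1]], r[[2]], r[[3]], drop = FALSE]
}

embed_in_frame <- function(mask, roi) {
  out <- array(FALSE, dim = roi$shape)
  r <- roi_ranges(roi)
  out[r[[1]], r[[2]], r[[3]]] <- mask
  out
}

#' Build one training example for a cascade stage
#'
#' Training inputs derive from ground truth: the parent region's ROI
#' (stage 1: the whole volume; stages 2-3: the previous stage's target mask)
#' is extended by the cascade margins and cropped, then a tumor-centered
#' patch is sampled inside it and paired with the stage's binary target.
#'
#' @param volume A (normalized) [multimodal_volume()].
#' @param labels The matching [label_volume()].
#' @param stage A [cascade_stage()] or index.
#' @param patch_size Integer length-3, default c(96, 96, 48).
#' @param margins Extension margins, default c(32, 32, 8).
#' @param center `"target"` draws the patch center uniformly from the
#'   stage's target voxels (the default); `"uniform"` places the patch
#'   uniformly inside the parent ROI regardless of content, yielding
#'   (mostly) negative examples that teach the network what tumor-free
#'   tissue looks like.
#' @return List with `input` (x,y,z,4), `target` (logical x,y,z), `labels`
#'   (the label crop) and `roi`; or `NULL` with a warning when the parent
#'   region is empty (case skipped).
#' @export
make_stage_training_example <- function(volume, labels, stage,
                                        patch_size = c(96L, 96L, 48L),
                                        margins = c(32L, 32L, 8L),
                                        center = c("target", "uniform")) {
  center <- match.arg(center)
  if (!inherits(stage, "cascade_stage")) stage <- cascade_stage(stage)
  if (stage$index == 1L) {
    roi <- structure(list(lo = c(0L, 0L, 0L), hi = labels$shape,
                          shape = labels$shape, empty = FALSE), class = "roi")
  } else {
    parent <- stage_target_mask(labels, stage$index - 1L)
    box <- bounding_box(parent)
    if (box$empty) {
      warning("case has empty parent region for stage ", stage$index,
              "; skipped")
      return(NULL)
    }
    roi <- extend_roi(box, margins)
  }
  vol_crop <- crop_to_roi(volume$intensities, roi)
  lab_crop <- crop_to_roi(labels$labels, roi)
  patch_size <- as.integer(patch_size)
  if (center == "uniform") {
    # unbiased placement inside the (padded) parent ROI; the target mask
    # may legitimately be empty
    shp <- dim(lab_crop)
    pad <- pmax(patch_size - shp, 0L)
    if (any(pad > 0L)) {
      lo_pad <- pad %/% 2L
      vp <- array(0, dim = c(shp + pad, 4L))
      vp[lo_pad[1] + seq_len(shp[1]), lo_pad[2] + seq_len(shp[2]),
         lo_pad[3] + seq_len(shp[3]), ] <- vol_crop
      vol_crop <- vp
      shp <- shp + pad
    }
    origin <- vapply(1:3, function(ax)
      sample.int(shp[ax] - patch_size[ax] + 1L, 1L) - 1L, integer(1))
    input <- vol_crop[origin[1] + seq_len(patch_size[1]),
                      origin[2] + seq_len(patch_size[2]),
                      origin[3] + seq_len(patch_size[3]), , drop = FALSE]
    full_lab <- pad_and_crop_labels(lab_crop, origin, patch_size)
    return(list(input = input,
                target = array(full_lab %in% stage$targets,
                               dim = patch_size),
                labels = full_lab, roi = roi))
  }
  if (!any(lab_crop %in% stage$targets)) {
    warning("case has no stage-", stage$index, " target voxels; skipped")
    return(NULL)
  }
  # anchor the patch on a uniformly drawn target voxel, but place that
  # anchor at a uniformly random position inside the patch: centering every
  # patch on tumor would teach the network a spurious location prior
  shp <- dim(lab_crop)
  pad <- pmax(patch_size - shp, 0L)
  lo_pad <- pad %/% 2L
  if (any(pad > 0L)) {
    vp <- array(0, dim = c(shp + pad, 4L))
    vp[lo_pad[1] + seq_len(shp[1]), lo_pad[2] + seq_len(shp[2]),
       lo_pad[3] + seq_len(shp[3]), ] <- vol_crop
    vol_crop <- vp
  }
  pshp <- shp + pad
  targets_idx <- which(lab_crop %in% stage$targets)
  anchor <- arrayInd(targets_idx[[sample.int(length(targets_idx), 1L)]],
                     shp)[1, ] + lo_pad
  offset <- vapply(1:3, function(ax) sample.int(patch_size[ax], 1L) - 1L,
                   integer(1))
  origin <- pmin(pmax(anchor - 1L - offset, 0L), pshp - patch_size)
  input <- vol_crop[origin[1] + seq_len(patch_size[1]),
                    origin[2] + seq_len(patch_size[2]),
                    origin[3] + seq_len(patch_size[3]), , drop = FALSE]
  full_lab <- pad_and_crop_labels(lab_crop, origin, patch_size)
  list(input = input,
       target = array(full_lab %in% stage$targets, dim = patch_size),
       labels = full_lab, roi = roi)
}

# Reproduce sample_patch's padding geometry to crop a label grid at the
# same origin.
pad_and_crop_labels <- function(lab, origin, size) {
  shp <- dim(lab)
  pad <- pmax(size - shp, 0L)
  lo_pad <- pad %/% 2L
  if (any(pad > 0L)) {
    lp <- array(0L, dim = shp + pad)
    lp[lo_pad[1] + seq_len(shp[1]), lo_pad[2] + seq_len(shp[2]),
       lo_pad[3] + seq_len(shp[3])] <- lab
    lab <- lp
  }
  lab[origin[1] + seq_len(size[1]), origin[2] + seq_len(size[2]),
      origin[3] + seq_len(size[3]), drop = FALSE]
}

#' Fuse the three cascade stage masks into a label volume
#'
#' Later (finer) stages take precedence: label 3 where the enhancing mask is
#' set, else 2 where the core mask is set, else 1 where the whole-tumor mask
#' is set, else 0.
#'
#' @param m1,m2,m3 Logical arrays of one shape (stages 1-3).
#' @return A [label_volume()].
#' @export
fuse_stage_masks <- function(m1, m2, m3) {
  stopifnot(identical(dim(m1), dim(m2)), identical(dim(m2), dim(m3)))
  lab <- array(0L, dim = dim(m1))
  lab[m1] <- 1L
  lab[m2] <- 2L
  lab[m3] <- 3L
  label_volume(lab)
}

#' Run the full three-stage cascade on a volume
#'
#' Stage 1 predicts on the whole (preprocessed) volume; its binarized mask's
#' bounding box, extended by the margins, crops stage 2's input, and
#' likewise stage 2 crops stage 3. Each stage mask is re-embedded in the
#' full-volume frame before fusion. An empty stage-1 mask short-circuits to
#' an all-background result; an empty stage-2 mask skips stage 3.
#'
#' @param predictors List of three functions; each takes a 4-channel crop
#'   and returns per-voxel foreground probabilities (same spatial shape).
#' @param volume A (normalized) [multimodal_volume()].
#' @param margins Extension margins, default c(32, 32, 8).
#' @param threshold Foreground binarization threshold, default 0.5.
#' @return List with `masks` (3 logical full-frame arrays), `labels` (the
#'   fused [label_volume()]) and `rois` (the per-stage crop boxes).
#' @export
run_cascade <- function(predictors, volume, margins = c(32L, 32L, 8L),
                        threshold = 0.5) {
  stopifnot(length(predictors) == 3L)
  shape <- volume$shape
  empty <- array(FALSE, dim = shape)
  full_roi <- structure(list(lo = c(0L, 0L, 0L), hi = shape, shape = shape,
                             empty = FALSE), class = "roi")
  rois <- list(full_roi, NULL, NULL)
  masks <- list(empty, empty, empty)

  m1 <- predictors[[1]](volume$intensities) >= threshold
  masks[[1]] <- m1
  if (any(m1)) {
    roi2 <- extend_roi(bounding_box(m1), margins, shape)
    rois[[2]] <- roi2
    crop2 <- crop_to_roi(volume$intensities, roi2)
    m2 <- predictors[[2]](crop2) >= threshold
    masks[[2]] <- embed_in_frame(m2, roi2)
    if (any(m2)) {
      roi3 <- extend_roi(bounding_box(masks[[2]]), margins, shape)
      rois[[3]] <- roi3
      crop3 <- crop_to_roi(volume$intensities, roi3)
      m3 <- predictors[[3]](crop3) >= threshold
      masks[[3]] <- embed_in_frame(m3, roi3)
    }
  }
  list(masks = masks,
       labels = fuse_stage_masks(masks[[1]], masks[[2]], masks[[3]]),
       rois = rois)
}
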
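# Multimodal phantom generator: nested ellipsoidal tumor sub-regions inside
# an elliptical brain mask, with per-modality class contrast and Gaussian
# noise. The goal is statistical structure sufficient to train and test the
# pipeline, not MR physics realism.

#' Phantom configuration
#'
#' Defaults describe a 64 x 64 x 32 voxel case: an elliptical "brain" of
#' semi-axes (28, 28, 14) holding nested tumor ellipsoids -- whole tumor
#' (13, 13, 9), core (8, 8, 5), enhancing (5, 5, 3) -- at a randomized
#' center. The class-mean table gives each synthetic modality a distinct
#' contrast: the post-contrast T1 channel is bright in enhancing tumor and
#' the FLAIR channel bright in edema, mimicking their clinical roles.
#'
#' @param shape Volume shape, default c(64, 64, 32).
#' @param brain_semi_axes Brain-mask ellipsoid semi-axes (voxels).
#' @param whole_semi_axes,core_semi_axes,enh_semi_axes Nested tumor
#'   ellipsoid semi-axes; must be ordered enh <= core <= whole.
#' @param class_means 4 x 4 numeric matrix, rows = modality (T1, T2, post-
#'   contrast T1, FLAIR), columns = tissue (brain, edema, non-enhancing,
#'   enhancing).
#' @param noise_sd Gaussian noise standard deviation, default 10.
#' @param benign If TRUE, the enhancing region is merged into non-enhancing
#'   (a tumor without enhancement).
#' @param center_range Optional 3 x 2 matrix of min/max tumor-center voxel
#'   coordinates; default keeps the whole ellipsoid inside the brain.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 32L),
                           brain_semi_axes = c(28, 28, 14),
                           whole_semi_axes = c(13, 13, 9),
                           core_semi_axes = c(8, 8, 5),
                           enh_semi_axes = c(5, 5, 3),
                           class_means = default_class_means(),
                           noise_sd = 10,
                           benign = FALSE,
                           center_range = NULL) {
  stopifnot(all(enh_semi_axes <= core_semi_axes),
            all(core_semi_axes <= whole_semi_axes),
            all(enh_semi_axes >= 1), all(shape > 0), noise_sd >= 0,
            identical(dim(class_means), c(4L, 4L)))
  if (is.null(center_range)) {
    c0 <- (shape + 1) / 2
    # conservative: center within a box that keeps the whole-tumor
    # ellipsoid well inside the brain ellipsoid
    slack <- pmax(floor(0.55 * brain_semi_axes - whole_semi_axes), 0)
    center_range <- cbind(ceiling(c0 - slack), floor(c0 + slack))
  }
  structure(list(shape = as.integer(shape), brain_semi_axes = brain_semi_axes,
                 whole_semi_axes = whole_semi_axes,
                 core_semi_axes = core_semi_axes,
                 enh_semi_axes = enh_semi_axes, class_means = class_means,
                 noise_sd = noise_sd, benign = benign,
                 center_range = center_range),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_class_means <- function() {
  m <- rbind(t1    = c(100,  80,  70,  75),
             t2    = c(100, 140, 120, 110),
             t1ce  = c(100,  90,  80, 160),
             flair = c(100, 160, 120, 110))
  colnames(m) <- c("brain", "edema", "non_enhancing", "enhancing")
  m
}

ellipsoid_mask <- function(shape, center, semi) {
  gx <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape)
  gy <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape)
  gz <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  ((gx - center[1]) / semi[1])^2 + ((gy - center[2]) / semi[2])^2 +
    ((gz - center[3]) / semi[3])^2 <= 1
}

#' Generate one multimodal phantom case
#'
#' Labels are nested ellipsoids at a randomized center: enhancing innermost
#' (3), core shell (2), edema shell (1), brain tissue 0 inside an elliptical
#' brain mask and exact zero outside it (so border cropping has work to do).
#' Each modality is a class-mean lookup plus Gaussian noise. The whole-tumor
#' region is one connected component by construction. Deterministic under
#' the current RNG state.
#'
#' @param config A [phantom_config()].
#' @return List with `volume` ([multimodal_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
generate_phantom <- function(config = phantom_config()) {
  shp <- config$shape
  cr <- config$center_range
  center <- vapply(1:3, function(ax)
    if (cr[ax, 1] >= cr[ax, 2]) cr[ax, 1]
    else stats::runif(1, cr[ax, 1], cr[ax, 2]), numeric(1))
  brain_center <- (shp + 1) / 2
  brain <- ellipsoid_mask(shp, brain_center, config$brain_semi_axes)
  whole <- ellipsoid_mask(shp, center, config$whole_semi_axes)
  core <- ellipsoid_mask(shp, center, config$core_semi_axes)
  enh <- ellipsoid_mask(shp, center, config$enh_semi_axes)
  if (any(whole & !brain))
    stop("tumor ellipsoid exceeds the brain mask; shrink semi-axes or ",
         "center range")
  labels <- array(0L, dim = shp)
  labels[whole] <- 1L
  labels[core] <- 2L
  labels[enh] <- if (config$benign) 2L else 3L

  # tissue code per voxel: 0 outside brain, 1 brain, 2 edema, 3 core, 4 enh
  tissue <- array(0L, dim = shp)
  tissue[brain] <- 1L
  tissue[labels > 0L] <- labels[labels > 0L] + 1L

  arr <- array(0, dim = c(shp, 4L))
  n <- prod(shp)
  for (m in 1:4) {
    means <- c(0, config$class_means[m, ])       # index by tissue + 1
    ch <- means[tissue + 1L] + stats::rnorm(n, sd = config$noise_sd)
    ch[tissue == 0L] <- 0                         # true zero background
    arr[, , , m] <- ch
  }
  list(volume = multimodal_volume(arr), labels = label_volume(labels))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` seeded phantoms (randomized centers; optionally a benign
#' fraction) as NIfTI files plus a case manifest compatible with
#' [read_manifest()].
#'
#' @param n Number of cases.
#' @param dir Output directory (created if needed).
#' @param config Base [phantom_config()].
#' @param benign_fraction Fraction of cases generated with `benign = TRUE`;
#'   default 0.
#' @param seed Master seed; per-case seeds derive from it.
#' @return List of [case_record()]s (manifest written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
generate_dataset <- function(n, dir, config = phantom_config(),
                             benign_fraction = 0, seed = 1L) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max, n)
  benign <- stats::runif(n) < benign_fraction
  records <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(case_seeds[i])
    cfg <- config
    cfg$benign <- benign[i]
    case <- generate_phantom(cfg)
    id <- sprintf("phantom_%03d", i)
    paths <- stats::setNames(file.path(dir, paste0(id, "_", MODALITIES,
                                                   ".nii.gz")), MODALITIES)
    lab_path <- file.path(dir, paste0(id, "_labels.nii.gz"))
    write_volume(case$volume, paths)
    write_labels(case$labels, lab_path)
    records[[i]] <- case_record(id, paths[["t1"]], paths[["t2"]],
                                paths[["t1ce"]], paths[["flair"]],
                                labels = lab_path)
  }
  write_manifest(records, file.path(dir, "manifest.csv"))
  records
}

#' Inject post-processing test artifacts into a case
#'
#' Adds `k_distractors` small tumor-labeled spheres disjoint from the main
#' tumor (inside the brain mask) and, when `speck_size > 0`, one small
#' enhancing speck inside the core region. The pre-injection labels are
#' returned so recovery by [postprocess_pipeline()] can be verified.
#'
#' @param case List with `volume` and `labels` from [generate_phantom()].
#' @param config The [phantom_config()] used to generate it.
#' @param k_distractors Number of distractor blobs.
#' @param speck_size Approximate voxel count of the enhancing speck.
#' @return The case with `labels` modified, plus `truth` (pre-injection
#'   labels).
#' @export
inject_artifacts <- function(case, config = phantom_config(),
                             k_distractors = 3L, speck_size = 5L) {
  truth <- case$labels
  grid <- truth$labels
  shp <- dim(grid)
  if (k_distractors > 0) {
    brain <- ellipsoid_mask(shp, (shp + 1) / 2, config$brain_semi_axes)
    # dilate-ish exclusion: stay away from existing tumor by bounding box + margin
    box <- bounding_box(grid > 0L)
    margin <- 4L
    candidates <- which(brain & grid == 0L)
    co <- arrayInd(candidates, shp)
    far <- co[, 1] < box$lo[1] - margin | co[, 1] > box$hi[1] + margin |
      co[, 2] < box$lo[2] - margin | co[, 2] > box$hi[2] + margin |
      co[, 3] < box$lo[3] - margin | co[, 3] > box$hi[3] + margin
    pool <- candidates[far]
    # keep blobs off the brain border so the sphere stays inside the mask
    if (length(pool) < k_distractors)
      stop("no room to place ", k_distractors, " disjoint distractors")
    placed <- 0L
    tries <- 0L
    while (placed < k_distractors && tries < 200L) {
      tries <- tries + 1L
      cen_idx <- pool[sample.int(length(pool), 1L)]
      cen <- arrayInd(cen_idx, shp)[1, ]
      blob <- ellipsoid_mask(shp, cen, c(2, 2, 1.5))
      if (all(brain[blob]) && all(grid[blob] == 0L)) {
        grid[blob] <- 1L
        placed <- placed + 1L
      }
    }
    if (placed < k_distractors)
      stop("no room to place ", k_distractors, " disjoint distractors")
  }
  if (speck_size > 0) {
    core2 <- which(grid == 2L)
    if (!length(core2)) stop("no non-enhancing voxels to host the speck")
    r <- max(1, (3 * speck_size / (4 * pi))^(1 / 3))
    placed_speck <- FALSE
    for (try in 1:200) {
      cen <- arrayInd(core2[sample.int(length(core2), 1L)], shp)[1, ]
      guard <- ellipsoid_mask(shp, cen, rep(r + 1.5, 3))
      if (any(grid[guard] == 3L)) next   # would touch the real enhancing core
      speck <- ellipsoid_mask(shp, cen, rep(r, 3)) & grid == 2L
      if (!any(speck)) next
      grid[speck] <- 3L
      placed_speck <- TRUE
      break
    }
    if (!placed_speck)
      stop("no room to place an enhancing speck disjoint from the core")
  }
  case$labels <- label_volume(grid, spacing = truth$spacing)
  case$truth <- truth
  case
}
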
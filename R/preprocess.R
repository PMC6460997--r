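#' Z-score normalize each modality
#'
#' Per channel, subtracts the mean and divides by the population standard
#' deviation (divide-by-n), computed over the whole volume for one patient.
#' A constant channel (zero variance) maps to all zeros.
#'
#' @param volume A [multimodal_volume()].
#' @return A [multimodal_volume()] with per-channel mean 0 and sd 1.
#' @export
zscore_normalize <- function(volume) {
  x <- volume$intensities
  if (!all(is.finite(x))) stop("non-finite intensities")
  for (c in 1:4) {
    ch <- x[, , , c]
    mu <- mean(ch)
    sigma <- sqrt(mean((ch - mu)^2))
    x[, , , c] <- if (sigma > 0) (ch - mu) / sigma else 0
  }
  multimodal_volume(x, spacing = volume$spacing, orientation = volume$orientation)
}

#' Crop uninformative black borders in x and y
#'
#' Reduces the x/y extent to the tight bounding box of voxels that are
#' nonzero in any channel; the z-axis is left untouched (it is handled by
#' [select_middle_slab()]). Labels, when given, are cropped with the same
#' box.
#'
#' @param volume A [multimodal_volume()].
#' @param labels Optional [label_volume()] sharing the volume's shape.
#' @return List with `volume`, `labels` (or `NULL`) and `report`, the latter
#'   holding the kept half-open box per axis and the original shape.
#' @export
crop_black_borders <- function(volume, labels = NULL) {
  x <- volume$intensities
  nz <- apply(x != 0, 1:3, any)
  if (!any(nz)) stop("all-zero volume: nothing to keep")
  xs <- which(apply(nz, 1, any)); ys <- which(apply(nz, 2, any))
  d <- dim(nz)
  box <- list(x = c(min(xs) - 1L, max(xs)),   # half-open, 0-based
              y = c(min(ys) - 1L, max(ys)),
              z = c(0L, d[3]))
  xr <- (box$x[1] + 1L):box$x[2]; yr <- (box$y[1] + 1L):box$y[2]
  out_v <- multimodal_volume(x[xr, yr, , , drop = FALSE],
                             spacing = volume$spacing,
                             orientation = volume$orientation)
  out_l <- NULL
  if (!is.null(labels)) {
    stopifnot(identical(labels$shape, volume$shape))
    out_l <- label_volume(labels$labels[xr, yr, , drop = FALSE],
                          spacing = labels$spacing)
  }
  list(volume = out_v, labels = out_l,
       report = list(box = box, original_shape = volume$shape))
}

#' Keep the middle fraction of axial slices
#'
#' The head and tail of the slice stack are mostly uninformative; this keeps
#' `k = round(fraction * Z)` consecutive slices centered in the stack, using
#' the lower start index when two centerings exist.
#'
#' @param volume A [multimodal_volume()].
#' @param labels Optional [label_volume()].
#' @param fraction Fraction of slices kept, in (0, 1]; default 0.7.
#' @return List with `volume`, `labels` (or `NULL`) and `z_range`, the kept
#'   half-open 0-based slice interval.
#' @export
select_middle_slab <- function(volume, labels = NULL, fraction = 0.7) {
  stopifnot(fraction > 0, fraction <= 1)
  Z <- volume$shape[3]
  k <- round(fraction * Z)
  if (k < 1) stop("slab would be empty: round(", fraction, " * ", Z, ") < 1")
  start <- floor((Z - k) / 2)            # 0-based, lower tie-break
  zr <- (start + 1L):(start + k)
  out_v <- multimodal_volume(volume$intensities[, , zr, , drop = FALSE],
                             spacing = volume$spacing,
                             orientation = volume$orientation)
  out_l <- NULL
  if (!is.null(labels))
    out_l <- label_volume(labels$labels[, , zr, drop = FALSE],
                          spacing = labels$spacing)
  list(volume = out_v, labels = out_l, z_range = c(start, start + k))
}

#' Sample a tumor-centered training patch
#'
#' Draws a patch center uniformly from tumor voxels (label > 0), then clamps
#' the patch box into bounds; axes smaller than the patch size are
#' zero-padded symmetrically (labels padded with background). Deterministic
#' under the current RNG state.
#'
#' @param volume A [multimodal_volume()].
#' @param labels A [label_volume()] with at least one tumor voxel.
#' @param size Integer length-3 patch size; default c(96, 96, 48).
#' @return List of class `patch` with `intensities` (x,y,z,4), `labels`
#'   (x,y,z), and `origin`, the 0-based offset of the patch into the
#'   (possibly padded) source.
#' @export
sample_patch <- function(volume, labels, size = c(96L, 96L, 48L)) {
  size <- as.integer(size)
  tumor <- which(labels$labels > 0L)
  if (!length(tumor)) stop("no tumor voxels to sample around")
  center_idx <- tumor[[sample.int(length(tumor), 1L)]]
  center <- arrayInd(center_idx, labels$shape)[1, ]

  x <- volume$intensities
  lab <- labels$labels
  shp <- labels$shape
  pad <- pmax(size - shp, 0L)
  lo_pad <- pad %/% 2L
  if (any(pad > 0L)) {
    newshp <- shp + pad
    xp <- array(0, dim = c(newshp, 4L))
    lp <- array(0L, dim = newshp)
    xr <- lo_pad[1] + seq_len(shp[1]); yr <- lo_pad[2] + seq_len(shp[2])
    zr <- lo_pad[3] + seq_len(shp[3])
    xp[xr, yr, zr, ] <- x; lp[xr, yr, zr] <- lab
    x <- xp; lab <- lp; shp <- newshp
    center <- center + lo_pad
  }
  # clamp the half-open box [origin, origin + size) into bounds (0-based)
  origin <- pmin(pmax(center - 1L - size %/% 2L, 0L), shp - size)
  xr <- origin[1] + seq_len(size[1]); yr <- origin[2] + seq_len(size[2])
  zr <- origin[3] + seq_len(size[3])
  structure(list(intensities = x[xr, yr, zr, , drop = FALSE],
                 labels = lab[xr, yr, zr, drop = FALSE],
                 origin = origin),
            class = "patch")
}
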
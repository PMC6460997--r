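#' Augmentation configuration
#'
#' Seeded, label-consistent augmentation applied to training patches in the
#' fixed order flip, rotate, gamma, elastic.
#'
#' @param flip_prob Per-axis flip probability, default 0.5.
#' @param rotation_range Axial-plane rotation range in degrees, default
#'   c(-15, 15).
#' @param gamma_range Gamma-correction exponent range, default c(0.4, 1.6).
#' @param elastic_alpha Displacement magnitude in voxels, default 10.
#' @param elastic_sigma Gaussian smoothing of the displacement field in
#'   voxels, default 4.
#' @param enable_flip,enable_rotate,enable_gamma,enable_elastic Stage flags.
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(flip_prob = 0.5, rotation_range = c(-15, 15),
                           gamma_range = c(0.4, 1.6),
                           elastic_alpha = 10, elastic_sigma = 4,
                           enable_flip = TRUE, enable_rotate = TRUE,
                           enable_gamma = TRUE, enable_elastic = TRUE) {
  stopifnot(flip_prob >= 0, flip_prob <= 1,
            length(rotation_range) == 2, rotation_range[1] <= rotation_range[2],
            length(gamma_range) == 2, gamma_range[1] <= gamma_range[2],
            gamma_range[1] > 0, elastic_alpha >= 0, elastic_sigma >= 0)
  if (elastic_alpha > 0 && elastic_sigma <= 0)
    stop("elastic_sigma must be > 0 when elastic_alpha > 0")
  structure(list(flip_prob = flip_prob, rotation_range = rotation_range,
                 gamma_range = gamma_range, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, enable_flip = enable_flip,
                 enable_rotate = enable_rotate, enable_gamma = enable_gamma,
                 enable_elastic = enable_elastic),
            class = "augment_config")
}

flip_axis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), length(dim(arr)))
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Random axis flips
#'
#' Each spatial axis is independently reversed with probability
#' `config$flip_prob`; intensities and labels are flipped identically, so
#' applying the same flip mask twice restores the input.
#'
#' @param patch A `patch` (see [sample_patch()]).
#' @param config An [augment_config()].
#' @return The flipped patch.
#' @export
random_flip <- function(patch, config = augment_config()) {
  do_flip <- stats::runif(3) < config$flip_prob
  for (ax in which(do_flip)) {
    patch$intensities <- flip_axis(patch$intensities, ax)
    patch$labels <- flip_axis(patch$labels, ax)
  }
  patch
}

# Bilinear (intensities) / nearest (labels) in-plane rotation about the
# z-axis; out-of-bounds voxels fill with 0.
rotate_patch <- function(patch, angle_deg) {
  if (angle_deg == 0) return(patch)
  d <- dim(patch$labels)
  X <- d[1]; Y <- d[2]; Z <- d[3]
  th <- angle_deg * pi / 180
  cx <- (X + 1) / 2; cy <- (Y + 1) / 2
  gx <- matrix(seq_len(X), X, Y) - cx
  gy <- matrix(seq_len(Y), X, Y, byrow = TRUE) - cy
  # inverse mapping: source = R(-theta) * target
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy

  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inb <- function(ix, iy) ix >= 1 & ix <= X & iy >= 1 & iy <= Y
  corners <- list(list(x0, y0, (1 - fx) * (1 - fy)),
                  list(x0 + 1, y0, fx * (1 - fy)),
                  list(x0, y0 + 1, (1 - fx) * fy),
                  list(x0 + 1, y0 + 1, fx * fy))
  new_int <- array(0, dim = dim(patch$intensities))
  for (k in seq_len(Z)) {
    for (c in 1:4) {
      plane <- patch$intensities[, , k, c]
      acc <- matrix(0, X, Y)
      for (co in corners) {
        ok <- inb(co[[1]], co[[2]])
        if (any(ok)) {
          v <- matrix(0, X, Y)
          v[ok] <- plane[cbind(co[[1]][ok], co[[2]][ok])]
          acc <- acc + co[[3]] * v
        }
      }
      new_int[, , k, c] <- acc
    }
  }
  # nearest neighbor for labels
  nx <- round(sx); ny <- round(sy)
  ok <- inb(nx, ny)
  new_lab <- array(0L, dim = d)
  for (k in seq_len(Z)) {
    plane <- patch$labels[, , k]
    out <- matrix(0L, X, Y)
    out[ok] <- plane[cbind(nx[ok], ny[ok])]
    new_lab[, , k] <- out
  }
  patch$intensities <- new_int
  patch$labels <- new_lab
  patch
}

#' Random in-plane rotation
#'
#' Draws an angle uniformly from `config$rotation_range` and rotates the
#' patch in the axial (x-y) plane about the z-axis: intensities with linear
#' interpolation, labels nearest-neighbor, out-of-bounds filled with 0.
#' Rotation is restricted to the axial plane because the through-plane
#' extent of brain volumes is much smaller than in-plane.
#'
#' @inheritParams random_flip
#' @return The rotated patch.
#' @export
random_rotate <- function(patch, config = augment_config()) {
  angle <- stats::runif(1, config$rotation_range[1], config$rotation_range[2])
  rotate_patch(patch, angle)
}

#' Random gamma correction
#'
#' Per channel, intensities are min-max rescaled to [0, 1], raised to a
#' gamma drawn uniformly from `config$gamma_range`, and rescaled back to the
#' original min/max (inputs are z-scored, so gamma is applied in min-max
#' space). Constant channels are left unchanged; labels untouched.
#'
#' @inheritParams random_flip
#' @return The gamma-corrected patch.
#' @export
random_gamma <- function(patch, config = augment_config()) {
  gamma <- stats::runif(1, config$gamma_range[1], config$gamma_range[2])
  for (c in 1:4) {
    ch <- patch$intensities[, , , c]
    lo <- min(ch); hi <- max(ch)
    if (hi > lo)
      patch$intensities[, , , c] <- ((ch - lo) / (hi - lo))^gamma * (hi - lo) + lo
  }
  patch
}

# Separable Gaussian smoothing by shift-and-add along each axis.
gaussian_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, dim = d)
    for (t in seq(-r, r)) {
      w <- k[t + r + 1]
      n <- d[ax]
      dst <- max(1, 1 - t):min(n, n - t)
      src <- dst + t
      idx_d <- rep(list(quote(expr = )), 3); idx_s <- idx_d
      idx_d[[ax]] <- dst; idx_s[[ax]] <- src
      piece <- do.call(`[`, c(list(arr), idx_s, list(drop = FALSE)))
      cur <- do.call(`[`, c(list(out), idx_d, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), idx_d, list(cur + w * piece)))
    }
    arr <- out
  }
  arr
}

#' Random elastic distortion
#'
#' A dense displacement field is built as iid Gaussian noise smoothed with a
#' Gaussian of width `elastic_sigma` and scaled by `elastic_alpha`;
#' intensities are warped with trilinear interpolation, labels with nearest
#' neighbor. The same RNG state yields the same field.
#'
#' @inheritParams random_flip
#' @return The distorted patch.
#' @export
elastic_distort <- function(patch, config = augment_config()) {
  if (config$elastic_alpha <= 0) return(patch)
  d <- dim(patch$labels)
  disp <- lapply(1:3, function(i) {
    f <- gaussian_smooth3(array(stats::rnorm(prod(d)), dim = d),
                          config$elastic_sigma)
    config$elastic_alpha * f
  })
  gx <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  gy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  gz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  sx <- gx + disp[[1]]; sy <- gy + disp[[2]]; sz <- gz + disp[[3]]

  clamp <- function(v, n) pmin(pmax(v, 1), n)
  # trilinear gather
  x0 <- clamp(floor(sx), d[1]); y0 <- clamp(floor(sy), d[2]); z0 <- clamp(floor(sz), d[3])
  x1 <- clamp(x0 + 1, d[1]); y1 <- clamp(y0 + 1, d[2]); z1 <- clamp(z0 + 1, d[3])
  fx <- clamp(sx, d[1]) - x0; fy <- clamp(sy, d[2]) - y0; fz <- clamp(sz, d[3]) - z0
  lin <- function(ix, iy, iz) ((iz - 1) * d[2] + (iy - 1)) * d[1] + ix
  new_int <- patch$intensities
  for (c in 1:4) {
    ch <- patch$intensities[, , , c]
    v <- (1 - fx) * (1 - fy) * (1 - fz) * ch[lin(x0, y0, z0)] +
      fx * (1 - fy) * (1 - fz) * ch[lin(x1, y0, z0)] +
      (1 - fx) * fy * (1 - fz) * ch[lin(x0, y1, z0)] +
      fx * fy * (1 - fz) * ch[lin(x1, y1, z0)] +
      (1 - fx) * (1 - fy) * fz * ch[lin(x0, y0, z1)] +
      fx * (1 - fy) * fz * ch[lin(x1, y0, z1)] +
      (1 - fx) * fy * fz * ch[lin(x0, y1, z1)] +
      fx * fy * fz * ch[lin(x1, y1, z1)]
    new_int[, , , c] <- array(v, dim = d)
  }
  nx <- clamp(round(sx), d[1]); ny <- clamp(round(sy), d[2]); nz <- clamp(round(sz), d[3])
  new_lab <- array(patch$labels[lin(nx, ny, nz)], dim = d)
  storage.mode(new_lab) <- "integer"
  patch$intensities <- new_int
  patch$labels <- new_lab
  patch
}

#' Full augmentation pipeline
#'
#' Applies flip, rotate, gamma and elastic distortion in that fixed order,
#' honoring the per-stage enable flags; deterministic given the RNG state.
#'
#' @inheritParams random_flip
#' @return The augmented patch; shape, channel count and label alphabet are
#'   unchanged.
#' @export
augment_pipeline <- function(patch, config = augment_config()) {
  if (config$enable_flip) patch <- random_flip(patch, config)
  if (config$enable_rotate) patch <- random_rotate(patch, config)
  if (config$enable_gamma) patch <- random_gamma(patch, config)
  if (config$enable_elastic) patch <- elastic_distort(patch, config)
  patch
}
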
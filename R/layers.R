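# Minimal trainable-layer engine for 3D segmentation networks.
#
# A "layer" is an environment with fields:
#   kind      character tag
#   params    named list of numeric arrays (trainable)
#   grads     named list, same shapes, accumulated by backward()
#   children  list of sub-layers (composites)
#   forward(x, train)  (X,Y,Z,C_in) array -> (X',Y',Z',C_out) array
#   backward(gy)       gradient wrt output -> gradient wrt input
# Activations are carried as 4-D channel-last arrays; internally most layers
# view them as (n_voxels x C) matrices, which makes every convolution a
# small set of BLAS products over precomputed voxel-index shifts.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- list()
  e$grads <- list()
  e$children <- list()
  class(e) <- c("ndn_layer", "environment")
  e
}

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

as_arr <- function(xm, spat, C) {
  dim(xm) <- c(spat, C)
  xm
}

# --- 3x3x3 (dilated) / 1x1x1 convolution --------------------------------

# Precompute, for one spatial shape and dilation, the source/destination
# linear voxel indices of every kernel tap.
conv_tap_indices <- function(spat, K, dil) {
  X <- spat[1]; Y <- spat[2]; Z <- spat[3]
  cen <- (K + 1L) %/% 2L
  taps <- list()
  t <- 0L
  for (c in 1:K) for (b in 1:K) for (a in 1:K) {
    t <- t + 1L
    off <- (c(a, b, c) - cen) * dil
    lo <- pmax(1L, 1L - off); hi <- pmin(spat, spat - off)
    if (any(hi < lo)) { taps[[t]] <- NULL; next }
    ox <- lo[1]:hi[1]; oy <- lo[2]:hi[2]; oz <- lo[3]:hi[3]
    # linear indices (column-major) of output region and shifted source region
    gx <- rep.int(ox, length(oy) * length(oz))
    gy <- rep.int(rep(oy, each = length(ox)), length(oz))
    gz <- rep(oz, each = length(ox) * length(oy))
    out_idx <- gx + (gy - 1L) * X + (gz - 1L) * X * Y
    src_idx <- (gx + off[1]) + (gy + off[2] - 1L) * X + (gz + off[3] - 1L) * X * Y
    taps[[t]] <- list(w = t, out = out_idx, src = src_idx)
  }
  Filter(Negate(is.null), taps)
}

# im2col memory cap: above this many column-matrix elements the tap-loop
# path is used instead (large inference-only inputs).
IM2COL_MAX <- 6e7

# Padded-grid gather indices: for each kernel tap, the linear index into the
# zero-padded grid of every output voxel's source, plus the indices of the
# interior (original grid) inside the padded one.
conv_pad_indices <- function(spat, K, dil) {
  m <- dil * (K - 1L) %/% 2L
  ps <- spat + 2L * m
  ox <- seq_len(spat[1]); oy <- seq_len(spat[2]); oz <- seq_len(spat[3])
  gx <- rep.int(ox, length(oy) * length(oz))
  gy <- rep.int(rep(oy, each = length(ox)), length(oz))
  gz <- rep(oz, each = length(ox) * length(oy))
  cen <- (K + 1L) %/% 2L
  taps <- vector("list", K^3)
  t <- 0L
  for (c in 1:K) for (b in 1:K) for (a in 1:K) {
    t <- t + 1L
    off <- (c(a, b, c) - cen) * dil + m     # shift into padded coords
    taps[[t]] <- (gx + off[1]) + (gy + off[2] - 1L) * ps[1] +
      (gz + off[3] - 1L) * ps[1] * ps[2]
  }
  inner <- (gx + m) + (gy + m - 1L) * ps[1] + (gz + m - 1L) * ps[1] * ps[2]
  list(taps = taps, inner = inner, padded = ps, m = m)
}

#' Create a 3D convolution layer
#'
#' Kernel-K (default 3) dilated convolution with symmetric zero padding, so
#' the spatial shape is preserved. Weights use He-normal initialization.
#' Moderate-size inputs run as one im2col GEMM over a zero-padded grid;
#' very large inputs fall back to a per-tap loop that avoids the column
#' matrix.
#'
#' @param c_in,c_out Channel counts.
#' @param kernel Odd kernel size (1 or 3 typical).
#' @param dilation Dilation rate.
#' @param weight_scale Multiplier on the He init sd.
#' @return A layer environment.
#' @keywords internal
layer_conv3 <- function(c_in, c_out, kernel = 3L, dilation = 1L,
                        weight_scale = 1) {
  l <- new_layer(sprintf("conv%dx%d d%d %d->%d", kernel, kernel, dilation,
                         c_in, c_out))
  K <- as.integer(kernel)
  fan_in <- K^3 * c_in
  l$params$W <- array(stats::rnorm(K^3 * c_in * c_out,
                                   sd = weight_scale * sqrt(2 / fan_in)),
                      dim = c(K, K, K, c_in, c_out))
  l$params$b <- numeric(c_out)
  l$grads$W <- array(0, dim = dim(l$params$W))
  l$grads$b <- numeric(c_out)
  l$K <- K; l$dil <- as.integer(dilation); l$c_in <- c_in; l$c_out <- c_out
  l$cache_spat <- NULL

  # weight matrix with rows ordered (tap-major, channel fastest) to match
  # the column layout of the im2col matrix
  w_mat <- function() {
    Wf <- l$params$W
    dim(Wf) <- c(K^3, c_in, c_out)
    Wm <- aperm(Wf, c(2, 1, 3))
    dim(Wm) <- c(c_in * K^3, c_out)
    Wm
  }

  l$forward <- function(x, train = FALSE) {
    spat <- dim(x)[1:3]
    n <- prod(spat)
    if (is.null(l$cache_spat) || !identical(l$cache_spat, spat)) {
      l$cache_spat <- spat
      l$use_col <- K > 1L && n * K^3 * c_in <= IM2COL_MAX
      if (K == 1L) l$idx <- NULL
      else if (l$use_col) l$idx <- conv_pad_indices(spat, K, l$dil)
      else l$taps <- conv_tap_indices(spat, K, l$dil)
    }
    xm <- as_mat(x)
    if (K == 1L) {
      if (train) l$x_mat <- xm
      Wm <- matrix(l$params$W, c_in, c_out)
      ym <- xm %*% Wm
      ym <- sweep(ym, 2, l$params$b, `+`)
      return(as_arr(ym, spat, c_out))
    }
    if (l$use_col) {
      ps <- l$idx$padded
      xpm <- matrix(0, prod(ps), c_in)
      xpm[l$idx$inner, ] <- xm
      col <- matrix(0, n, c_in * K^3)
      for (t in seq_len(K^3))
        col[, (t - 1L) * c_in + seq_len(c_in)] <- xpm[l$idx$taps[[t]], ]
      if (train) l$col <- col
      ym <- col %*% w_mat()
      ym <- sweep(ym, 2, l$params$b, `+`)
      return(as_arr(ym, spat, c_out))
    }
    # large-input path: per-tap shift-and-gemm, no column matrix
    if (train) l$x_mat <- xm
    ym <- matrix(l$params$b, n, c_out, byrow = TRUE)
    Wf <- l$params$W
    dim(Wf) <- c(K^3, c_in, c_out)
    for (tp in l$taps) {
      Wt <- matrix(Wf[tp$w, , ], c_in, c_out)
      ym[tp$out, ] <- ym[tp$out, ] + xm[tp$src, , drop = FALSE] %*% Wt
    }
    as_arr(ym, spat, c_out)
  }

  l$backward <- function(gy) {
    spat <- l$cache_spat
    gym <- as_mat(gy)
    l$grads$b <- l$grads$b + colSums(gym)
    if (K == 1L) {
      Wm <- matrix(l$params$W, c_in, c_out)
      gW <- crossprod(l$x_mat, gym)
      dim(gW) <- dim(l$params$W)
      l$grads$W <- l$grads$W + gW
      return(as_arr(tcrossprod(gym, Wm), spat, c_in))
    }
    if (l$use_col) {
      Wm <- w_mat()
      gWm <- crossprod(l$col, gym)                 # (c_in*K^3) x c_out
      dim(gWm) <- c(c_in, K^3, c_out)
      gWm <- aperm(gWm, c(2, 1, 3))
      dim(gWm) <- dim(l$params$W)
      l$grads$W <- l$grads$W + gWm
      gcol <- tcrossprod(gym, Wm)                  # n x (c_in*K^3)
      ps <- l$idx$padded
      gxpm <- matrix(0, prod(ps), c_in)
      for (t in seq_len(K^3)) {
        blk <- gcol[, (t - 1L) * c_in + seq_len(c_in), drop = FALSE]
        ti <- l$idx$taps[[t]]
        gxpm[ti, ] <- gxpm[ti, ] + blk
      }
      return(as_arr(gxpm[l$idx$inner, , drop = FALSE], spat, c_in))
    }
    gxm <- matrix(0, nrow(gym), c_in)
    Wf <- l$params$W
    dim(Wf) <- c(K^3, c_in, c_out)
    gWf <- l$grads$W
    dim(gWf) <- c(K^3, c_in, c_out)
    for (tp in l$taps) {
      gsub <- gym[tp$out, , drop = FALSE]
      xsub <- l$x_mat[tp$src, , drop = FALSE]
      gWf[tp$w, , ] <- gWf[tp$w, , ] + crossprod(xsub, gsub)
      Wt <- matrix(Wf[tp$w, , ], c_in, c_out)
      gxm[tp$src, ] <- gxm[tp$src, ] + tcrossprod(gsub, Wt)
    }
    dim(gWf) <- c(K, K, K, c_in, c_out)
    l$grads$W <- gWf
    as_arr(gxm, spat, c_in)
  }
  l
}

# --- batch normalization -------------------------------------------------

# Normalization statistics: training always uses the current sample (with
# one-patch batches this is instance-normalization semantics). Inference
# defaults to the same per-input statistics ("input" mode), which avoids
# the distribution gap between tumor-centered training patches and whole
# volumes; "running" mode (exponential averages, momentum 0.9) is kept for
# analytic uses such as impulse-response measurement.
layer_bn <- function(C, eps = 1e-5, momentum = 0.9) {
  l <- new_layer(sprintf("bn %d", C))
  l$params$gamma <- rep(1, C)
  l$params$beta <- rep(0, C)
  l$grads$gamma <- numeric(C)
  l$grads$beta <- numeric(C)
  l$running_mean <- rep(0, C)
  l$running_var <- rep(1, C)
  l$eps <- eps; l$momentum <- momentum; l$C <- C
  l$stats_mode <- "input"

  l$forward <- function(x, train = FALSE) {
    spat <- dim(x)[1:3]
    xm <- as_mat(x)
    n <- nrow(xm)
    if (train || l$stats_mode == "input") {
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc * xc)
      inv_std <- 1 / sqrt(v + l$eps)
      xhat <- sweep(xc, 2, inv_std, `*`)
      if (train) {
        l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * mu
        l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * v
        l$xhat <- xhat; l$inv_std <- inv_std; l$n <- n
      }
      ym <- sweep(sweep(xhat, 2, l$params$gamma, `*`), 2, l$params$beta, `+`)
    } else {
      inv_std <- 1 / sqrt(l$running_var + l$eps)
      ym <- sweep(sweep(sweep(xm, 2, l$running_mean), 2,
                        l$params$gamma * inv_std, `*`),
                  2, l$params$beta, `+`)
    }
    as_arr(ym, spat, l$C)
  }

  l$backward <- function(gy) {
    spat <- dim(gy)[1:3]
    gym <- as_mat(gy)
    n <- l$n
    sum_gy <- colSums(gym)
    sum_gy_xhat <- colSums(gym * l$xhat)
    l$grads$gamma <- l$grads$gamma + sum_gy_xhat
    l$grads$beta <- l$grads$beta + sum_gy
    coef <- l$params$gamma * l$inv_std / n
    gxm <- sweep(n * gym, 2, sum_gy) - sweep(l$xhat, 2, sum_gy_xhat, `*`)
    gxm <- sweep(gxm, 2, coef, `*`)
    as_arr(gxm, spat, l$C)
  }
  l
}

# --- element-wise activations -------------------------------------------

layer_relu <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, train = FALSE) {
    y <- x * (x > 0)
    if (train) l$mask <- x > 0
    y
  }
  l$backward <- function(gy) gy * l$mask
  l
}

# --- 2x2x2 max pooling ---------------------------------------------------

pool_corner_indices <- function(spat) {
  X <- spat[1]; Y <- spat[2]; Z <- spat[3]
  ox <- seq(1L, X, by = 2L); oy <- seq(1L, Y, by = 2L); oz <- seq(1L, Z, by = 2L)
  gx <- rep.int(ox, length(oy) * length(oz))
  gy <- rep.int(rep(oy, each = length(ox)), length(oz))
  gz <- rep(oz, each = length(ox) * length(oy))
  idx <- list()
  t <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    t <- t + 1L
    idx[[t]] <- (gx + dx) + (gy + dy - 1L) * X + (gz + dz - 1L) * X * Y
  }
  idx
}

layer_maxpool <- function() {
  l <- new_layer("maxpool2")
  l$cache_spat <- NULL
  l$forward <- function(x, train = FALSE) {
    spat <- dim(x)[1:3]; C <- dim(x)[4]
    if (any(spat %% 2L != 0L))
      stop("maxpool requires even spatial axes, got ",
           paste(spat, collapse = "x"))
    if (is.null(l$cache_spat) || !identical(l$cache_spat, spat)) {
      l$corners <- pool_corner_indices(spat)
      l$cache_spat <- spat
    }
    xm <- as_mat(x)
    best <- xm[l$corners[[1]], , drop = FALSE]
    arg <- matrix(1L, nrow(best), ncol(best))
    for (t in 2:8) {
      cand <- xm[l$corners[[t]], , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      arg[upd] <- t
    }
    if (train) { l$arg <- arg; l$in_spat <- spat; l$C <- C }
    as_arr(best, spat %/% 2L, C)
  }
  l$backward <- function(gy) {
    gym <- as_mat(gy)
    n_in <- prod(l$in_spat)
    gxm <- matrix(0, n_in, l$C)
    for (t in 1:8) {
      sel <- l$arg == t
      if (any(sel)) {
        rows <- l$corners[[t]][row(sel)[sel]]
        cols <- col(sel)[sel]
        gxm[cbind(rows, cols)] <- gxm[cbind(rows, cols)] + gym[sel]
      }
    }
    as_arr(gxm, l$in_spat, l$C)
  }
  l
}

# --- nearest-neighbor 2x upsampling -------------------------------------

layer_upsample <- function() {
  l <- new_layer("upsample2")
  l$cache_spat <- NULL
  l$forward <- function(x, train = FALSE) {
    spat <- dim(x)[1:3]; C <- dim(x)[4]
    if (is.null(l$cache_spat) || !identical(l$cache_spat, spat)) {
      X <- spat[1]; Y <- spat[2]; Z <- spat[3]
      sx <- rep(seq_len(X), each = 2L); sy <- rep(seq_len(Y), each = 2L)
      sz <- rep(seq_len(Z), each = 2L)
      gx <- rep.int(sx, length(sy) * length(sz))
      gy <- rep.int(rep(sy, each = length(sx)), length(sz))
      gz <- rep(sz, each = length(sx) * length(sy))
      l$src <- gx + (gy - 1L) * X + (gz - 1L) * X * Y
      l$cache_spat <- spat
    }
    xm <- as_mat(x)
    if (train) { l$in_spat <- spat; l$C <- C }
    as_arr(xm[l$src, , drop = FALSE], spat * 2L, C)
  }
  l$backward <- function(gy) {
    gym <- as_mat(gy)
    gxm <- rowsum(gym, group = l$src)      # groups 1..n_in, sorted
    as_arr(gxm, l$in_spat, l$C)
  }
  l
}

# --- dense (for the SE excitation) --------------------------------------

layer_dense <- function(c_in, c_out, activation = c("relu", "sigmoid")) {
  activation <- match.arg(activation)
  l <- new_layer(sprintf("dense %d->%d %s", c_in, c_out, activation))
  l$params$W <- matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / (c_in + c_out))),
                       c_in, c_out)
  l$params$b <- numeric(c_out)
  l$grads$W <- matrix(0, c_in, c_out)
  l$grads$b <- numeric(c_out)
  l$activation <- activation
  l$forward <- function(x, train = FALSE) {      # x: plain numeric vector
    u <- drop(x %*% l$params$W) + l$params$b
    y <- if (activation == "relu") pmax(u, 0) else 1 / (1 + exp(-u))
    if (train) { l$x <- x; l$y <- y; l$u <- u }
    y
  }
  l$backward <- function(gy) {
    gu <- if (activation == "relu") gy * (l$u > 0) else gy * l$y * (1 - l$y)
    l$grads$W <- l$grads$W + outer(l$x, gu)
    l$grads$b <- l$grads$b + gu
    drop(l$params$W %*% gu)
  }
  l
}

# --- generic traversal ---------------------------------------------------

walk_layers <- function(layer, fn) {
  fn(layer)
  for (ch in layer$children) walk_layers(ch, fn)
  invisible(NULL)
}

#' Count trainable parameters of a network or block
#'
#' @param layer A layer or composite block built by the `build_*` functions.
#' @return Integer total of trainable scalars.
#' @export
count_parameters <- function(layer) {
  total <- 0L
  walk_layers(layer, function(l) {
    for (p in l$params) total <<- total + length(p)
  })
  total
}

# Zero accumulated gradients everywhere.
zero_grads <- function(layer) {
  walk_layers(layer, function(l) {
    for (nm in names(l$grads)) l$grads[[nm]][] <- 0
  })
}

# Set every conv/dense weight and bias to a constant (testing aid: impulse
# response measurements use all-ones weights).
set_constant_weights <- function(layer, value) {
  walk_layers(layer, function(l) {
    if (!is.null(l$params$W)) l$params$W[] <- value
    if (!is.null(l$params$b)) l$params$b[] <- 0
  })
  invisible(layer)
}

# Drop transient per-layer caches (im2col matrices, activations, gather
# indices). They rebuild on demand; clearing them keeps long-lived trained
# models small.
clear_caches <- function(layer) {
  fields <- c("col", "x_mat", "xhat", "inv_std", "mask", "arg", "corners",
              "src", "taps", "idx", "xm", "w", "x", "y", "u", "q", "in_spat")
  walk_layers(layer, function(l) {
    present <- intersect(fields, names(l))
    if (length(present)) rm(list = present, envir = l)
    if (!is.null(l$cache_spat)) l$cache_spat <- NULL
  })
  if (!is.null(layer$gskips)) layer$gskips <- list()
  invisible(layer)
}

# Flat list of (layer, param-name) pairs for the optimizer.
parameter_refs <- function(layer) {
  refs <- list()
  walk_layers(layer, function(l) {
    for (nm in names(l$params))
      refs[[length(refs) + 1L]] <<- list(layer = l, name = nm)
  })
  refs
}

# Deep copy of all parameter values (checkpointing).
get_state <- function(layer) {
  st <- list()
  i <- 0L
  walk_layers(layer, function(l) {
    i <<- i + 1L
    st[[i]] <<- list(params = l$params, running_mean = l$running_mean,
                     running_var = l$running_var)
  })
  st
}

set_state <- function(layer, st) {
  i <- 0L
  walk_layers(layer, function(l) {
    i <<- i + 1L
    l$params <- st[[i]]$params
    if (!is.null(st[[i]]$running_mean)) l$running_mean <- st[[i]]$running_mean
    if (!is.null(st[[i]]$running_var)) l$running_var <- st[[i]]$running_var
  })
  invisible(layer)
}
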
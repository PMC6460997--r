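# Composite blocks: plain sequences, residual blocks, SE blocks, RnD blocks
# and the full encoder-decoder network. Each composite follows the same
# layer contract as the primitives in layers.R.

seq_block <- function(layers, kind = "seq") {
  l <- new_layer(kind)
  l$children <- layers
  l$forward <- function(x, train = FALSE) {
    for (ch in l$children) x <- ch$forward(x, train)
    x
  }
  l$backward <- function(gy) {
    for (ch in rev(l$children)) gy <- ch$backward(gy)
    gy
  }
  l
}

#' Build a residual block
#'
#' Residual path = conv3-BN-ReLU-conv3-BN-ReLU; output = path(x) + shortcut,
#' where the shortcut is the identity when `c_in == c_out` and a 1x1x1
#' projection otherwise. Spatial shape is preserved.
#'
#' @param c_in,c_out Channel counts.
#' @return A layer environment (callable via `$forward(x, train)`).
#' @export
build_residual_block <- function(c_in, c_out) {
  l <- new_layer(sprintf("residual %d->%d", c_in, c_out))
  path <- seq_block(list(layer_conv3(c_in, c_out), layer_bn(c_out), layer_relu(),
                         layer_conv3(c_out, c_out), layer_bn(c_out), layer_relu()),
                    "res_path")
  proj <- if (c_in != c_out) layer_conv3(c_in, c_out, kernel = 1L) else NULL
  l$children <- c(list(path), if (!is.null(proj)) list(proj))
  l$forward <- function(x, train = FALSE) {
    p <- path$forward(x, train)
    s <- if (is.null(proj)) x else proj$forward(x, train)
    p + s
  }
  l$backward <- function(gy) {
    gx <- path$backward(gy)
    gs <- if (is.null(proj)) gy else proj$backward(gy)
    gx + gs
  }
  l
}

#' Build a squeeze-and-excitation block
#'
#' Squeeze: spatial global average per channel. Excitation: fully connected
#' C -> ceiling(C / reduction) with ReLU, then back to C with sigmoid. The
#' resulting per-channel weights are reshaped to (1, 1, 1, C) and multiplied
#' onto the input, so the output shape equals the input shape.
#'
#' @param C Channel count.
#' @param reduction Bottleneck reduction ratio (floored at 1), default 16.
#' @return A layer environment.
#' @export
build_se_block <- function(C, reduction = 16) {
  l <- new_layer(sprintf("se %d r%d", C, reduction))
  cr <- max(1L, as.integer(ceiling(C / reduction)))
  fc1 <- layer_dense(C, cr, "relu")
  fc2 <- layer_dense(cr, C, "sigmoid")
  l$children <- list(fc1, fc2)
  l$forward <- function(x, train = FALSE) {
    spat <- dim(x)[1:3]
    xm <- as_mat(x)
    s <- colMeans(xm)
    w <- fc2$forward(fc1$forward(s, train), train)
    ym <- sweep(xm, 2, w, `*`)
    if (train) { l$xm <- xm; l$w <- w; l$spat <- spat }
    as_arr(ym, spat, C)
  }
  l$backward <- function(gy) {
    gym <- as_mat(gy)
    gw <- colSums(gym * l$xm)
    gxm <- sweep(gym, 2, l$w, `*`)
    gs <- fc1$backward(fc2$backward(gw))
    n <- nrow(gxm)
    gxm <- gxm + matrix(gs / n, n, C, byrow = TRUE)
    as_arr(gxm, l$spat, C)
  }
  l
}

#' Build a residual block nested with dilations (RnD)
#'
#' Three serial dilated convolutions at the scheme's rates (kernel 3), each
#' followed by batch normalization and ReLU, with a residual connection
#' across the triple (1x1x1 projection on channel mismatch). The scheme must
#' pass the hybrid-dilated-convolution rules unless `override = TRUE`.
#'
#' @param c_in,c_out Channel counts.
#' @param scheme A [dilation_scheme()], default rates (1, 2, 5).
#' @param override Skip HDC validation (not recommended).
#' @return A layer environment.
#' @export
build_rnd_block <- function(c_in, c_out, scheme = dilation_scheme(),
                            override = FALSE) {
  report <- validate_hdc(scheme)
  if (!report$valid && !override) {
    msg <- paste0("dilation scheme (", paste(scheme$rates, collapse = ", "),
                  ") fails HDC validation: coprime_ok=", report$coprime_ok,
                  ", distance_ok=", report$distance_ok)
    cond <- simpleError(msg)
    cond$hdc_report <- report
    stop(cond)
  }
  l <- new_layer(sprintf("rnd %d->%d (%s)", c_in, c_out,
                         paste(scheme$rates, collapse = ",")))
  chans <- c(c_in, rep(c_out, length(scheme$rates)))
  convs <- list()
  for (i in seq_along(scheme$rates)) {
    convs <- c(convs, list(layer_conv3(chans[i], chans[i + 1],
                                       kernel = scheme$kernel,
                                       dilation = scheme$rates[i]),
                           layer_bn(chans[i + 1]), layer_relu()))
  }
  path <- seq_block(convs, "rnd_path")
  proj <- if (c_in != c_out) layer_conv3(c_in, c_out, kernel = 1L) else NULL
  l$children <- c(list(path), if (!is.null(proj)) list(proj))
  l$hdc_report <- report
  l$forward <- function(x, train = FALSE) {
    p <- path$forward(x, train)
    s <- if (is.null(proj)) x else proj$forward(x, train)
    p + s
  }
  l$backward <- function(gy) {
    gx <- path$backward(gy)
    gs <- if (is.null(proj)) gy else proj$backward(gy)
    gx + gs
  }
  l
}

# Nearest-neighbor 2x upsampling followed by conv3-BN-ReLU.
build_upconv <- function(c_in, c_out) {
  seq_block(list(layer_upsample(), layer_conv3(c_in, c_out), layer_bn(c_out),
                 layer_relu()),
            sprintf("upconv %d->%d", c_in, c_out))
}

#' Network specification
#'
#' Declarative description of the nested dilation network from which
#' [build_ndn()] assembles a model: 4 input channels, a configurable class
#' count, three max-pooling levels whose filter width doubles per level,
#' RnD blocks on the first two encoder levels and residual blocks elsewhere,
#' an SE block after every stage, concatenation skip fusion and
#' nearest-neighbor + conv upsampling.
#'
#' @param classes Output classes per softmax head (4 for the full problem,
#'   2 for a cascade stage).
#' @param base_filters Filter count at the first level, doubled per level;
#'   default 16.
#' @param in_channels Input channels, default 4 (the four modalities).
#' @param depth Number of pooling levels, default 3 (input axes must be
#'   divisible by 2^depth).
#' @param se_reduction SE bottleneck ratio, default 16 (floored at 1).
#' @param scheme [dilation_scheme()] for the RnD blocks.
#' @param decoder_blocks Residual blocks per decoder stack, default 1.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(classes = 4L, base_filters = 16L, in_channels = 4L,
                         depth = 3L, se_reduction = 16, scheme = dilation_scheme(),
                         decoder_blocks = 1L) {
  stopifnot(classes >= 2, base_filters >= 1, depth >= 1, decoder_blocks >= 1)
  structure(list(classes = as.integer(classes),
                 base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels),
                 depth = as.integer(depth), se_reduction = se_reduction,
                 scheme = scheme, decoder_blocks = as.integer(decoder_blocks)),
            class = "network_spec")
}

#' Build the nested dilation network
#'
#' Encoder levels 1-2 use RnD blocks, level 3 a residual block, each
#' followed by an SE block and 2x max pooling; the bottleneck is a residual
#' block plus SE; each decoder level upsamples, concatenates the encoder
#' skip, and applies residual + SE; a final 1x1x1 convolution produces class
#' logits and a softmax head per-voxel probabilities. An input of shape
#' (X, Y, Z, 4) yields (X, Y, Z, classes); all axes must be divisible by
#' 2^depth.
#'
#' @param spec A [network_spec()].
#' @return A layer environment; `$forward(x, train)` returns per-voxel class
#'   probabilities, `$backward(gq)` expects the gradient with respect to
#'   those probabilities.
#' @export
build_ndn <- function(spec = network_spec()) {
  F <- spec$base_filters
  filt <- F * 2L^(0:spec$depth)           # per level, doubling
  red <- spec$se_reduction
  enc_blocks <- list(); enc_se <- list(); pools <- list()
  c_prev <- spec$in_channels
  for (lev in seq_len(spec$depth)) {
    blk <- if (lev <= 2L)
      build_rnd_block(c_prev, filt[lev], spec$scheme)
    else
      build_residual_block(c_prev, filt[lev])
    enc_blocks[[lev]] <- blk
    enc_se[[lev]] <- build_se_block(filt[lev], red)
    pools[[lev]] <- layer_maxpool()
    c_prev <- filt[lev]
  }
  bottleneck <- build_residual_block(c_prev, filt[spec$depth + 1L])
  bottleneck_se <- build_se_block(filt[spec$depth + 1L], red)

  upconvs <- list(); dec_blocks <- list(); dec_se <- list()
  c_prev <- filt[spec$depth + 1L]
  for (lev in rev(seq_len(spec$depth))) {
    upconvs[[lev]] <- build_upconv(c_prev, filt[lev])
    stack <- list(build_residual_block(filt[lev] * 2L, filt[lev]))
    if (spec$decoder_blocks > 1L)
      for (i in 2:spec$decoder_blocks)
        stack <- c(stack, list(build_residual_block(filt[lev], filt[lev])))
    dec_blocks[[lev]] <- seq_block(stack, sprintf("dec_stack L%d", lev))
    dec_se[[lev]] <- build_se_block(filt[lev], red)
    c_prev <- filt[lev]
  }
  # small head init keeps the initial softmax near-uniform
  head_conv <- layer_conv3(filt[1], spec$classes, kernel = 1L,
                           weight_scale = 0.1)

  net <- new_layer(sprintf("ndn f%d c%d", F, spec$classes))
  net$spec <- spec
  net$children <- c(enc_blocks, enc_se, pools,
                    list(bottleneck, bottleneck_se),
                    upconvs, dec_blocks, dec_se, list(head_conv))

  net$forward <- function(x, train = FALSE) {
    spat <- dim(x)[1:3]
    div <- 2L^spec$depth
    for (ax in 1:3)
      if (spat[ax] %% div != 0L)
        stop("input axis ", c("x", "y", "z")[ax], " (", spat[ax],
             ") not divisible by ", div)
    skips <- vector("list", spec$depth)
    for (lev in seq_len(spec$depth)) {
      x <- enc_se[[lev]]$forward(enc_blocks[[lev]]$forward(x, train), train)
      skips[[lev]] <- x
      x <- pools[[lev]]$forward(x, train)
    }
    x <- bottleneck_se$forward(bottleneck$forward(x, train), train)
    net$bottleneck_shape <- dim(x)[1:3]
    for (lev in rev(seq_len(spec$depth))) {
      x <- upconvs[[lev]]$forward(x, train)
      x <- abind4(x, skips[[lev]])
      x <- dec_se[[lev]]$forward(dec_blocks[[lev]]$forward(x, train), train)
    }
    z <- head_conv$forward(x, train)
    q <- softmax4(z)
    if (train) net$q <- q
    q
  }

  net$backward <- function(gq) {
    q <- net$q
    spat <- dim(q)[1:3]; K <- dim(q)[4]
    qm <- as_mat(q); gqm <- as_mat(gq)
    s <- rowSums(gqm * qm)
    gz <- as_arr(qm * (gqm - s), spat, K)
    g <- head_conv$backward(gz)
    for (lev in seq_len(spec$depth)) {
      g <- dec_blocks[[lev]]$backward(dec_se[[lev]]$backward(g))
      ch <- dim(g)[4] %/% 2L
      gskip <- g[, , , (ch + 1L):(2L * ch), drop = FALSE]
      g <- upconvs[[lev]]$backward(g[, , , 1:ch, drop = FALSE])
      net$gskips[[lev]] <- gskip
    }
    g <- bottleneck$backward(bottleneck_se$backward(g))
    for (lev in rev(seq_len(spec$depth))) {
      g <- pools[[lev]]$backward(g)
      g <- g + net$gskips[[lev]]
      g <- enc_blocks[[lev]]$backward(enc_se[[lev]]$backward(g))
    }
    g
  }
  net$gskips <- vector("list", spec$depth)
  net
}

# Channel-axis concatenation of two (X,Y,Z,C) arrays.
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Numerically stable per-voxel softmax along the channel axis.
softmax4 <- function(z) {
  spat <- dim(z)[1:3]; K <- dim(z)[4]
  zm <- as_mat(z)
  zm <- zm - apply(zm, 1, max)
  e <- exp(zm)
  as_arr(e / rowSums(e), spat, K)
}

#' Measure the impulse-response support of a block
#'
#' Runs an inference-mode forward pass of a block with all conv/dense
#' weights set to one on a centered unit impulse and reports the nonzero
#' extent per axis -- an empirical check of [receptive_field()].
#'
#' @param block A layer environment (shape-preserving).
#' @param shape Odd spatial shape large enough to contain the support.
#' @param c_in Input channel count the block expects.
#' @return Integer length-3 vector of nonzero spans.
#' @export
impulse_response_support <- function(block, shape = c(25L, 25L, 25L),
                                     c_in = 1L) {
  set_constant_weights(block, 1)
  # fresh running statistics (mean 0, var 1) make normalization an identity,
  # so the measured support reflects the convolutions alone
  walk_layers(block, function(l) {
    if (!is.null(l$stats_mode)) l$stats_mode <- "running"
  })
  x <- array(0, dim = c(shape, c_in))
  cen <- (shape + 1L) %/% 2L
  x[cen[1], cen[2], cen[3], ] <- 1
  y <- block$forward(x, train = FALSE)
  nz <- apply(abs(y) > 1e-9, 1:3, any)
  vapply(1:3, function(ax) {
    hit <- which(apply(nz, ax, any))
    if (!length(hit)) 0L else as.integer(max(hit) - min(hit) + 1L)
  }, integer(1))
}
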
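# Shared fixtures: tiny volumes, patches and scalar-loop loss oracles.
# Everything is generated in code; no stored data.

tiny_volume <- function(shape = c(8L, 8L, 4L), seed = 1) {
  set.seed(seed)
  multimodal_volume(array(rnorm(prod(shape) * 4), dim = c(shape, 4L)))
}

tiny_labels <- function(shape = c(8L, 8L, 4L), seed = 2) {
  set.seed(seed)
  label_volume(array(sample(0:3, prod(shape), replace = TRUE), dim = shape))
}

# A patch with a centered bright sphere, convenient for geometric checks.
sphere_patch <- function(shape = c(24L, 24L, 12L), radius = 6) {
  cen <- (shape + 1) / 2
  gx <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape)
  gy <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape)
  gz <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  inside <- (gx - cen[1])^2 + (gy - cen[2])^2 + ((gz - cen[3]) * 2)^2 <= radius^2
  lab <- array(0L, dim = shape)
  lab[inside] <- 1L
  intens <- array(0, dim = c(shape, 4L))
  for (c in 1:4) intens[, , , c] <- as.numeric(inside) * c + 0.1
  structure(list(intensities = intens, labels = lab,
                 origin = c(0L, 0L, 0L)),
            class = "patch")
}

random_field <- function(n_vox = 64L, classes = 4L, seed = 1) {
  set.seed(seed)
  d <- c(n_vox, 1L, 1L)
  z <- matrix(rnorm(n_vox * classes), n_vox, classes)
  q <- exp(z) / rowSums(exp(z))
  p_lab <- sample.int(classes, n_vox, replace = TRUE)
  p <- matrix(0, n_vox, classes)
  p[cbind(seq_len(n_vox), p_lab)] <- 1
  probability_field(array(q, dim = c(d, classes)), array(p, dim = c(d, classes)))
}

# Scalar-loop reference implementations of the four losses (independent of
# the vectorized code paths).
oracle_ce <- function(field, weights = NULL) {
  q <- field$q; p <- field$p
  d <- dim(q)
  acc <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    for (cl in seq_len(d[4])) {
      qi <- min(max(q[i, j, k, cl], 1e-7), 1)
      w <- if (is.null(weights)) 1 else weights[cl]
      acc <- acc + w * p[i, j, k, cl] * log(qi)
    }
  -acc / prod(d[1:3])
}

oracle_focal <- function(field, gamma = 2) {
  q <- field$q; p <- field$p
  d <- dim(q)
  num <- 0; den <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    for (cl in seq_len(d[4])) {
      qi <- min(max(q[i, j, k, cl], 1e-7), 1)
      num <- num + p[i, j, k, cl] * (1 - qi)^gamma * log(qi)
      den <- den + p[i, j, k, cl]
    }
  -num / den
}

oracle_dice_loss <- function(field, epsilon = 1e-5, as_printed = FALSE) {
  q <- field$q; p <- field$p
  d <- dim(q)
  s <- 0; sp <- 0; sq <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    for (cl in seq_len(d[4])) {
      s <- s + p[i, j, k, cl] * q[i, j, k, cl]
      sp <- sp + p[i, j, k, cl]
      sq <- sq + q[i, j, k, cl]
    }
  frac <- 2 * s / (sp + sq + epsilon)
  if (as_printed) frac <- frac / prod(d[1:3])
  1 - frac
}

# Naive flood-fill component labeling (recursion-free DFS), the oracle for
# connected_components on small grids.
oracle_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(connectivity),
                      "6" = manh == 1, "18" = manh <= 2,
                      "26" = rep(TRUE, nrow(offs))), ]
  labels <- array(0L, dim = d)
  comp <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    labels[start] <- comp
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      co <- arrayInd(v, d)[1, ]
      for (o in seq_len(nrow(offs))) {
        nb <- co + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[li] && labels[li] == 0L) {
          labels[li] <- comp
          stack <- c(stack, li)
        }
      }
    }
  }
  labels
}
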
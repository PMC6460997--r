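# Connected-component refinement: brain tumors in this dataset form a
# single connected domain, so isolated clusters are artifacts, and tiny
# "enhancing" clusters in benign cases are false positives.

connectivity_offsets <- function(connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = rep(TRUE, nrow(offs)),
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(offs[keep, ])
}

#' Label connected components of a 3D binary mask
#'
#' Standard component labeling under a 6-, 18- or 26-neighborhood,
#' implemented as vectorized breadth-first flood fill. Component ids are
#' contiguous from 1 in discovery (linear-index) order.
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List with `labels` (integer array, 0 = background), `sizes`
#'   (voxel count per component id) and `connectivity`.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  offs <- connectivity_offsets(connectivity)
  X <- d[1]; Y <- d[2]; Z <- d[3]
  lin_off <- offs[, 1] + offs[, 2] * X + offs[, 3] * X * Y

  labels <- array(0L, dim = d)
  fg <- which(mask)
  if (!length(fg)) {
    return(list(labels = labels, sizes = integer(0),
                connectivity = as.integer(connectivity)))
  }
  in_fg <- array(FALSE, dim = d)
  in_fg[fg] <- TRUE
  co <- arrayInd(fg, d)
  cx <- integer(prod(d)); cy <- cx; cz <- cx
  cx[fg] <- co[, 1]; cy[fg] <- co[, 2]; cz[fg] <- co[, 3]

  comp <- 0L
  sizes <- integer(0)
  remaining <- in_fg
  seeds <- fg              # ascending linear order = discovery order
  for (s in seeds) {
    if (!remaining[s]) next
    comp <- comp + 1L
    frontier <- s
    remaining[s] <- FALSE
    labels[s] <- comp
    n_comp <- 1L
    while (length(frontier)) {
      # all neighbors of the frontier, with boundary filtering
      nb <- rep(frontier, each = nrow(offs)) + rep(lin_off, length(frontier))
      bx <- rep(cx[frontier], each = nrow(offs)) + offs[, 1]
      by <- rep(cy[frontier], each = nrow(offs)) + offs[, 2]
      bz <- rep(cz[frontier], each = nrow(offs)) + offs[, 3]
      ok <- bx >= 1 & bx <= X & by >= 1 & by <= Y & bz >= 1 & bz <= Z
      nb <- unique(nb[ok])
      nb <- nb[remaining[nb]]
      if (length(nb)) {
        labels[nb] <- comp
        remaining[nb] <- FALSE
        n_comp <- n_comp + length(nb)
      }
      frontier <- nb
    }
    sizes[comp] <- n_comp
  }
  list(labels = labels, sizes = sizes, connectivity = as.integer(connectivity))
}

#' Keep only the largest whole-tumor component
#'
#' Components are computed on the whole-tumor mask (label > 0); every voxel
#' outside the largest component is reset to background. Ties break toward
#' the lowest component id (first discovered).
#'
#' @param labels A [label_volume()].
#' @param connectivity Neighborhood, default 26.
#' @return A [label_volume()].
#' @export
keep_largest_component <- function(labels, connectivity = 26L) {
  grid <- labels$labels
  cc <- connected_components(grid > 0L, connectivity)
  if (length(cc$sizes) <= 1L) return(labels)
  keep <- which.max(cc$sizes)         # first maximum = lowest id
  grid[cc$labels != keep] <- 0L
  label_volume(grid, spacing = labels$spacing)
}

#' Remove small enhancing clusters
#'
#' Connected components of the enhancing (label 3) mask smaller than
#' `min_volume` voxels are relabeled to non-enhancing (label 2) by default,
#' preserving the whole-tumor mask; `mode = "delete"` resets them to
#' background instead.
#'
#' @param labels A [label_volume()].
#' @param min_volume Minimum cluster size in voxels; clusters strictly
#'   smaller are removed. Default 200 (a pipeline choice, exposed in
#'   configuration).
#' @param mode `"relabel"` (to non-enhancing) or `"delete"`.
#' @param connectivity Neighborhood, default 26.
#' @return A [label_volume()].
#' @export
remove_small_enhancing <- function(labels, min_volume = 200L,
                                   mode = c("relabel", "delete"),
                                   connectivity = 26L) {
  mode <- match.arg(mode)
  stopifnot(min_volume >= 0)
  grid <- labels$labels
  cc <- connected_components(grid == 3L, connectivity)
  small <- which(cc$sizes < min_volume)
  if (length(small)) {
    repl <- if (mode == "relabel") 2L else 0L
    grid[cc$labels %in% small] <- repl
  }
  label_volume(grid, spacing = labels$spacing)
}

#' Full post-processing pipeline
#'
#' Applies [keep_largest_component()] then [remove_small_enhancing()];
#' deterministic and idempotent.
#'
#' @param labels A [label_volume()].
#' @param min_volume,mode,connectivity See the two steps.
#' @return A [label_volume()].
#' @export
postprocess_pipeline <- function(labels, min_volume = 200L,
                                 mode = c("relabel", "delete"),
                                 connectivity = 26L) {
  mode <- match.arg(mode)
  out <- keep_largest_component(labels, connectivity)
  remove_small_enhancing(out, min_volume, mode, connectivity)
}
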
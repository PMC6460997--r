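MODALITIES <- c("t1", "t2", "t1ce", "flair")
INTERNAL_LABELS <- 0:3

#' Construct a multimodal MRI volume
#'
#' Bundles four co-registered modalities (T1, T2, post-contrast T1, FLAIR)
#' into a single channel-last array with voxel spacing and opaque orientation
#' metadata.
#'
#' @param intensities Numeric array of dimension (X, Y, Z, 4); channel order
#'   T1, T2, post-contrast T1, FLAIR.
#' @param spacing Numeric length-3 vector, mm per voxel along each axis.
#' @param orientation Arbitrary metadata carried through for round-trip
#'   (e.g. a NIfTI header); never interpreted.
#' @return An object of class `multimodal_volume`.
#' @export
multimodal_volume <- function(intensities, spacing = c(1, 1, 1),
                              orientation = NULL) {
  d <- dim(intensities)
  if (length(d) != 4L || d[4] != 4L)
    stop("intensities must be a 4-D array with exactly 4 channels, got dim ",
         paste(d, collapse = "x"))
  if (!all(is.finite(intensities)))
    stop("intensities contain non-finite values")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  structure(
    list(intensities = intensities, shape = d[1:3], spacing = as.numeric(spacing),
         orientation = orientation),
    class = "multimodal_volume")
}

#' Construct a label volume
#'
#' Integer tumor sub-region labels over the internal coding
#' 0 = background, 1 = edema, 2 = non-enhancing tumor, 3 = enhancing tumor.
#'
#' @param labels Integer 3-D array with values in {0, 1, 2, 3}.
#' @param spacing Voxel spacing, mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  bad <- setdiff(unique(as.vector(labels)), INTERNAL_LABELS)
  if (length(bad))
    stop("unknown label value(s): {", paste(sort(bad), collapse = ", "), "}")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, shape = dim(labels),
                 spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  cat("multimodal_volume:", paste(x$shape, collapse = "x"),
      "voxels, 4 channels (", paste(MODALITIES, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$labels, levels = INTERNAL_LABELS))
  cat("label_volume:", paste(x$shape, collapse = "x"), "voxels;",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Standard label codings
#'
#' `brats_label_mapping()` maps the BraTS on-disk coding
#' {0 background, 1 necrotic/non-enhancing core, 2 edema, 4 enhancing} to the
#' internal scheme; `identity_label_mapping()` is the identity on {0..3}.
#' A mapping is a named integer vector `external -> internal`.
#'
#' @return Named integer vector.
#' @export
brats_label_mapping <- function() {
  c("0" = 0L, "1" = 2L, "2" = 1L, "4" = 3L)
}

#' @rdname brats_label_mapping
#' @export
identity_label_mapping <- function() {
  c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L)
}

invert_mapping <- function(mapping) {
  if (anyDuplicated(mapping))
    stop("label mapping is not a bijection: duplicated target values")
  stats::setNames(as.integer(names(mapping)), as.character(mapping))
}

apply_label_mapping <- function(grid, mapping) {
  vals <- unique(as.vector(grid))
  unknown <- setdiff(vals, as.integer(names(mapping)))
  if (length(unknown))
    stop("unknown label value(s): {", paste(sort(unknown), collapse = ", "),
         "} not covered by mapping")
  out <- array(mapping[as.character(as.vector(grid))], dim = dim(grid))
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Case record: one patient's file set
#'
#' @param case_id Identifier string.
#' @param t1,t2,t1ce,flair Paths to the four modality NIfTI files.
#' @param labels Optional path to the label NIfTI.
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, t1, t2, t1ce, flair, labels = NULL) {
  structure(list(case_id = case_id,
                 paths = c(t1 = t1, t2 = t2, t1ce = t1ce, flair = flair),
                 label_path = labels),
            class = "case_record")
}

#' Read a segmentation case from NIfTI files
#'
#' Loads the four modalities into canonical channel order and, when present,
#' the label volume mapped to the internal coding. All five grids must share
#' one shape; a mismatch is a hard error naming the offending file.
#'
#' @param record A [case_record()].
#' @param label_mapping Named integer vector mapping on-disk label values to
#'   the internal coding; default [identity_label_mapping()].
#' @return List with elements `volume` ([multimodal_volume()]) and `labels`
#'   ([label_volume()] or `NULL`).
#' @export
read_case <- function(record, label_mapping = identity_label_mapping()) {
  for (p in c(record$paths, record$label_path))
    if (!file.exists(p)) stop("missing file for case ", record$case_id, ": ", p)
  imgs <- lapply(record$paths, RNifti::readNifti)
  ref_dim <- dim(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), ref_dim))
      stop("shape mismatch in case ", record$case_id, ": file ",
           record$paths[i], " has dim ", paste(dim(imgs[[i]]), collapse = "x"),
           " but ", record$paths[1], " has ", paste(ref_dim, collapse = "x"))
  }
  spacing <- RNifti::pixdim(imgs[[1]])[1:3]
  arr <- array(0, dim = c(ref_dim, 4L))
  for (i in 1:4) arr[, , , i] <- as.array(imgs[[i]])
  vol <- multimodal_volume(arr, spacing = spacing, orientation = imgs[[1]])
  labs <- NULL
  if (!is.null(record$label_path)) {
    lab_img <- RNifti::readNifti(record$label_path)
    if (!identical(dim(lab_img), ref_dim))
      stop("shape mismatch in case ", record$case_id, ": label file ",
           record$label_path, " has dim ", paste(dim(lab_img), collapse = "x"))
    lab <- apply_label_mapping(array(as.integer(round(as.array(lab_img))),
                                     dim = ref_dim),
                               label_mapping)
    labs <- label_volume(lab, spacing = spacing)
  }
  list(volume = vol, labels = labs)
}

#' Write a multimodal volume to four NIfTI files
#'
#' @param volume A [multimodal_volume()].
#' @param paths Named character vector with entries t1, t2, t1ce, flair.
#' @return Invisibly, `paths`.
#' @export
write_volume <- function(volume, paths) {
  stopifnot(all(MODALITIES %in% names(paths)))
  for (i in seq_along(MODALITIES)) {
    img <- RNifti::asNifti(volume$intensities[, , , i, drop = TRUE])
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, paths[[MODALITIES[i]]])
  }
  invisible(paths)
}

#' Write a label volume under a chosen external coding
#'
#' The mapping (internal -> external) must be a bijection covering every
#' label present; composing with its inverse on read restores the grid
#' exactly.
#'
#' @param labels A [label_volume()].
#' @param path Output NIfTI path.
#' @param mapping Named integer vector, internal value -> external value;
#'   default identity.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path, mapping = identity_label_mapping()) {
  if (anyDuplicated(mapping))
    stop("label mapping is not a bijection: duplicated target values")
  used <- unique(as.vector(labels$labels))
  missing_cls <- setdiff(used, as.integer(names(mapping)))
  if (length(missing_cls))
    stop("mapping omits label value(s) present in grid: {",
         paste(sort(missing_cls), collapse = ", "), "}")
  out <- array(as.integer(mapping[as.character(as.vector(labels$labels))]),
               dim = labels$shape)
  img <- RNifti::asNifti(out)
  RNifti::pixdim(img) <- labels$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a case manifest
#'
#' A manifest is a CSV table with columns case_id, t1, t2, t1ce, flair and
#' optionally labels; relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @return List of [case_record()]s.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", MODALITIES)
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(df)), function(i) {
    lab <- if ("labels" %in% names(df) && nzchar(df$labels[i]))
      resolve(df$labels[i]) else NULL
    case_record(df$case_id[i], resolve(df$t1[i]), resolve(df$t2[i]),
                resolve(df$t1ce[i]), resolve(df$flair[i]), labels = lab)
  })
}

#' @rdname read_manifest
#' @param records List of [case_record()]s.
#' @export
write_manifest <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(case_id = r$case_id, t1 = r$paths[["t1"]], t2 = r$paths[["t2"]],
               t1ce = r$paths[["t1ce"]], flair = r$paths[["flair"]],
               labels = if (is.null(r$label_path)) "" else r$label_path,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
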
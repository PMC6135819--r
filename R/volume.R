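#' Labeled voxel volumes
#'
#' A `labeled_volume` holds a 3D voxel grid (0 = background, >0 = object
#' label), the physical voxel spacing, and acquisition provenance. Binary
#' masks use values in {0, 1}. The array axes are (y, x, z): TIFF pages map
#' to the z axis and each page is stored rows-first, matching how
#' [tiff::readTIFF()] returns pages. The voxel with index (i, j, k) has its
#' center at physical position ((i, j, k) - 0.5) * spacing.
#'
#' @param voxels 3D integer array of non-negative labels.
#' @param spacing positive length-3 physical voxel size per axis (y, x, z),
#'   e.g. micrometres.
#' @param image_id identifier of the source microscopy image (grouping unit
#'   for cross-validation).
#' @param channel `"nuclear"` or `"nucleolar"`.
#' @param condition class label of the biological condition (e.g. `"SS"`,
#'   `"PROLIF"`).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, spacing = c(1, 1, 1), image_id = "img",
                           channel = c("nuclear", "nucleolar"),
                           condition = NA_character_) {
  channel <- match.arg(channel)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1)) stop("all grid dimensions must be >= 1")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive lengths")
  storage.mode(voxels) <- "integer"
  if (any(voxels < 0)) stop("voxel labels must be non-negative")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 image_id = as.character(image_id), channel = channel,
                 condition = as.character(condition)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("labeled_volume %s [%s/%s]: %s voxels, %d foreground\n",
              x$image_id, x$channel, x$condition,
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels > 0)))
  invisible(x)
}

is_binary_volume <- function(volume) all(volume$voxels %in% c(0L, 1L))

#' Read a 3D mask volume from a multi-page TIFF
#'
#' Pages become the z axis. Non-zero pixels are mapped to 1, so 8-bit and
#' 16-bit masks (e.g. values 0/65535) both load as binary volumes.
#'
#' @param path a multi-page TIFF file.
#' @param spacing physical voxel size per (y, x, z) axis; default isotropic 1.
#' @param image_id,channel,condition metadata attached verbatim (see
#'   [labeled_volume()]).
#' @return A binary `labeled_volume`.
#' @export
read_mask_volume <- function(path, spacing = c(1, 1, 1), image_id = "img",
                             channel = "nuclear", condition = NA_character_) {
  if (!file.exists(path)) stop("cannot read mask volume, no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
                      stop("failed to read TIFF '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page shapes in TIFF: ", path)
  vox <- array(0L, c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]   # drop extra channels
    vox[, , k] <- as.integer(p != 0)
  }
  labeled_volume(vox, spacing, image_id, channel, condition)
}

#' Write a binary mask volume as a multi-page TIFF
#'
#' @param volume a binary `labeled_volume`.
#' @param path output file path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_mask_volume <- function(volume, path, bits_per_sample = 16) {
  stopifnot(inherits(volume, "labeled_volume"))
  vox <- volume$voxels
  pages <- lapply(seq_len(dim(vox)[3]),
                  function(k) (vox[, , k] > 0) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Object masks: one connected component of a binary volume
#'
#' An `object_mask` carries a cropped binary subgrid containing exactly one
#' connected foreground component, plus its position in the parent volume.
#'
#' @name object_mask
#' @format A list with fields `voxels` (cropped binary array), `spacing`,
#'   `image_id`, `channel`, `condition`, `object_id`, `bounding_box` (3 x 2
#'   inclusive index range in the parent grid), `offset` (index offset:
#'   parent index = offset + local index) and `centroid` (physical
#'   coordinates in the parent frame).
NULL

new_object_mask <- function(volume, voxels, object_id, bbox) {
  offset <- bbox[, 1] - 1L
  idx <- which(voxels > 0, arr.ind = TRUE)
  centroid <- (colMeans(idx) + offset - 0.5) * volume$spacing
  structure(list(voxels = voxels, spacing = volume$spacing,
                 image_id = volume$image_id, channel = volume$channel,
                 condition = volume$condition, object_id = object_id,
                 bounding_box = bbox, offset = offset, centroid = centroid),
            class = c("object_mask", "labeled_volume"))
}

#' @export
print.object_mask <- function(x, ...) {
  cat(sprintf("object_mask %s#%d [%s/%s]: %d voxels in %s subgrid\n",
              x$image_id, x$object_id, x$channel, x$condition,
              sum(x$voxels), paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

#' Split a binary volume into connected objects
#'
#' Labels maximal connected components of the foreground and returns each as
#' a cropped [object_mask]. Components smaller than `min_voxels` are
#' discarded (a message reports how many).
#'
#' @param volume a binary `labeled_volume`.
#' @param connectivity 26 (default; face/edge/corner adjacency) or 6
#'   (face adjacency only).
#' @param min_voxels minimum component size kept; default 50 suppresses
#'   segmentation specks.
#' @return A list of `object_mask` objects (empty for an empty volume).
#' @export
split_objects <- function(volume, connectivity = 26, min_voxels = 50) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (!is_binary_volume(volume)) stop("split_objects expects a binary volume")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  lab <- .cc_label(volume$voxels, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) return(list())
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(sizes >= min_voxels)
  if (length(keep) < n)
    message(sprintf("split_objects: discarded %d object(s) smaller than %d voxels",
                    n - length(keep), min_voxels))
  out <- vector("list", length(which(sizes >= min_voxels)))
  oid <- 0L
  for (l in keep) {
    oid <- oid + 1L
    idx <- which(lab == l, arr.ind = TRUE)
    bbox <- cbind(apply(idx, 2, min), apply(idx, 2, max))
    sub <- array(0L, bbox[, 2] - bbox[, 1] + 1L)
    sub[idx - matrix(bbox[, 1] - 1L, nrow(idx), 3, byrow = TRUE)] <- 1L
    out[[oid]] <- new_object_mask(volume, sub, oid, bbox)
  }
  out
}

# does this object's mask contain the given parent-grid voxel index?
object_contains_voxel <- function(object, voxel_index) {
  loc <- voxel_index - object$offset
  d <- dim(object$voxels)
  if (any(loc < 1) || any(loc > d)) return(FALSE)
  object$voxels[loc[1], loc[2], loc[3]] > 0
}

#' Assign nucleoli to their parent nuclei
#'
#' A nucleolus belongs to the nucleus whose mask contains its centroid voxel.
#' Nucleoli falling in no nucleus are dropped, and nuclei without any
#' internal nucleolus are excluded from the result (both logged), so every
#' retained nucleus has at least one nucleolus.
#'
#' @param nuclei list of nuclear `object_mask`s from one image.
#' @param nucleoli list of nucleolar `object_mask`s from the same image and
#'   grid.
#' @return Named list: one entry per retained nucleus (name =
#'   `object_id`), each a list with `nucleus` and `nucleoli` (non-empty list).
#' @export
assign_nucleoli <- function(nuclei, nucleoli) {
  if (length(nuclei) == 0) return(list())
  sp <- nuclei[[1]]$spacing
  for (nc in nucleoli) {
    if (!isTRUE(all.equal(nc$spacing, sp)))
      stop("nuclear and nucleolar volumes have mismatched grids/spacing")
  }
  assigned <- vector("list", length(nuclei))
  dropped <- 0L
  for (nc in nucleoli) {
    cen_idx <- as.integer(ceiling(nc$centroid / sp - 1e-9))
    hit <- which(vapply(nuclei, object_contains_voxel, logical(1),
                        voxel_index = cen_idx))
    if (length(hit) == 0) {
      dropped <- dropped + 1L
    } else {
      # nuclei are disjoint components; at most one can contain the centroid
      h <- hit[1]
      assigned[[h]] <- c(assigned[[h]], list(nc))
    }
  }
  if (dropped > 0)
    message(sprintf("assign_nucleoli: dropped %d nucleolus(i) outside all nuclei",
                    dropped))
  keep <- which(lengths(assigned) > 0)
  if (length(keep) < length(nuclei))
    message(sprintf("assign_nucleoli: excluded %d nucleus(i) without nucleoli",
                    length(nuclei) - length(keep)))
  out <- lapply(keep, function(i)
    list(nucleus = nuclei[[i]], nucleoli = assigned[[i]]))
  names(out) <- vapply(keep, function(i) as.character(nuclei[[i]]$object_id), "")
  out
}

#' Read or write a volume manifest
#'
#' A manifest is a CSV with columns `path`, `image_id`, `channel`,
#' `condition`, `spacing_y`, `spacing_x`, `spacing_z` describing one TIFF
#' mask volume per row.
#'
#' @param path CSV file path.
#' @return `read_manifest`: a data.frame; `write_manifest`: `path`,
#'   invisibly.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "image_id", "channel", "condition",
            "spacing_y", "spacing_x", "spacing_z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_manifest
#' @param manifest a manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load every volume listed in a manifest
#'
#' @param manifest a manifest data.frame (see [read_manifest()]); relative
#'   paths are resolved against `base_dir`.
#' @param base_dir directory that relative `path` entries are resolved
#'   against.
#' @return List of `labeled_volume` objects.
#' @export
load_manifest_volumes <- function(manifest, base_dir = ".") {
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    p <- r$path
    if (!file.exists(p)) p <- file.path(base_dir, r$path)
    read_mask_volume(p,
                     spacing = c(r$spacing_y, r$spacing_x, r$spacing_z),
                     image_id = r$image_id, channel = r$channel,
                     condition = r$condition)
  })
}
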
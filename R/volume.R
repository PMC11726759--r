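#' 3D image volume
#'
#' A `wm_volume` wraps a 3D numeric array together with its voxel spacing
#' (mm per axis), physical origin (mm) and a free-text modality tag. All
#' wavemorph geometry is expressed in 0-based voxel indices of the volume's
#' own grid; spacing is carried for physical-unit metrics (e.g. surface
#' distances in mm).
#'
#' @param data 3D numeric array (H x W x L).
#' @param spacing numeric length-3, mm per voxel along each axis; must be > 0.
#' @param origin numeric length-3, mm.
#' @param modality free-text tag (e.g. "CT", "MR").
#' @return An object of class `wm_volume`.
#' @export
wm_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      modality = "") {
  if (length(dim(data)) != 3L) stopf("expected 3D volume, got %dD", length(dim(data)))
  if (any(dim(data) < 1L)) stopf("all dimensions must be >= 1")
  if (length(spacing) != 3L || any(spacing <= 0)) stopf("spacing must be 3 positive reals")
  if (!all(is.finite(data))) stopf("volume data must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = as.double(spacing),
                 origin = as.double(origin), modality = as.character(modality)),
            class = "wm_volume")
}

#' @export
print.wm_volume <- function(x, ...) {
  cat(sprintf("<wm_volume %s  %s  spacing %s mm  range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              if (nzchar(x$modality)) x$modality else "(untagged)",
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.wm_volume <- function(x) dim(x$data)

#' @export
as.array.wm_volume <- function(x, ...) x$data

#' Integer label map aligned with a volume
#'
#' @param data 3D integer array; 0 is background.
#' @param labels named integer vector mapping label id to name (optional).
#' @param spacing voxel spacing in mm.
#' @return An object of class `wm_labelmap`.
#' @export
wm_labelmap <- function(data, labels = NULL, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stopf("expected 3D label map")
  if (any(data < 0)) stopf("label ids must be >= 0 (0 = background)")
  storage.mode(data) <- "integer"
  if (is.null(labels)) {
    ids <- sort(setdiff(unique(as.vector(data)), 0L))
    labels <- stats::setNames(ids, paste0("label", ids))
  }
  structure(list(data = data, labels = labels, spacing = as.double(spacing)),
            class = "wm_labelmap")
}

#' @export
dim.wm_labelmap <- function(x) dim(x$data)

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality optional modality tag attached to the result.
#' @return A [wm_volume].
#' @export
read_volume <- function(path, modality = "") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stopf("expected 3D volume, got %dD image in %s", length(d), path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  sp <- as.double(pd[seq_len(3)])
  sp[!is.finite(sp) | sp <= 0] <- 1
  wm_volume(array(as.double(img), dim = d), spacing = sp, modality = modality)
}

#' Write a volume (or raw array) as NIfTI-1
#'
#' @param vol a [wm_volume], [wm_labelmap] or 3D/4D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "wm_volume") || inherits(vol, "wm_labelmap")) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
  } else {
    img <- RNifti::asNifti(vol)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI label map
#'
#' @inheritParams read_volume
#' @return A [wm_labelmap].
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stopf("expected 3D label map, got %dD image in %s", length(d), path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  sp <- as.double(pd[seq_len(3)])
  sp[!is.finite(sp) | sp <= 0] <- 1
  wm_labelmap(array(as.integer(round(img)), dim = d), spacing = sp)
}

#' Resample a volume onto a target grid
#'
#' Trilinear resampling onto `target_shape`. When `target_spacing` is omitted
#' it is chosen so the physical extent of the volume (corner-to-corner) is
#' preserved. Indices map corner-aligned: output voxel i samples input
#' coordinate `i * target_spacing / spacing`.
#'
#' @param vol a [wm_volume].
#' @param target_shape integer length-3.
#' @param target_spacing numeric length-3 or `NULL`.
#' @return A resampled [wm_volume].
#' @export
resample_to <- function(vol, target_shape, target_spacing = NULL) {
  stopifnot(inherits(vol, "wm_volume"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    stopf("target_shape must be 3 integers >= 1")
  }
  in_shape <- dim(vol$data)
  if (is.null(target_spacing)) {
    target_spacing <- vol$spacing * (in_shape - 1) / pmax(target_shape - 1, 1)
    target_spacing[target_shape == 1] <- vol$spacing[target_shape == 1]
  }
  if (all(target_shape == in_shape) && all(abs(target_spacing - vol$spacing) < 1e-12)) {
    return(vol)
  }
  step <- target_spacing / vol$spacing
  ax <- function(a) (seq_len(target_shape[a]) - 1) * step[a]
  x <- ax(1); y <- ax(2); z <- ax(3)
  co <- cbind(
    rep.int(x, length(y) * length(z)),
    rep.int(rep(y, each = length(x)), length(z)),
    rep(z, each = length(x) * length(y))
  )
  v <- cpp_sample3(as.double(vol$data), as.integer(c(in_shape, 1L)), co, FALSE)
  dim(v) <- target_shape
  wm_volume(v, spacing = target_spacing, origin = vol$origin, modality = vol$modality)
}

#' Normalize volume intensities
#'
#' `minmax` maps intensities to \[0, 1\]; `zscore` to mean 0, sd 1. A constant
#' image is returned as all zeros with a warning.
#'
#' @param vol a [wm_volume].
#' @param mode `"minmax"` or `"zscore"`.
#' @return A [wm_volume] with normalized intensities.
#' @export
normalize_intensity <- function(vol, mode = c("minmax", "zscore")) {
  stopifnot(inherits(vol, "wm_volume"))
  mode <- match.arg(mode)
  x <- vol$data
  r <- range(x)
  if (r[2] - r[1] <= .Machine$double.eps) {
    warnf("constant image: normalization returns all zeros")
    vol$data <- array(0, dim = dim(x))
    return(vol)
  }
  vol$data <- if (mode == "minmax") (x - r[1]) / (r[2] - r[1]) else (x - mean(x)) / sd(x)
  vol
}

#' Crop away low-intensity background
#'
#' Finds the tightest bounding box of voxels strictly above `threshold`,
#' extends it to even extents per axis (growing into the volume where
#' possible, otherwise replicating the edge slice) and crops. The returned
#' offsets allow exact re-embedding into the original grid.
#'
#' @param vol a [wm_volume].
#' @param threshold intensity threshold; voxels `> threshold` are foreground.
#' @return A list with elements `volume` (cropped [wm_volume]), `offset`
#'   (1-based start index per axis in the original grid), `original_shape`,
#'   and `padded` (logical per axis: TRUE where an edge slice was replicated).
#' @export
crop_background <- function(vol, threshold) {
  stopifnot(inherits(vol, "wm_volume"))
  x <- vol$data
  d <- dim(x)
  fg <- which(x > threshold, arr.ind = TRUE)
  if (nrow(fg) == 0L) {
    warnf("no foreground voxels above threshold %g: returning input unchanged", threshold)
    return(list(volume = vol, offset = c(1L, 1L, 1L), original_shape = d,
                padded = c(FALSE, FALSE, FALSE)))
  }
  if (nrow(fg) == prod(d)) {
    return(list(volume = vol, offset = c(1L, 1L, 1L), original_shape = d,
                padded = c(FALSE, FALSE, FALSE)))
  }
  lo <- apply(fg, 2, min)
  hi <- apply(fg, 2, max)
  padded <- c(FALSE, FALSE, FALSE)
  for (a in 1:3) {
    if ((hi[a] - lo[a] + 1L) %% 2L == 1L) {
      if (hi[a] < d[a]) hi[a] <- hi[a] + 1L
      else if (lo[a] > 1L) lo[a] <- lo[a] - 1L
      else padded[a] <- TRUE
    }
  }
  crop <- x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  for (a in which(padded)) {
    dd <- dim(crop)
    idx <- lapply(dd, seq_len)
    idx[[a]] <- c(idx[[a]], dd[a])        # replicate last slice
    crop <- do.call(`[`, c(list(crop), idx, list(drop = FALSE)))
  }
  out <- wm_volume(crop, spacing = vol$spacing, origin = vol$origin,
                   modality = vol$modality)
  list(volume = out, offset = as.integer(lo), original_shape = d, padded = padded)
}

#' Re-embed a crop into its original grid
#'
#' Inverse of [crop_background] for the non-replicated region.
#'
#' @param crop result list from [crop_background].
#' @param fill value for voxels outside the crop.
#' @return A [wm_volume] with the original shape.
#' @export
uncrop <- function(crop, fill = 0) {
  d <- crop$original_shape
  x <- array(fill, dim = d)
  cd <- dim(crop$volume$data)
  keep <- cd - ifelse(crop$padded, 1L, 0L)
  lo <- crop$offset
  x[lo[1]:(lo[1] + keep[1] - 1L), lo[2]:(lo[2] + keep[2] - 1L),
    lo[3]:(lo[3] + keep[3] - 1L)] <-
    crop$volume$data[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3])]
  wm_volume(x, spacing = crop$volume$spacing, origin = crop$volume$origin,
            modality = crop$volume$modality)
}
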
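# Dense displacement-field algebra: warping, composition, resolution changes,
# Jacobian folding analysis. Displacements are stored in voxel units of the
# field's own grid, component order (x, y, z) along the 4th array axis.

#' Dense displacement field
#'
#' @param vectors 4D numeric array H x W x L x 3; displacement in voxels of
#'   the field's own grid, component order (x, y, z).
#' @return An object of class `wm_field`.
#' @export
wm_field <- function(vectors) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L) stopf("field must be an H x W x L x 3 array")
  if (!all(is.finite(vectors))) stopf("field entries must be finite")
  storage.mode(vectors) <- "double"
  structure(list(vectors = vectors, shape = d[1:3]), class = "wm_field")
}

#' Zero displacement field
#' @param shape integer length-3 grid shape.
#' @return A [wm_field] of zeros.
#' @export
zero_field <- function(shape) wm_field(array(0, dim = c(shape, 3L)))

#' @export
print.wm_field <- function(x, ...) {
  m <- sqrt(rowSums(matrix(x$vectors, ncol = 3L)^2))
  cat(sprintf("<wm_field %s  |u| mean %.3f max %.3f voxels>\n",
              paste(x$shape, collapse = "x"), mean(m), max(m)))
  invisible(x)
}

#' @export
dim.wm_field <- function(x) dim(x$vectors)

#' Warp a volume or label map by a displacement field
#'
#' `output(x) = input(x + u(x))` with border clamping. Volumes are sampled
#' with the requested interpolation; label maps always use nearest-neighbour
#' so no new labels are invented.
#'
#' @param x a [wm_volume], [wm_labelmap] or 3D array on the field's grid.
#' @param field a [wm_field] with the same grid shape.
#' @param interp `"trilinear"` or `"nearest"` (volumes only).
#' @return Warped object of the same kind as `x`.
#' @export
warp <- function(x, field, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(field, "wm_field"))
  arr <- if (inherits(x, "wm_volume") || inherits(x, "wm_labelmap")) x$data else x
  d <- dim(arr)
  if (!all(d == field$shape)) {
    stopf("shape mismatch: volume %s vs field %s",
          paste(d, collapse = "x"), paste(field$shape, collapse = "x"))
  }
  nearest <- interp == "nearest" || inherits(x, "wm_labelmap")
  co <- identity_grid(d) + matrix(field$vectors, ncol = 3L)
  v <- cpp_sample3(as.double(arr), as.integer(c(d, 1L)), co, nearest)
  dim(v) <- d
  if (inherits(x, "wm_volume")) {
    wm_volume(v, spacing = x$spacing, origin = x$origin, modality = x$modality)
  } else if (inherits(x, "wm_labelmap")) {
    wm_labelmap(array(as.integer(round(v)), dim = d), labels = x$labels,
                spacing = x$spacing)
  } else v
}

#' Compose two displacement fields
#'
#' `result(x) = outer(x + inner(x)) + inner(x)`: applying the result is
#' equivalent to applying `inner` first, then `outer` (refine-then-accumulate;
#' the field emitted by a later cascade stage is the `outer` refinement of the
#' accumulated `inner` field).
#'
#' @param outer,inner [wm_field]s on the same grid.
#' @return The composed [wm_field].
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "wm_field"), inherits(inner, "wm_field"))
  if (!all(outer$shape == inner$shape)) {
    stopf("shape mismatch: outer %s vs inner %s",
          paste(outer$shape, collapse = "x"), paste(inner$shape, collapse = "x"))
  }
  d <- outer$shape
  co <- identity_grid(d) + matrix(inner$vectors, ncol = 3L)
  v <- cpp_sample3(as.double(outer$vectors), as.integer(c(d, 3L)), co, FALSE)
  wm_field(array(v + as.vector(inner$vectors), dim = c(d, 3L)))
}

#' Resize a displacement field to a new grid
#'
#' Trilinearly interpolates the vectors onto the new grid and rescales each
#' component by the per-axis grid ratio, keeping displacements in voxel units
#' of the *new* grid. [upsample_field] is the integer-factor special case
#' (constant field c at factor 2 becomes constant 2c).
#'
#' @param field a [wm_field].
#' @param new_shape integer length-3 target grid.
#' @return A [wm_field] on `new_shape`.
#' @export
resize_field <- function(field, new_shape) {
  stopifnot(inherits(field, "wm_field"))
  new_shape <- as.integer(new_shape)
  if (all(new_shape == field$shape)) return(field)
  v <- resize_array(field$vectors, new_shape)
  scale <- new_shape / field$shape
  for (a in 1:3) v[, , , a] <- v[, , , a] * scale[a]
  wm_field(v)
}

#' Upsample a displacement field by an integer factor
#'
#' @param field a [wm_field].
#' @param factor integer >= 2.
#' @return A [wm_field] on the `factor`-times finer grid, magnitudes scaled
#'   by `factor`.
#' @export
upsample_field <- function(field, factor) {
  factor <- as.integer(factor)
  if (factor < 2L) stopf("factor must be >= 2")
  resize_field(field, field$shape * factor)
}

#' Jacobian determinant map of a deformation
#'
#' Computes, per voxel, the determinant of the Jacobian of the transform
#' `x + u(x)` via central differences (one-sided at the volume boundary).
#'
#' @param field a [wm_field]; grid must be >= 2 per axis.
#' @return 3D array of determinants, same shape as the field grid.
#' @export
jacobian_map <- function(field) {
  stopifnot(inherits(field, "wm_field"))
  if (any(field$shape < 2L)) stopf("grid must be >= 2 per axis")
  u <- field$vectors
  J <- array(0, dim = c(field$shape, 3L, 3L))
  for (i in 1:3) for (j in 1:3) {
    J[, , , i, j] <- axis_cdiff(u[, , , i], j) + (i == j)
  }
  J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
    J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
    J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
}

#' Fraction of folding voxels (Jacobian determinant <= 0)
#'
#' Evaluated over interior voxels (central differences are one-sided at the
#' boundary, so boundary voxels are excluded from the fraction).
#'
#' @param field a [wm_field].
#' @return List with `fraction` (proportion in \[0, 1\] of interior voxels
#'   with non-positive determinant) and `det` (the determinant map).
#' @export
jacobian_nonpositive_fraction <- function(field) {
  det <- jacobian_map(field)
  d <- dim(det)
  interior <- det[seq(2, max(d[1] - 1, 2)), seq(2, max(d[2] - 1, 2)),
                  seq(2, max(d[3] - 1, 2)), drop = FALSE]
  list(fraction = mean(interior <= 0), det = det)
}

#' Save a displacement field as 4D NIfTI
#'
#' Last axis is the vector component, order (x, y, z), voxel units.
#'
#' @param field a [wm_field].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "wm_field"))
  RNifti::writeNifti(RNifti::asNifti(field$vectors), path)
  invisible(path)
}

#' Read a displacement field from 4D NIfTI
#' @param path path to a 4D NIfTI with 3 components on the last axis.
#' @return A [wm_field].
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L) stopf("expected H x W x L x 3 field image")
  wm_field(array(as.double(img), dim = d))
}
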
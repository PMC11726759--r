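# Grey-scale morphology with dual (ring) structuring elements and the
# associated top-hat transforms, used to simulate large organ deformation when
# building similarity-evaluator training samples.

#' Ball (disc) structuring element
#'
#' Binary mask of voxels within Euclidean distance `radius` of the centre, on
#' an odd cubic support of side `2*radius + 1`. With `slicewise = TRUE` the
#' element is a 2D disc in the (x, y) plane (support thickness 1 in z).
#'
#' @param radius integer >= 1, in voxels.
#' @param slicewise build a 2D disc instead of a 3D ball.
#' @return Logical array of dim `c(2r+1, 2r+1, 2r+1)` (or `c(2r+1, 2r+1, 1)`).
#' @export
ball_element <- function(radius, slicewise = FALSE) {
  radius <- as.integer(radius)
  if (radius < 1L) stopf("radius must be >= 1")
  r <- -radius:radius
  z <- if (slicewise) 0L else r
  d2 <- outer(outer(r^2, r^2, `+`), z^2, `+`)
  array(d2 <= radius^2, dim = dim(d2))
}

# Offsets (m x 3 integer matrix, centred) of the TRUE voxels of a mask.
element_offsets <- function(mask) {
  d <- dim(mask)
  ctr <- (d + 1L) %/% 2L
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx, 2L, ctr)
}

#' Pair of structuring elements defining a ring
#'
#' The ring element is the hollow shell `ball(outer) \ ball(inner)` (voxels
#' with `inner < dist <= outer`); the intermediate element is a ball of radius
#' `round((outer + inner) / 2)`.
#'
#' @param outer outer radius (voxels); must exceed `inner`.
#' @param inner inner radius, >= 1.
#' @param slicewise use 2D discs instead of 3D balls.
#' @return Object of class `wm_structpair` with the ring and intermediate
#'   offset sets and the radii.
#' @export
structuring_pair <- function(outer, inner, slicewise = FALSE) {
  outer <- as.integer(outer); inner <- as.integer(inner)
  if (inner < 1L) stopf("inner radius must be >= 1")
  if (outer <= inner) stopf("outer radius (%d) must exceed inner radius (%d)", outer, inner)
  ro <- element_offsets(ball_element(outer, slicewise))
  dist <- sqrt(rowSums(ro^2))
  ring_off <- ro[dist > inner & dist <= outer, , drop = FALSE]
  if (nrow(ring_off) == 0L) stopf("degenerate ring: no voxels between radii %d and %d", inner, outer)
  mid <- as.integer(round((outer + inner) / 2))
  mid <- max(mid, 1L)
  structure(list(outer = outer, inner = inner, mid = mid,
                 ring_width = outer - inner, slicewise = slicewise,
                 ring_offsets = ring_off,
                 mid_offsets = element_offsets(ball_element(mid, slicewise))),
            class = "wm_structpair")
}

#' @export
print.wm_structpair <- function(x, ...) {
  cat(sprintf("<wm_structpair outer %d inner %d mid %d (%s, ring %d voxels)>\n",
              x$outer, x$inner, x$mid, if (x$slicewise) "2D" else "3D",
              nrow(x$ring_offsets)))
  invisible(x)
}

mm_filter <- function(x, offsets, do_max) {
  arr <- if (inherits(x, "wm_volume")) x$data else x
  out <- cpp_minmax3(as.double(arr), as.integer(dim(arr)),
                     apply(offsets, 2L, as.integer), do_max)
  if (inherits(x, "wm_volume")) wm_volume(out, x$spacing, x$origin, x$modality) else out
}

#' Grey-scale erosion / dilation
#'
#' Min (erode) or max (dilate) filter over the translated structuring
#' element; borders use replicate padding.
#'
#' @param x 3D array or [wm_volume].
#' @param elem binary mask (e.g. from [ball_element]) or an offset matrix.
#' @return Filtered object of the same kind.
#' @export
erode <- function(x, elem) {
  off <- if (is.matrix(elem)) elem else element_offsets(elem)
  if (nrow(off) == 0L) stopf("empty structuring element")
  mm_filter(x, off, do_max = FALSE)
}

#' @rdname erode
#' @export
dilate <- function(x, elem) {
  off <- if (is.matrix(elem)) elem else element_offsets(elem)
  if (nrow(off) == 0L) stopf("empty structuring element")
  mm_filter(x, off, do_max = TRUE)
}

#' Dual-structure opening / closing
#'
#' Opening-like and closing-like operators built from the ring element and
#' the intermediate ball of a [structuring_pair]:
#' `dual_open(f) = erode(dilate(f, ring), mid)` and
#' `dual_close(f) = dilate(erode(f, ring), mid)`. Unlike plain opening these
#' are not idempotent: the ring element deliberately reshapes structures at
#' the ring scale to mimic large organ deformation.
#'
#' @param x 3D array or [wm_volume].
#' @param pair a [structuring_pair].
#' @return Same kind as `x`.
#' @export
dual_open <- function(x, pair) {
  stopifnot(inherits(pair, "wm_structpair"))
  mm_filter(mm_filter(x, pair$ring_offsets, TRUE), pair$mid_offsets, FALSE)
}

#' @rdname dual_open
#' @export
dual_close <- function(x, pair) {
  stopifnot(inherits(pair, "wm_structpair"))
  mm_filter(mm_filter(x, pair$ring_offsets, FALSE), pair$mid_offsets, TRUE)
}

#' Dual-structure top-hat transforms
#'
#' `white_tophat_dual(f) = f - dual_open(f)` isolates bright structures
#' narrower than the ring; `black_tophat_dual(f) = dual_close(f) - f` isolates
#' dark ones. Both vanish on constant images and are invariant to adding a
#' constant.
#'
#' @inheritParams dual_open
#' @return Same kind as `x`.
#' @export
white_tophat_dual <- function(x, pair) {
  arr <- if (inherits(x, "wm_volume")) x$data else x
  res <- arr - (if (inherits(x, "wm_volume")) dual_open(x, pair)$data else dual_open(arr, pair))
  if (inherits(x, "wm_volume")) wm_volume(res, x$spacing, x$origin, x$modality) else res
}

#' @rdname white_tophat_dual
#' @export
black_tophat_dual <- function(x, pair) {
  arr <- if (inherits(x, "wm_volume")) x$data else x
  res <- (if (inherits(x, "wm_volume")) dual_close(x, pair)$data else dual_close(arr, pair)) - arr
  if (inherits(x, "wm_volume")) wm_volume(res, x$spacing, x$origin, x$modality) else res
}
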
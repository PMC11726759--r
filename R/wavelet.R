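# Three-level separable 3D discrete wavelet transform with orthonormal
# Daubechies filters and periodic boundary handling, plus the gradient-fused
# high-frequency enhancement image.

# Orthonormal Daubechies analysis low-pass filters. The high-pass is the
# quadrature mirror g[n] = (-1)^n h[L-1-n]. Periodic (circular) convolution
# with decimation by 2 makes the transform an orthogonal map: shapes halve
# exactly, energy is preserved, and the inverse is the adjoint filter bank.
.wavelet_lo <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
          0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
          0.16010239797419293)
)
.wavelet_lo$haar <- .wavelet_lo$db1

#' Analysis filter pair of an orthonormal wavelet
#'
#' @param wavelet one of `"db1"`/`"haar"`, `"db2"`, `"db5"`.
#' @return List with `lo` and `hi` filter taps.
#' @export
wavelet_filters <- function(wavelet = "db5") {
  lo <- .wavelet_lo[[wavelet]]
  if (is.null(lo)) stopf("unknown wavelet '%s' (available: %s)", wavelet,
                         paste(names(.wavelet_lo), collapse = ", "))
  n <- length(lo)
  hi <- (-1)^(0:(n - 1)) * rev(lo)
  list(lo = lo, hi = hi)
}

.band_codes <- c("aaa", "aad", "ada", "add", "daa", "dad", "dda", "ddd")

new_subband_set <- function(bands, level) {
  stopifnot(setequal(names(bands), .band_codes))
  structure(list(level = as.integer(level), bands = bands[.band_codes],
                 shape = dim(bands[[1]])), class = "wm_subbands")
}

#' @export
print.wm_subbands <- function(x, ...) {
  cat(sprintf("<wm_subbands level %d  8 bands of %s>\n", x$level,
              paste(x$shape, collapse = "x")))
  invisible(x)
}

# One separable analysis level. Band code letters follow axis order (x, y, z);
# 'a' = low-pass, 'd' = high-pass.
dwt3_single <- function(x, wavelet = "db5") {
  d <- dim(x)
  if (any(d %% 2L != 0L)) stopf("all axes must be even for one DWT level, got %s",
                                paste(d, collapse = "x"))
  f <- wavelet_filters(wavelet)
  s1 <- cpp_dwt_axis(as.double(x), as.integer(d), f$lo, f$hi, 0L)
  out <- list()
  for (cx in c("a", "d")) {
    x1 <- if (cx == "a") s1$a else s1$d
    s2 <- cpp_dwt_axis(as.double(x1), as.integer(dim(x1)), f$lo, f$hi, 1L)
    for (cy in c("a", "d")) {
      x2 <- if (cy == "a") s2$a else s2$d
      s3 <- cpp_dwt_axis(as.double(x2), as.integer(dim(x2)), f$lo, f$hi, 2L)
      out[[paste0(cx, cy, "a")]] <- s3$a
      out[[paste0(cx, cy, "d")]] <- s3$d
    }
  }
  out
}

idwt3_single <- function(bands, wavelet = "db5") {
  f <- wavelet_filters(wavelet)
  up2 <- list()
  for (cx in c("a", "d")) {
    for (cy in c("a", "d")) {
      a <- bands[[paste0(cx, cy, "a")]]
      d <- bands[[paste0(cx, cy, "d")]]
      up2[[paste0(cx, cy)]] <- cpp_idwt_axis(as.double(a), as.double(d),
                                             as.integer(dim(a)), f$lo, f$hi, 2L)
    }
  }
  up1 <- list()
  for (cx in c("a", "d")) {
    a <- up2[[paste0(cx, "a")]]
    d <- up2[[paste0(cx, "d")]]
    up1[[cx]] <- cpp_idwt_axis(as.double(a), as.double(d), as.integer(dim(a)),
                               f$lo, f$hi, 1L)
  }
  cpp_idwt_axis(as.double(up1$a), as.double(up1$d), as.integer(dim(up1$a)),
                f$lo, f$hi, 0L)
}

#' Multi-level 3D discrete wavelet decomposition
#'
#' Decomposes a volume into `levels` levels of 8 subbands each (codes
#' `aaa`...`ddd`; letter order = axis order, `a` low-pass, `d` high-pass).
#' The `aaa` approximation of level k is the input of level k+1. The
#' transform is orthonormal (periodic boundary), so the full tree preserves
#' energy and reconstructs the input exactly up to round-off.
#'
#' @param vol a [wm_volume] or 3D array.
#' @param wavelet wavelet name; the registration cascade default is `db5`.
#' @param levels number of decomposition levels (default 3).
#' @return List of `wm_subbands`, one per level (fine to coarse).
#' @export
dwt3_level <- function(vol, wavelet = "db5", levels = 3L) {
  x <- if (inherits(vol, "wm_volume")) vol$data else vol
  d <- dim(x)
  if (!is_dyadic_compatible(d, levels)) {
    stopf("volume shape %s is not divisible by 2^%d; pad first",
          paste(d, collapse = "x"), levels)
  }
  out <- vector("list", levels)
  cur <- x
  for (lv in seq_len(levels)) {
    bands <- dwt3_single(cur, wavelet)
    out[[lv]] <- new_subband_set(bands, lv)
    cur <- bands$aaa
  }
  out
}

#' Inverse multi-level 3D DWT
#'
#' @param tree list of `wm_subbands` as returned by [dwt3_level].
#' @param wavelet wavelet name used for the analysis.
#' @return The reconstructed 3D array.
#' @export
idwt3_level <- function(tree, wavelet = "db5") {
  levels <- length(tree)
  cur <- tree[[levels]]$bands$aaa
  for (lv in rev(seq_len(levels))) {
    bands <- tree[[lv]]$bands
    bands$aaa <- cur
    cur <- idwt3_single(bands, wavelet)
  }
  cur
}

#' High-frequency enhancement image
#'
#' Fuses the seven high-frequency subbands of one level into a single
#' non-negative edge-emphasis image: the per-voxel sum over bands of the
#' gradient magnitude of each band (central differences in the interior,
#' one-sided at the boundary). Optionally min-max rescaled to \[0, 1\] so
#' different levels share an intensity scale before entering the network.
#'
#' @param sub a `wm_subbands` (by default the level-1 set is expected).
#' @param renormalize rescale the result to \[0, 1\] (default TRUE).
#' @return List of class `wm_enhanced` with `data` (3D array, band shape) and
#'   `level`.
#' @export
enhance_highfreq <- function(sub, renormalize = TRUE) {
  stopifnot(inherits(sub, "wm_subbands"))
  hf <- setdiff(.band_codes, "aaa")
  missing <- setdiff(hf, names(sub$bands))
  if (length(missing)) stopf("missing band code(s): %s", paste(missing, collapse = ", "))
  e <- array(0, dim = sub$shape)
  for (code in hf) e <- e + grad_magnitude(sub$bands[[code]])
  if (renormalize) e <- minmax01(e)
  structure(list(data = e, level = sub$level), class = "wm_enhanced")
}

#' Export subbands as NIfTI files
#'
#' Writes each band of each level as `<level>_<code>.nii.gz` under `dir`.
#'
#' @param tree list of `wm_subbands` from [dwt3_level].
#' @param dir output directory (created if needed).
#' @param spacing voxel spacing recorded in the files (finest level; doubled
#'   per level).
#' @return Character vector of written paths, invisibly.
#' @export
export_subbands <- function(tree, dir, spacing = c(1, 1, 1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sub in tree) {
    sp <- spacing * 2^sub$level
    for (code in .band_codes) {
      p <- file.path(dir, sprintf("%d_%s.nii.gz", sub$level, code))
      write_volume(wm_volume(sub$bands[[code]], spacing = sp), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
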
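# Synthetic multimodal phantom generator: paired pseudo-CT / pseudo-MR
# pelvis-like volumes with labelled organs and a known smooth + locally large
# ground-truth deformation. The two modalities render the same anatomy with
# deliberately different tissue-intensity orderings (bone bright on
# pseudo-CT but dark on pseudo-MR, fluid the reverse), so mono-modal
# similarity measures fail while structure is shared.

.ct_table <- c(background = 0.00, body = 0.45, bladder = 0.28, ctv = 0.55,
               femur = 0.95, intestine = 0.38)
.mr_table <- c(background = 0.02, body = 0.50, bladder = 0.95, ctv = 0.68,
               femur = 0.15, intestine = 0.80)

#' Phantom specification
#'
#' Organ geometry is ellipsoidal: a soft-tissue body, a large fluid-filled
#' bladder, an adjacent target volume, two lateral bone structures and an
#' intestinal blob, with small seed-controlled jitter. The ground-truth
#' deformation is a smoothed Gaussian random field of RMS magnitude
#' `amplitude` voxels plus a radial bladder-centred expansion of peak
#' magnitude `organ_expand` voxels (emulating organ-filling change between
#' acquisitions).
#'
#' @param shape grid shape; each axis must be divisible by 8 (three dyadic
#'   wavelet levels). Default 64 x 64 x 16.
#' @param amplitude RMS magnitude (voxels) of the smooth random deformation.
#' @param smoothness Gaussian sigma (voxels) of the random field.
#' @param organ_expand peak magnitude (voxels) of the radial bladder
#'   expansion component.
#' @param noise_sd additive Gaussian intensity noise (unit intensity range).
#' @param blur rendering blur sigma (voxels).
#' @param seed generation seed; identical specs generate identical phantoms.
#' @return Object of class `wm_phantomspec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 16L), amplitude = 4, smoothness = 6,
                         organ_expand = 1.5, noise_sd = 0.02, blur = 0.6,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (!is_dyadic_compatible(shape, 3L)) {
    stopf("shape must be divisible by 8, got %s", paste(shape, collapse = "x"))
  }
  if (amplitude < 0 || organ_expand < 0) stopf("deformation amplitudes must be >= 0")
  structure(list(shape = shape, amplitude = amplitude, smoothness = smoothness,
                 organ_expand = organ_expand, noise_sd = noise_sd, blur = blur,
                 seed = as.integer(seed), ct_table = .ct_table, mr_table = .mr_table),
            class = "wm_phantomspec")
}

# Fill an ellipsoid into a label array; errors if it pokes out of the grid.
fill_ellipsoid <- function(lab, center, radii, id, clip_ok = FALSE) {
  d <- dim(lab)
  if (!clip_ok && (any(center - radii < 1) || any(center + radii > d))) {
    stopf("organ %d overflows the grid (center %s radii %s)", id,
          paste(round(center, 1), collapse = ","), paste(round(radii, 1), collapse = ","))
  }
  g <- identity_grid(d) + 1
  r2 <- ((g[, 1] - center[1]) / radii[1])^2 + ((g[, 2] - center[2]) / radii[2])^2 +
    ((g[, 3] - center[3]) / radii[3])^2
  lab[r2 <= 1] <- id
  lab
}

phantom_label_ids <- c(body = 1L, bladder = 2L, ctv = 3L, femur = 4L, intestine = 5L)

# Build the base (moving) anatomy label array for a spec; RNG state is
# consumed (caller seeds).
phantom_anatomy <- function(spec) {
  d <- spec$shape
  lab <- array(0L, dim = d)
  jit <- function(s) runif(3, -s, s) * d
  ctr <- (d + 1) / 2
  lab <- fill_ellipsoid(lab, ctr, 0.44 * d, phantom_label_ids[["body"]], clip_ok = TRUE)
  bl_c <- ctr + c(0, -0.12 * d[2], 0) + jit(0.015)
  bl_r <- c(0.16, 0.14, 0.28) * d * runif(3, 0.9, 1.1)
  lab <- fill_ellipsoid(lab, bl_c, bl_r, phantom_label_ids[["bladder"]])
  ctv_c <- ctr + c(0, 0.1 * d[2], 0) + jit(0.012)
  ctv_r <- c(0.10, 0.09, 0.22) * d * runif(3, 0.9, 1.1)
  lab <- fill_ellipsoid(lab, ctv_c, ctv_r, phantom_label_ids[["ctv"]])
  for (sgn in c(-1, 1)) {
    f_c <- ctr + c(sgn * 0.33 * d[1], -0.02 * d[2], 0) + jit(0.01)
    f_r <- c(0.08, 0.08, 0.3) * d * runif(3, 0.9, 1.05)
    lab <- fill_ellipsoid(lab, f_c, f_r, phantom_label_ids[["femur"]])
  }
  in_c <- ctr + c(0, 0.28 * d[2], 0.08 * d[3]) + jit(0.012)
  in_r <- c(0.14, 0.10, 0.2) * d * runif(3, 0.85, 1.1)
  lab <- fill_ellipsoid(lab, in_c, in_r, phantom_label_ids[["intestine"]])
  list(labels = lab, bladder_center = bl_c, bladder_radius = mean(bl_r))
}

render_modality <- function(lab, table, noise_sd, blur) {
  img <- array(table[lab + 1L], dim = dim(lab))
  if (blur > 0) img <- smooth_gauss(img, blur)
  if (noise_sd > 0) img <- img + array(rnorm(length(img), sd = noise_sd), dim = dim(lab))
  img
}

#' Generate one multimodal phantom pair with known deformation
#'
#' Builds the anatomy, draws the ground-truth displacement field on the fixed
#' grid, warps the anatomy by it to obtain the fixed-image labels, and
#' renders the pseudo-CT (fixed) and pseudo-MR (moving) volumes from their
#' respective intensity tables. By construction, warping the moving label
#' map by `field_true` reproduces the fixed label map exactly, so recovered
#' fields can be scored against a known truth.
#'
#' @param spec a [phantom_spec].
#' @return List of class `wm_phantom_pair`: `fixed`, `moving`
#'   ([wm_volume]s), `fixed_labels`, `moving_labels` ([wm_labelmap]s),
#'   `field_true` ([wm_field]) and `spec`.
#' @export
generate_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "wm_phantomspec"))
  set.seed(spec$seed)
  d <- spec$shape
  anat <- phantom_anatomy(spec)
  u <- array(0, dim = c(d, 3L))
  if (spec$amplitude > 0) {
    u <- random_smooth_field(d, spec$amplitude, spec$smoothness)
  }
  if (spec$organ_expand > 0) {
    g <- identity_grid(d) + 1
    rel <- sweep(g, 2L, anat$bladder_center)
    r <- sqrt(rowSums(rel^2))
    sr <- anat$bladder_radius
    prof <- (r / sr) * exp(0.5 - 0.5 * (r / sr)^2) * spec$organ_expand
    dirv <- rel / pmax(r, 1e-9)
    u <- u + array(dirv * prof, dim = c(d, 3L))
  }
  field <- wm_field(u)
  moving_labels <- wm_labelmap(anat$labels,
                               labels = stats::setNames(as.integer(phantom_label_ids),
                                                        names(phantom_label_ids)))
  fixed_labels <- warp(moving_labels, field)
  moving <- wm_volume(render_modality(moving_labels$data, spec$mr_table,
                                      spec$noise_sd, spec$blur),
                      modality = "pseudo-MR")
  fixed <- wm_volume(render_modality(fixed_labels$data, spec$ct_table,
                                     spec$noise_sd, spec$blur),
                     modality = "pseudo-CT")
  structure(list(fixed = fixed, moving = moving, fixed_labels = fixed_labels,
                 moving_labels = moving_labels, field_true = field, spec = spec),
            class = "wm_phantom_pair")
}

#' Generate a benchmark suite of phantom pairs
#'
#' `n` pairs with consecutive seeds and a deterministic 80/20 train/test
#' split. When `dir` is given, volumes, label maps and fields are written as
#' NIfTI plus a JSON manifest whose recorded seeds regenerate the identical
#' data; otherwise pairs are returned in memory.
#'
#' @param n number of pairs (>= 2).
#' @param spec template [phantom_spec]; per-pair seeds are `seed + 0:(n-1)`.
#' @param seed base seed.
#' @param dir optional output directory.
#' @return List with `pairs` (NULL when written to disk), `manifest`
#'   (data.frame: id, seed, split) and `dir`.
#' @export
benchmark_suite <- function(n, spec = phantom_spec(), seed = 1L, dir = NULL) {
  if (n < 2L) stopf("n must be >= 2")
  seeds <- seed + seq_len(n) - 1L
  split <- rep("train", n)
  ntest <- max(1L, round(n * 0.2))
  split[(n - ntest + 1L):n] <- "test"
  manifest <- data.frame(id = sprintf("pair%03d", seq_len(n)), seed = seeds,
                         split = split, stringsAsFactors = FALSE)
  make <- function(i) {
    sp <- spec
    sp$seed <- seeds[i]
    generate_pair(sp)
  }
  if (is.null(dir)) {
    return(list(pairs = lapply(seq_len(n), make), manifest = manifest, dir = NULL))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n)) {
    p <- make(i)
    base <- file.path(dir, manifest$id[i])
    write_volume(p$fixed, paste0(base, "_fixed.nii.gz"))
    write_volume(p$moving, paste0(base, "_moving.nii.gz"))
    write_volume(p$fixed_labels, paste0(base, "_fixed_labels.nii.gz"))
    write_volume(p$moving_labels, paste0(base, "_moving_labels.nii.gz"))
    write_field(p$field_true, paste0(base, "_field.nii.gz"))
  }
  jsonlite::write_json(list(spec = unclass(spec)[setdiff(names(unclass(spec)),
                                                         c("ct_table", "mr_table"))],
                            entries = manifest),
                       file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  list(pairs = NULL, manifest = manifest, dir = dir)
}
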
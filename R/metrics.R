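# Registration quality metrics: Dice similarity coefficient, average
# symmetric surface distance, and the Jacobian folding summary.

label_mask <- function(x, label) {
  arr <- if (inherits(x, "wm_labelmap")) x$data else x
  arr == label
}

#' Dice similarity coefficient for one label
#'
#' `2 |A ∩ B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [wm_labelmap]s or integer arrays of the same shape.
#' @param label label id to compare.
#' @return DSC in \[0, 1\].
#' @export
dsc <- function(a, b, label = 1L) {
  ma <- label_mask(a, label); mb <- label_mask(b, label)
  if (!all(dim(ma) == dim(mb))) stopf("shape mismatch")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0L) return(1)
  2 * sum(ma & mb) / (sa + sb)
}

# Boundary voxels of a mask: mask voxels with a 6-neighbour outside the mask
# (the volume border counts as outside).
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift <- function(m, ax, by) {
    out <- array(FALSE, dim = d)
    n <- d[ax]
    src <- seq_len(n) - by
    ok <- src >= 1 & src <= n
    idx_dst <- lapply(d, seq_len); idx_src <- lapply(d, seq_len)
    idx_dst[[ax]] <- which(ok); idx_src[[ax]] <- src[ok]
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) interior <- interior & shift(mask, ax, by)
  which(mask & !interior, arr.ind = TRUE)
}

#' Average symmetric surface distance for one label
#'
#' Mean of nearest-surface distances in both directions between the boundary
#' voxel sets (6-connectivity surface definition), in mm using the voxel
#' spacing.
#'
#' @param a,b [wm_labelmap]s or integer arrays of the same shape.
#' @param label label id.
#' @param spacing mm per voxel (taken from `a` if it is a [wm_labelmap]).
#' @return ASSD in mm (>= 0).
#' @export
assd <- function(a, b, label = 1L, spacing = NULL) {
  if (is.null(spacing)) spacing <- if (inherits(a, "wm_labelmap")) a$spacing else c(1, 1, 1)
  ma <- label_mask(a, label); mb <- label_mask(b, label)
  if (!all(dim(ma) == dim(mb))) stopf("shape mismatch")
  if (!any(ma)) stopf("label %s empty in first map", label)
  if (!any(mb)) stopf("label %s empty in second map", label)
  sa <- surface_voxels(ma); sb <- surface_voxels(mb)
  storage.mode(sa) <- "double"; storage.mode(sb) <- "double"
  dab <- cpp_min_dists(sa, sb, as.double(spacing))
  dba <- cpp_min_dists(sb, sa, as.double(spacing))
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

#' Per-label registration quality report
#'
#' Assembles, for every label present in either map, pre-registration DSC
#' (fixed vs. moving), post-registration DSC and ASSD (fixed vs. warped
#' moving), and the global Jacobian folding percentage of the displacement
#' field. Labels present in only one of the maps are flagged in the `status`
#' column rather than dropped.
#'
#' @param fixed_labels fixed-image [wm_labelmap].
#' @param moving_labels moving-image [wm_labelmap].
#' @param field final [wm_field] (full resolution).
#' @param warped_labels optional pre-computed warped moving labels; computed
#'   by nearest-neighbour warping when omitted.
#' @return Object of class `wm_metrics`: list with `table` (data.frame) and
#'   `jd_nonpositive_pct`.
#' @export
metrics_report <- function(fixed_labels, moving_labels, field, warped_labels = NULL) {
  stopifnot(inherits(fixed_labels, "wm_labelmap"), inherits(moving_labels, "wm_labelmap"))
  if (!all(dim(fixed_labels$data) == dim(moving_labels$data))) stopf("label map shape mismatch")
  if (is.null(warped_labels)) warped_labels <- warp(moving_labels, field)
  ids <- sort(union(setdiff(unique(as.vector(fixed_labels$data)), 0L),
                    setdiff(unique(as.vector(moving_labels$data)), 0L)))
  rows <- lapply(ids, function(id) {
    in_f <- any(fixed_labels$data == id)
    in_m <- any(moving_labels$data == id)
    status <- if (in_f && in_m) "ok" else if (in_f) "missing_in_moving" else "missing_in_fixed"
    pre <- dsc(fixed_labels, moving_labels, id)
    post <- dsc(fixed_labels, warped_labels, id)
    a_mm <- if (in_f && any(warped_labels$data == id)) {
      assd(fixed_labels, warped_labels, id, spacing = fixed_labels$spacing)
    } else NA_real_
    name <- names(fixed_labels$labels)[match(id, fixed_labels$labels)]
    if (is.na(name) || is.null(name)) name <- paste0("label", id)
    data.frame(label = id, name = name, status = status,
               dsc_pre = pre, dsc_post = post, dsc_gain = post - pre,
               assd_mm = a_mm, stringsAsFactors = FALSE)
  })
  jd <- jacobian_nonpositive_fraction(field)
  structure(list(table = do.call(rbind, rows),
                 jd_nonpositive_pct = 100 * jd$fraction),
            class = "wm_metrics")
}

#' @export
print.wm_metrics <- function(x, ...) {
  cat("Registration metrics\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("JD<=0: %.3f%% of interior voxels\n", x$jd_nonpositive_pct))
  invisible(x)
}

#' Serialize / deserialize a metrics report as JSON
#'
#' @param x a `wm_metrics` object.
#' @param path output path.
#' @return `path` invisibly, or the recovered `wm_metrics` for the reader.
#' @export
write_metrics <- function(x, path) {
  stopifnot(inherits(x, "wm_metrics"))
  jsonlite::write_json(list(table = x$table, jd_nonpositive_pct = x$jd_nonpositive_pct),
                       path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Aggregate metrics reports across registration cases
#'
#' Binds the per-label tables of several `wm_metrics` objects into one data
#' frame with a case identifier, suitable for CSV export.
#'
#' @param reports named list of `wm_metrics` objects (names become case ids).
#' @param path optional CSV output path.
#' @return The combined data.frame, invisibly when written to `path`.
#' @export
aggregate_metrics <- function(reports, path = NULL) {
  if (is.null(names(reports))) names(reports) <- sprintf("case%03d", seq_along(reports))
  out <- do.call(rbind, lapply(names(reports), function(nm) {
    tb <- reports[[nm]]$table
    cbind(case = nm, tb, jd_nonpositive_pct = reports[[nm]]$jd_nonpositive_pct)
  }))
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = as.data.frame(obj$table, stringsAsFactors = FALSE),
                 jd_nonpositive_pct = as.numeric(obj$jd_nonpositive_pct)),
            class = "wm_metrics")
}
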
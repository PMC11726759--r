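# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_dyadic_compatible <- function(shape, levels) all(shape %% (2^levels) == 0)

# 0-based identity voxel grid as an n x 3 matrix, column-major voxel order
# (first axis fastest), cached per shape.
.grid_cache <- new.env(parent = emptyenv())
identity_grid <- function(shape) {
  key <- paste(shape, collapse = "x")
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    h <- shape[1]; w <- shape[2]; l <- shape[3]
    g <- cbind(
      rep.int(seq_len(h) - 1, w * l),
      rep.int(rep(seq_len(w) - 1, each = h), l),
      rep(seq_len(l) - 1, each = h * w)
    )
    storage.mode(g) <- "double"
    .grid_cache[[key]] <- g
  }
  g
}

# Sampling coordinates for a trilinear resize (corner-aligned; degenerate
# output axes sample the input centre).
resize_coords <- function(in_shape, out_shape) {
  ax <- function(a) {
    if (out_shape[a] == 1) return(rep((in_shape[a] - 1) / 2, 1))
    (seq_len(out_shape[a]) - 1) * (in_shape[a] - 1) / (out_shape[a] - 1)
  }
  x <- ax(1); y <- ax(2); z <- ax(3)
  cbind(
    rep.int(x, length(y) * length(z)),
    rep.int(rep(y, each = length(x)), length(z)),
    rep(z, each = length(x) * length(y))
  )
}

# Trilinear resize of an [H,W,L] or [H,W,L,C] array.
resize_array <- function(x, out_shape) {
  d <- dim(x)
  ch <- if (length(d) == 4) d[4] else 1L
  in_shape <- d[1:3]
  if (all(in_shape == out_shape)) return(x)
  co <- resize_coords(in_shape, out_shape)
  v <- cpp_sample3(as.double(x), as.integer(c(in_shape, ch)), co, FALSE)
  dim(v) <- if (length(d) == 4) c(out_shape, ch) else out_shape
  v
}

# Average-pool an [H,W,L] or [H,W,L,C] array by an integer factor per axis.
pool_array <- function(x, factor) {
  d <- dim(x)
  in_shape <- d[1:3]
  f <- rep(factor, length.out = 3)
  f <- pmin(f, in_shape)
  out <- floor(in_shape / f)
  resize_array(x, pmax(out, 1L))
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= .Machine$double.eps) return(array(0, dim = dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Per-axis central differences (forward/backward at the boundary) of a 3D
# array; returns the derivative along `axis` with the same shape.
axis_cdiff <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  if (n == 1) return(array(0, dim = d))
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  denom <- idx_p - idx_m
  take <- function(i) {
    switch(axis, x[i, , , drop = FALSE], x[, i, , drop = FALSE], x[, , i, drop = FALSE])
  }
  out <- (take(idx_p) - take(idx_m))
  sweepdim <- array(rep(denom, times = prod(d) / n), dim = d[c(axis, setdiff(1:3, axis))])
  out / aperm(sweepdim, order(c(axis, setdiff(1:3, axis))))
}

grad_magnitude <- function(x) {
  sqrt(axis_cdiff(x, 1)^2 + axis_cdiff(x, 2)^2 + axis_cdiff(x, 3)^2)
}

# Gaussian smoothing of a 3D array via normalized box-free separable
# convolution (zero-pad + renormalisation, so borders are unbiased).
smooth_gauss <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  rad <- max(1L, ceiling(2.5 * sigma))
  for (ax in 1:3) {
    k <- min(rad, d[ax] - 1L)
    if (k < 1) next
    ker <- exp(-((-k:k)^2) / (2 * sigma^2))
    kd <- c(1L, 1L, 1L); kd[ax] <- 2L * k + 1L
    pad <- c(0L, 0L, 0L); pad[ax] <- k
    w <- array(ker, dim = c(kd, 1L, 1L))
    ones <- array(1, dim = c(d, 1L))
    num <- cpp_conv3_fwd(as.double(x), as.integer(c(d, 1L)), as.double(w),
                         as.integer(dim(w)), 0, c(1L, 1L, 1L), as.integer(pad))
    den <- cpp_conv3_fwd(as.double(ones), as.integer(c(d, 1L)), as.double(w),
                         as.integer(dim(w)), 0, c(1L, 1L, 1L), as.integer(pad))
    x <- array(num / den, dim = d)
  }
  x
}
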
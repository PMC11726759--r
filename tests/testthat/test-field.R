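test_that("warping with a zero field is the identity for both interpolations", {
  set.seed(3)
  d <- c(6L, 5L, 4L)
  v <- array(rnorm(prod(d)), dim = d)
  f0 <- zero_field(d)
  expect_equal(warp(v, f0, "trilinear"), v)
  expect_equal(warp(v, f0, "nearest"), v)
})

test_that("a constant integer field shifts voxels exactly (index-shift oracle)", {
  set.seed(4)
  d <- c(6L, 5L, 4L)
  v <- array(rnorm(prod(d)), dim = d)
  w <- warp(v, const_field(d, c(1, 0, 0)))
  # interior: out[i,j,k] == in[i+1,j,k]; last slice clamps
  expect_equal(w[1:5, , ], v[2:6, , ])
  expect_equal(w[6, , ], v[6, , ])
  w2 <- warp(v, const_field(d, c(0, 2, -1)))
  expect_equal(w2[, 1:3, 2:4], v[, 3:5, 1:3])
})

test_that("label warping never invents labels and stays integer", {
  set.seed(5)
  d <- c(8L, 8L, 4L)
  lab <- wm_labelmap(array(sample(c(0L, 2L, 7L), prod(d), replace = TRUE), dim = d))
  f <- wm_field(array(runif(prod(d) * 3, -1.5, 1.5), dim = c(d, 3L)))
  wl <- warp(lab, f)
  expect_true(all(wl$data %in% c(0L, 2L, 7L)))
  expect_type(wl$data, "integer")
  expect_error(warp(array(0, c(4, 4, 4)), f), "mismatch")
})

test_that("composition follows result(x) = outer(x + inner(x)) + inner(x)", {
  d <- c(6L, 6L, 4L)
  fa <- const_field(d, c(1, 0.5, 0))
  fb <- const_field(d, c(0.25, -0.5, 1))
  z <- zero_field(d)
  expect_equal(compose_fields(fa, z)$vectors, fa$vectors)
  expect_equal(compose_fields(z, fb)$vectors, fb$vectors)
  # two constant translations compose to their sum; cross-check by warping
  comp <- compose_fields(fa, fb)
  expect_lt(max(abs(sweep(matrix(comp$vectors, ncol = 3), 2, c(1.25, 0, 1)))), 1e-12)
  # exact cross-check with integer translations (no interpolation error)
  fi <- const_field(d, c(1, 0, 0))
  fj <- const_field(d, c(0, 2, -1))
  v <- smooth_volume(d, seed = 6)
  two_step <- warp(warp(v, fi), fj)
  one_step <- warp(v, compose_fields(fi, fj))
  expect_lt(max(abs(one_step[1:5, 1:3, 2:4] - two_step[1:5, 1:3, 2:4])), 1e-12)
})

test_that("composition is associative on smooth fields within interpolation error", {
  set.seed(8)
  d <- c(16L, 16L, 8L)
  mk <- function(s) {
    u <- array(0, dim = c(d, 3L))
    for (a in 1:3) u[, , , a] <- wm$smooth_gauss(array(rnorm(prod(d)), dim = d), 4) * s
    wm_field(u)
  }
  f1 <- mk(2); f2 <- mk(2); f3 <- mk(2)
  left <- compose_fields(compose_fields(f1, f2), f3)
  right <- compose_fields(f1, compose_fields(f2, f3))
  expect_lt(mean(abs(left$vectors - right$vectors)), 1e-3)
})

test_that("field upsampling rescales magnitudes with the grid", {
  d <- c(4L, 4L, 4L)
  c2 <- const_field(d, c(0.5, 1, -0.25))
  up <- upsample_field(c2, 2)
  expect_equal(up$shape, d * 2L)
  expect_lt(max(abs(sweep(matrix(up$vectors, ncol = 3), 2, c(1, 2, -0.5)))), 1e-12)
  expect_equal(max(abs(upsample_field(zero_field(d), 3)$vectors)), 0)
  expect_error(upsample_field(c2, 1), "factor")
})

test_that("multi-resolution warping is consistent across grids", {
  # warping the fine image with the upsampled field should approximate
  # warping the coarse image with the original field, after downsampling
  d <- c(8L, 8L, 8L)
  vf <- smooth_volume(d * 2L, seed = 9)
  vc <- wm$resize_array(vf, d)
  set.seed(10)
  u <- array(0, dim = c(d, 3L))
  for (a in 1:3) u[, , , a] <- wm$smooth_gauss(array(rnorm(prod(d)), dim = d), 2.5)
  f <- wm_field(u / max(abs(u)) * 1.5)
  coarse_warp <- warp(vc, f)
  fine_warp <- wm$resize_array(warp(vf, upsample_field(f, 2)), d)
  rel <- sqrt(sum((coarse_warp - fine_warp)^2)) / sqrt(sum(coarse_warp^2))
  expect_lt(rel, 0.05)
})

test_that("Jacobian determinants match closed forms for linear fields", {
  d <- c(8L, 8L, 8L)
  jd0 <- jacobian_nonpositive_fraction(zero_field(d))
  expect_equal(jd0$fraction, 0)
  expect_lt(max(abs(jd0$det - 1)), 1e-12)

  g <- wm$identity_grid(d)
  iso <- wm_field(array(0.1 * g, dim = c(d, 3L)))
  jd1 <- jacobian_nonpositive_fraction(iso)
  expect_lt(max(abs(jd1$det[2:7, 2:7, 2:7] - 1.1^3)), 1e-6)
  expect_equal(jd1$fraction, 0)

  fold <- wm_field(array(c(-2 * g[, 1], 0 * g[, 2], 0 * g[, 3]), dim = c(d, 3L)))
  jd2 <- jacobian_nonpositive_fraction(fold)
  expect_equal(jd2$fraction, 1)
  expect_lt(max(abs(jd2$det[2:7, 2:7, 2:7] + 1)), 1e-12)

  # invariance to a constant translation
  set.seed(12)
  u <- array(0, dim = c(d, 3L))
  for (a in 1:3) u[, , , a] <- wm$smooth_gauss(array(rnorm(prod(d)), dim = d), 2)
  f <- wm_field(u)
  ft <- wm_field(sweep(u, 4, c(3, -2, 1), `+`))
  expect_equal(jacobian_nonpositive_fraction(f)$fraction,
               jacobian_nonpositive_fraction(ft)$fraction)
})

test_that("fields round-trip through 4D NIfTI", {
  d <- c(5L, 6L, 4L)
  f <- wm_field(array(rnorm(prod(d) * 3), dim = c(d, 3L)))
  p <- tempfile(fileext = ".nii.gz")
  write_field(f, p)
  r <- read_field(p)
  expect_lt(max(abs(r$vectors - f$vectors)), 1e-6)
})
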
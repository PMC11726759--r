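# Gradient correctness of the tape engine against central finite differences.
# Constants used inside each graph are fixed outside the closure so repeated
# evaluations see the same function.

test_that("elementwise, linear-algebra and normalization ops backpropagate correctly", {
  set.seed(41)
  tok <- matrix(rnorm(24 * 8), 24, 8)
  Wc <- matrix(rnorm(8 * 6, sd = 0.3), 8, 6)
  bc <- rnorm(6)
  gm <- rep(1, 8) + 0.1 * rnorm(8)
  bt <- 0.1 * rnorm(8)
  err <- fd_gradcheck(function(t, x) {
    y <- wm$op_layernorm(t, x, wm$ad_input(t, gm), wm$ad_input(t, bt))
    y <- wm$op_gelu(t, y)
    y <- wm$op_bias(t, wm$op_matmul(t, y, wm$ad_input(t, Wc)), wm$ad_input(t, bc))
    y <- wm$op_lrelu(t, y)
    wm$op_mean(t, wm$op_sq(t, y))
  }, tok)
  expect_lt(err, 1e-6)

  cube <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  other <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  err2 <- fd_gradcheck(function(t, x) {
    sc <- wm$op_bmm(t, x, wm$ad_input(t, other), tB = TRUE)
    at <- wm$op_softmax2(t, sc)
    ct <- wm$op_bmm(t, at, x)
    wm$op_mean(t, wm$op_abs(t, ct))
  }, cube)
  expect_lt(err2, 1e-6)

  # reshape / permute / slice / concat / roll round trip gradients
  arr <- array(rnorm(4 * 4 * 2 * 3), dim = c(4, 4, 2, 3))
  err3 <- fd_gradcheck(function(t, x) {
    y <- wm$op_aperm(t, x, c(2, 1, 3, 4))
    y <- wm$op_aperm(t, y, c(2, 1, 3, 4))
    y <- wm$op_roll3(t, y, c(1, -2, 1))
    a <- wm$op_slice_last(t, y, 1, 2)
    b <- wm$op_slice_last(t, y, 3, 3)
    y <- wm$op_cat_last(t, list(a, b))
    wm$op_mean(t, wm$op_sq(t, y))
  }, arr)
  expect_lt(err3, 1e-7)
})

test_that("convolution, sampling and warping kernels backpropagate correctly", {
  set.seed(42)
  x0 <- array(rnorm(6 * 6 * 4 * 2), dim = c(6, 6, 4, 2))
  w0 <- array(rnorm(27 * 2 * 3, sd = 0.3), dim = c(3, 3, 3, 2, 3))
  b0 <- rnorm(3)
  build <- function(t, x) {
    wn <- wm$ad_input(t, w0); bn <- wm$ad_input(t, b0)
    wm$op_mean(t, wm$op_sq(t, wm$op_conv3(t, x, wn, bn)))
  }
  expect_lt(fd_gradcheck(build, x0), 1e-8)
  buildw <- function(t, w) {
    xn <- wm$ad_input(t, x0); bn <- wm$ad_input(t, b0)
    wm$op_mean(t, wm$op_sq(t, wm$op_conv3(t, xn, w, bn)))
  }
  expect_lt(fd_gradcheck(buildw, w0), 1e-8)
  # strided variant
  expect_lt(fd_gradcheck(function(t, x) {
    wn <- wm$ad_input(t, w0); bn <- wm$ad_input(t, b0)
    wm$op_mean(t, wm$op_sq(t, wm$op_conv3(t, x, wn, bn, stride = 2L, pad = 1L)))
  }, x0), 1e-8)

  img0 <- array(rnorm(6 * 6 * 4 * 2), dim = c(6, 6, 4, 2))
  phi0 <- array(runif(6 * 6 * 4 * 3, -0.8, 0.8), dim = c(6, 6, 4, 3))
  expect_lt(fd_gradcheck(function(t, phi) {
    xn <- wm$ad_input(t, img0)
    wm$op_mean(t, wm$op_sq(t, wm$op_warp(t, xn, phi)))
  }, phi0, eps = 1e-5), 1e-6)
  expect_lt(fd_gradcheck(function(t, x) {
    pn <- wm$ad_input(t, phi0)
    wm$op_mean(t, wm$op_sq(t, wm$op_warp(t, x, pn)))
  }, img0), 1e-8)
  expect_lt(fd_gradcheck(function(t, x) {
    wm$op_mean(t, wm$op_sq(t, wm$op_resize3(t, x, c(9L, 5L, 7L))))
  }, img0), 1e-8)
})

test_that("loss building blocks (smoothness, local NCC) backpropagate correctly", {
  set.seed(43)
  phi0 <- array(rnorm(6 * 6 * 4 * 3), dim = c(6, 6, 4, 3))
  expect_lt(fd_gradcheck(function(t, p) wm$op_smoothness(t, p), phi0), 1e-7)

  a0 <- array(runif(8 * 8 * 6), dim = c(8, 8, 6))
  b0 <- array(runif(8 * 8 * 6), dim = c(8, 8, 6))
  expect_lt(fd_gradcheck(function(t, a) {
    wm$ncc_tape(t, a, wm$ad_input(t, b0), win = 5)
  }, a0), 1e-6)
  # the tape value agrees with the plain implementation
  t2 <- wm$ad_tape()
  v <- wm$ncc_tape(t2, wm$ad_input(t2, a0), wm$ad_input(t2, b0), win = 5)
  expect_equal(v$v, ncc(a0, b0, win = 5))
})

test_that("gradient flow respects constant leaves and accumulates shared weights", {
  set.seed(44)
  x0 <- matrix(rnorm(12), 4, 3)
  tape <- wm$ad_tape()
  ps <- wm$param_set(); ps[["w"]] <- matrix(rnorm(9), 3, 3)
  wn <- wm$ad_weight(tape, ps, "w")
  cn <- wm$ad_input(tape, x0)
  # use the same weight twice: gradient must be the sum of both paths
  y1 <- wm$op_matmul(tape, cn, wn)
  y2 <- wm$op_matmul(tape, cn, wm$ad_weight(tape, ps, "w"))
  out <- wm$op_mean(tape, wm$op_sq(tape, wm$op_add(tape, y1, y2)))
  wm$ad_backward(tape, out)
  expect_false(isTRUE(cn$rq))
  expect_null(cn$g)
  ga <- tape$wnodes[["w"]]$g
  # finite difference on the shared weight
  f <- function(W) mean(((x0 %*% W) + (x0 %*% W))^2)
  i <- which.max(abs(ga)); eps <- 1e-6
  Wp <- ps[["w"]]; Wp[i] <- Wp[i] + eps
  Wq <- ps[["w"]]; Wq[i] <- Wq[i] - eps
  expect_lt(abs(ga[i] - (f(Wp) - f(Wq)) / (2 * eps)), 1e-7)
})
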
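test_that("ball elements have the documented support and symmetry", {
  b1 <- ball_element(1)
  expect_equal(dim(b1), c(3L, 3L, 3L))
  # radius 1 keeps exactly the 7-voxel 3D cross (exhaustive distance check)
  off <- expand.grid(-1:1, -1:1, -1:1)
  expect_equal(sum(b1), sum(sqrt(rowSums(off^2)) <= 1))
  expect_equal(sum(b1), 7)
  expect_true(b1[2, 2, 2] && b1[1, 2, 2] && b1[2, 1, 2] && b1[2, 2, 1])
  expect_false(b1[1, 1, 2])

  b3 <- ball_element(3)
  expect_equal(dim(b3), rep(2L * 3L + 1L, 3))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    expect_equal(aperm(b3, perm), b3)
  }
  expect_equal(b3[7:1, , ], b3)          # reflection symmetry
  expect_error(ball_element(0), "radius")

  d2 <- ball_element(2, slicewise = TRUE)
  expect_equal(dim(d2), c(5L, 5L, 1L))
})

test_that("erode/dilate equal the brute-force min/max oracle on small grids", {
  set.seed(21)
  x <- array(runif(6 * 6 * 6), dim = c(6, 6, 6))
  for (r in c(1, 2, 3)) {
    el <- ball_element(r)
    off <- wm$element_offsets(el)
    expect_equal(erode(x, el), brute_morph(x, off, FALSE))
    expect_equal(dilate(x, el), brute_morph(x, off, TRUE))
  }
  # constants are fixed points; closing/opening bounds hold pointwise
  cst <- array(2.5, dim = c(6, 6, 6))
  el <- ball_element(2)
  expect_equal(erode(cst, el), cst)
  expect_equal(dilate(cst, el), cst)
  expect_true(all(erode(dilate(x, el), el) >= x - 1e-12))
  expect_true(all(dilate(erode(x, el), el) <= x + 1e-12))
  # single bright voxel dilates to the 7-voxel cross
  pt <- array(0, dim = c(5, 5, 5)); pt[3, 3, 3] <- 1
  dl <- dilate(pt, ball_element(1))
  expect_equal(sum(dl), 7)
  expect_equal(dl[3, 3, 3], 1); expect_equal(dl[2, 3, 3], 1); expect_equal(dl[3, 3, 2], 1)
})

test_that("structuring pairs build a ring plus intermediate ball", {
  p <- structuring_pair(5, 3)
  expect_equal(p$mid, 4L)
  expect_equal(p$ring_width, 2L)
  dist <- sqrt(rowSums(p$ring_offsets^2))
  expect_true(all(dist > 3 & dist <= 5))
  expect_error(structuring_pair(3, 3), "exceed")
  expect_error(structuring_pair(2, 0), ">= 1")
})

test_that("dual operators match their brute-force composition for all study radii", {
  set.seed(22)
  x <- array(runif(8 * 8 * 8), dim = c(8, 8, 8))
  for (r in c(3, 5, 6, 7, 9)) {
    p <- structuring_pair(r, max(1, r - 2))
    ring <- p$ring_offsets
    mid <- p$mid_offsets
    do_ref <- brute_morph(brute_morph(x, ring, TRUE), mid, FALSE)
    dc_ref <- brute_morph(brute_morph(x, ring, FALSE), mid, TRUE)
    expect_equal(dual_open(x, p), do_ref, info = paste("radius", r))
    expect_equal(dual_close(x, p), dc_ref, info = paste("radius", r))
    expect_equal(white_tophat_dual(x, p), x - do_ref)
    expect_equal(black_tophat_dual(x, p), dc_ref - x)
    # order-statistic envelope: no overshoot
    expect_true(all(dual_open(x, p) >= min(x) - 1e-12 & dual_open(x, p) <= max(x) + 1e-12))
  }
})

test_that("dual opening differs from plain opening by the outer ball", {
  set.seed(23)
  x <- array(runif(10 * 10 * 6), dim = c(10, 10, 6))
  p <- structuring_pair(3, 1)
  ball_off <- wm$element_offsets(ball_element(3))
  plain_open <- brute_morph(brute_morph(x, ball_off, FALSE), ball_off, TRUE)
  expect_gt(max(abs(dual_open(x, p) - plain_open)), 1e-6)
})

test_that("top-hats vanish on constants and ignore intensity offsets", {
  p <- structuring_pair(3, 1)
  cst <- array(4, dim = c(8, 8, 8))
  expect_true(all(white_tophat_dual(cst, p) == 0))
  expect_true(all(black_tophat_dual(cst, p) == 0))
  set.seed(24)
  x <- array(runif(8 * 8 * 8), dim = c(8, 8, 8))
  expect_equal(white_tophat_dual(x + 5, p), white_tophat_dual(x, p))
  expect_equal(black_tophat_dual(x + 5, p), black_tophat_dual(x, p))
  # a bright spot narrower than the ring shows up in the white top-hat
  blob <- array(0, dim = c(8, 8, 8))
  blob[4, 4, 4] <- 1
  wth <- white_tophat_dual(blob, p)
  expect_gt(wth[4, 4, 4], 0)
})
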
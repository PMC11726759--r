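test_that("spatial transforms honour identity, translation and determinism", {
  v <- smooth_volume(c(16, 16, 8), seed = 61)
  expect_lt(max(abs(apply_transform(v, identity_transform()) - v)), 1e-6)

  # pure translation matches the integer index-shift oracle in the interior
  tr <- identity_transform()
  tr$trans <- c(2, 0, 0)
  w <- apply_transform(v, tr)
  expect_lt(max(abs(w[1:14, , ] - v[3:16, , ])), 1e-12)

  t1 <- sample_transform(seed = 62)
  t2 <- sample_transform(seed = 62)
  t3 <- sample_transform(seed = 63)
  expect_identical(t1, t2)
  expect_false(identical(t1$trans, t3$trans))
  expect_identical(apply_transform(v, t1), apply_transform(v, t2))
  expect_true(all(abs(t1$rot) <= 3) && all(abs(t1$trans) <= 3) &&
                t1$scale >= 0.92 && t1$scale <= 1.08)
})

test_that("evaluator samples pair a corrupted image with an uncorrupted label", {
  v <- smooth_volume(c(16, 16, 8), seed = 64)
  s <- make_sample(v, seed = 65)
  expect_equal(dim(s$input), c(16L, 16L, 8L, 2L))
  expect_gte(s$target, 0)
  # the target is computed from the uncorrupted M1/M2 pair
  m1 <- apply_transform(v, s$meta$k1)
  m2 <- apply_transform(v, s$meta$k2)
  expect_equal(s$target, mean(abs(m2 - m1)))
  expect_equal(s$input[, , , 1], m2)
  # channel 2 carries the corruption, so it differs from plain M1
  expect_gt(mean(abs(s$input[, , , 2] - m1)), 1e-3)
  # reproducibility from the seed
  s2 <- make_sample(v, seed = 65)
  expect_identical(s2$input, s$input)
  expect_identical(s2$target, s$target)
})

test_that("spatial-error targets grow with the transform gap", {
  v <- smooth_volume(c(24, 24, 8), seed = 66)
  gaps <- 0:3
  targets <- vapply(gaps, function(g) {
    k1 <- identity_transform()
    k2 <- identity_transform()
    k2$trans <- c(g, 0, 0)
    m1 <- apply_transform(v, k1)
    m2 <- apply_transform(v, k2)
    mean(abs(m2 - m1))
  }, 1)
  expect_true(all(diff(targets) > 0))
  expect_equal(targets[1], 0)
})

test_that("a constant-zero-target dataset trains to near-zero predictions", {
  v <- smooth_volume(c(12, 12, 8), seed = 67)
  samples <- lapply(1:6, function(i) {
    s <- make_sample(v, seed = 70 + i)
    # identical transforms: spatial error identically zero
    s$input[, , , 1] <- v
    s$target <- 0
    s
  })
  ev <- train_evaluator(samples, epochs = 30, lr = 3e-3, seed = 68,
                        cfg = evaluator_config(channels = 4, pool_in = 1))
  preds <- vapply(samples, function(s) evaluator_predict(ev, s$input[, , , 1], s$input[, , , 2]), 1)
  expect_lt(mean(abs(preds)), 1e-2)
  expect_true(all(is.finite(preds)) && all(preds >= 0))
})

test_that("local NCC has the documented fixed points and invariances", {
  set.seed(69)
  a <- array(runif(10 * 10 * 8), dim = c(10, 10, 8))
  b <- array(runif(10 * 10 * 8), dim = c(10, 10, 8))
  expect_lt(abs(ncc(a, a)), 1e-6)
  expect_lt(abs(ncc(a, 1.7 * a + 0.4)), 1e-6)   # affine intensity invariance
  expect_gt(ncc(a, b), 0.5)                      # unrelated images score high
  expect_error(ncc(a, array(0, dim = c(4, 4, 4))), "mismatch")
})

test_that("evaluator checkpoints round-trip through JSON text", {
  v <- smooth_volume(c(12, 12, 8), seed = 70)
  samples <- lapply(1:3, function(i) make_sample(v, seed = 80 + i))
  ev <- train_evaluator(samples, epochs = 1, seed = 71,
                        cfg = evaluator_config(channels = 4))
  p <- tempfile(fileext = ".json")
  write_evaluator(ev, p)
  ev2 <- read_evaluator(p)
  x <- samples[[1]]
  expect_equal(evaluator_predict(ev2, x$input[, , , 1], x$input[, , , 2]),
               evaluator_predict(ev, x$input[, , , 1], x$input[, , , 2]),
               tolerance = 1e-12)
})
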
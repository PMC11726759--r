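test_that("one decomposition level yields 8 named subbands, 7 high-frequency", {
  v <- array(rnorm(8 * 8 * 8), dim = c(8, 8, 8))
  tree <- dwt3_level(v, "db5", 1)
  expect_length(tree, 1)
  bands <- tree[[1]]$bands
  expect_length(bands, 8)
  expect_setequal(names(bands),
                  c("aaa", "aad", "ada", "add", "daa", "dad", "dda", "ddd"))
  expect_length(setdiff(names(bands), "aaa"), 7)
  # every band has half the parent resolution per axis
  for (b in bands) expect_equal(dim(b), c(4L, 4L, 4L))
})

test_that("high-pass bands of a constant volume vanish (vanishing moments)", {
  tree <- dwt3_level(array(5, dim = c(8, 8, 8)), "db5", 1)
  for (code in setdiff(names(tree[[1]]$bands), "aaa")) {
    expect_lt(max(abs(tree[[1]]$bands[[code]])), 1e-10)
  }
})

test_that("the filter bank reconstructs perfectly and preserves energy", {
  set.seed(11)
  for (wname in c("db1", "db2", "db5")) {
    x <- array(rnorm(16^3), dim = c(16, 16, 16))
    tree <- dwt3_level(x, wname, 2)
    xr <- idwt3_level(tree, wname)
    expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
    # orthonormality: subband energy equals input energy
    e_sub <- sum(vapply(tree[[1]]$bands[-1], function(b) sum(b^2), 1)) +
      sum(vapply(tree[[2]]$bands, function(b) sum(b^2), 1))
    expect_lt(abs(e_sub / sum(x^2) - 1), 1e-6)
  }
})

test_that("level-k band shapes halve per axis and aaa chains levels", {
  x <- array(rnorm(16 * 8 * 8), dim = c(16, 8, 8))
  tree <- dwt3_level(x, "db2", 3)
  expect_equal(tree[[1]]$shape, c(8L, 4L, 4L))
  expect_equal(tree[[2]]$shape, c(4L, 2L, 2L))
  expect_equal(tree[[3]]$shape, c(2L, 1L, 1L))
  # level-2 decomposition of the level-1 aaa equals the stored level-2 bands
  again <- dwt3_level(tree[[1]]$bands$aaa, "db2", 1)
  expect_equal(again[[1]]$bands$ddd, tree[[2]]$bands$ddd)
  expect_error(dwt3_level(array(0, dim = c(6, 8, 8)), "db2", 3), "divisible")
  expect_error(dwt3_level(x, "nosuchwavelet", 1), "unknown wavelet")
})

test_that("enhancement image sums per-band gradient magnitudes", {
  zero_bands <- dwt3_level(array(rnorm(16^3), dim = c(16, 16, 16)), "db1", 1)[[1]]
  for (code in names(zero_bands$bands)) {
    zero_bands$bands[[code]] <- array(0, dim = c(8, 8, 8))
  }
  e0 <- enhance_highfreq(zero_bands, renormalize = FALSE)
  expect_true(all(e0$data == 0))

  # one band a linear ramp of slope 3 along x -> E constant 3 everywhere
  # (one-sided differences at the boundary reproduce the same slope)
  sub <- zero_bands
  sub$bands$aad <- array(rep(3 * (0:7)), dim = c(8, 8, 8))
  e <- enhance_highfreq(sub, renormalize = FALSE)
  expect_lt(max(abs(e$data - 3)), 1e-12)

  # permuting the 7 high-frequency band labels leaves E unchanged
  set.seed(2)
  sub2 <- zero_bands
  hf <- setdiff(names(sub2$bands), "aaa")
  for (code in hf) sub2$bands[[code]] <- array(rnorm(512), dim = c(8, 8, 8))
  e1 <- enhance_highfreq(sub2, renormalize = FALSE)
  sub3 <- sub2
  sub3$bands[hf] <- sub2$bands[sample(hf)]
  e2 <- enhance_highfreq(sub3, renormalize = FALSE)
  expect_equal(e1$data, e2$data)
  expect_true(min(e1$data) >= 0)

  # E of the original image is invariant to adding an intensity constant
  x <- array(runif(16^3), dim = c(16, 16, 16))
  ea <- enhance_highfreq(dwt3_level(x, "db5", 1)[[1]], renormalize = FALSE)
  eb <- enhance_highfreq(dwt3_level(x + 11, "db5", 1)[[1]], renormalize = FALSE)
  expect_lt(max(abs(ea$data - eb$data)), 1e-8)

  sub_missing <- sub2
  sub_missing$bands$dad <- NULL
  expect_error(enhance_highfreq(sub_missing))
})

test_that("subband export writes one NIfTI per level and code", {
  dirp <- tempfile()
  tree <- dwt3_level(array(rnorm(8^3), dim = c(8, 8, 8)), "db1", 2)
  export_subbands(tree, dirp)
  files <- list.files(dirp)
  expect_length(files, 16)
  expect_true("1_aaa.nii.gz" %in% files && "2_ddd.nii.gz" %in% files)
  back <- read_volume(file.path(dirp, "2_ddd.nii.gz"))
  expect_lt(max(abs(back$data - tree[[2]]$bands$ddd)), 1e-6)
})
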
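test_that("PSNR matches its closed form and flags identical images", {
  r <- matrix(c(0, 1), 8, 8)
  t <- r + 0.1
  ## range 1, MSE 0.01 -> PSNR = 20 dB
  expect_equal(as.numeric(psnr(r, t)), 20, tolerance = 1e-12)
  expect_identical(as.numeric(psnr(r, r)), Inf)
  expect_equal(attr(psnr(r, t), "dataRange"), 1)
  ## fixed data range overrides the reference range
  expect_equal(as.numeric(psnr(r, t, dataRange = 10)), 40, tolerance = 1e-12)
  expect_error(psnr(matrix(1, 4, 4), matrix(1, 4, 4) + 0.1), "range")
  expect_error(psnr(r, t[1:4, ]), "shape")
})

test_that("SSIM is 1 for identical images and decreases with noise", {
  set.seed(8)
  r <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim(r, r), 1, tolerance = 1e-12)
  small <- ssim(r, r + matrix(rnorm(1024, 0, 0.05), 32, 32))
  large <- ssim(r, r + matrix(rnorm(1024, 0, 0.3), 32, 32))
  expect_lt(small, 1)
  expect_lt(large, small)
  expect_error(ssim(r[1:5, 1:5], r[1:5, 1:5], window = 7), "window")
})

test_that("metric masks restrict the comparison region", {
  set.seed(9)
  r <- matrix(runif(32 * 32), 32, 32)
  t <- r
  mask <- reconMask(32, margin = 1)
  ## corrupt only pixels no masked SSIM window can reach: the mask keeps
  ## centres within radius 15, and a 7x7 window reaches at most 3*sqrt(2)
  ## further, so radius > 19.5 is untouched
  x <- seq_len(32) - 16.5
  far <- outer(x, x, function(a, b) sqrt(a^2 + b^2)) > 19.5
  t[far] <- 0
  expect_identical(as.numeric(psnr(r, t, mask = mask)), Inf)
  expect_equal(ssim(r, t, mask = mask), 1, tolerance = 1e-12)
  expect_lt(as.numeric(psnr(r, t)), Inf)
  expect_lt(ssim(r, t), 1)
})

test_that("metrics accept ReconImage objects directly", {
  img <- new("ReconImage", values = matrix(runif(256), 16, 16),
             pixelSize = 1, provenance = "fbp_of_clean")
  expect_equal(ssim(img, img), 1, tolerance = 1e-12)
  expect_identical(as.numeric(psnr(img, img)), Inf)
})
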
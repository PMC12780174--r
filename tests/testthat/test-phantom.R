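test_that("explicit disc rasterization matches area and attenuation", {
  n <- 64; r <- 20; mu <- 0.05
  ph <- discPhantom(n, r, mu)
  a <- attenuation(ph)
  inside <- sum(a > 0)
  expect_lt(abs(inside - pi * r^2) / (pi * r^2), 0.05)
  expect_equal(max(a), mu)
  expect_equal(unique(a[a > 0]), mu)
})

test_that("energy layers average to the nominal attenuation", {
  ph <- discPhantom(64, 20, 0.05, hardening = 2)
  lowE <- attenuation(ph, 1)
  highE <- attenuation(ph, 2)
  expect_gt(max(lowE), max(highE))
  expect_equal(max((lowE + highE) / 2), 0.05, tolerance = 1e-12)
  expect_equal(max(lowE) / max(highE), 2, tolerance = 1e-12)
})

test_that("phantom generation is a pure function of content and seed", {
  a <- generatePhantom(phantomContent(), 48, seed = 11)
  b <- generatePhantom(phantomContent(), 48, seed = 11)
  c <- generatePhantom(phantomContent(), 48, seed = 12)
  expect_identical(a@mu, b@mu)
  expect_false(identical(a@mu, c@mu))
})

test_that("random phantoms contain the documented object classes", {
  classes <- unlist(lapply(1:20, function(s) {
    generatePhantom(phantomContent(), 48, seed = s)@objects$class
  }))
  expect_true("matrix" %in% classes)
  expect_true("stone_small" %in% classes)
  expect_true("stone_large_grouped" %in% classes)
  ## grouped stones come in clusters of at least two
  for (s in 1:20) {
    obj <- generatePhantom(phantomContent(), 48, seed = s)@objects
    ng <- sum(obj$class == "stone_large_grouped")
    expect_true(ng == 0 || ng >= 2)
  }
})

test_that("objects that do not fit the grid are rejected", {
  bad <- data.frame(class = "matrix", cx = 5, cy = 32, r = 10, mu = 0.03,
                    hardening = 1)
  expect_error(generatePhantom(phantomContent(objects = bad), 64, seed = 1))
  expect_error(generatePhantom(phantomContent(), 16, seed = 1), "at least 32")
})
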
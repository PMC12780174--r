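test_that("FBP recovers a disc phantom with small interior error", {
  n <- 128; r <- 40; mu <- 0.02
  ph <- discPhantom(n, r, mu)
  g <- deskGeometry(nDetectorPixels = 192L, nProjections = 360L)
  proj <- forwardProject(ph, g)
  rec <- fbp(proj$bins[[1]], g, filterSpec("ramp"), imageSize = n)
  truth <- attenuation(ph)
  x <- seq_len(n) - (n + 1) / 2
  interior <- outer(x, x, function(a, b) sqrt(a^2 + b^2)) <= r - 3
  relL2 <- sqrt(sum((values(rec)[interior] - truth[interior])^2) /
                  sum(truth[interior]^2))
  expect_lt(relL2, 0.10)
})

test_that("FBP is linear in the sinogram", {
  g <- deskGeometry(nDetectorPixels = 64L, nProjections = 90L)
  set.seed(2)
  a <- matrix(runif(90 * 64), 90, 64)
  b <- matrix(runif(90 * 64), 90, 64)
  ra <- values(fbp(a, g, imageSize = 64))
  rb <- values(fbp(b, g, imageSize = 64))
  rab <- values(fbp(a + 2 * b, g, imageSize = 64))
  expect_equal(rab, ra + 2 * rb, tolerance = 1e-10)
})

test_that("filter specifications are validated and attenuate as documented", {
  expect_error(filterSpec("ramp", cutoff = 0), "cutoff")
  expect_error(filterSpec("boxcar"), "arg")
  f <- seq(0, 0.5, length.out = 101)
  ramp <- sinogap:::.filterResponse(f, filterSpec("ramp"))
  hann <- sinogap:::.filterResponse(f, filterSpec("hann"))
  expect_equal(ramp[1], 0)
  expect_equal(ramp[101], 1)           # 2|f| at Nyquist
  expect_true(all(hann <= ramp + 1e-12))
  ## cutoff zeroes the response above the fraction of Nyquist
  half <- sinogap:::.filterResponse(f, filterSpec("ramp", cutoff = 0.5))
  expect_equal(half[f > 0.26], rep(0, sum(f > 0.26)))
})

test_that("reconstruction pipeline maps provenance and masks the circle", {
  ds <- tinyDataset(nSlices = 1)
  cleanIli <- flatfieldCorrect(getSlice(ds, 1)$clean)
  rec <- reconstructPipeline(cleanIli, imageSize = 32)
  expect_identical(provenance(rec), "fbp_of_clean")
  noisyIli <- flatfieldCorrect(getSlice(ds, 1)$noisy)
  expect_identical(provenance(reconstructPipeline(noisyIli, imageSize = 32)),
                   "fbp_of_noisy")
  expect_true(all(values(rec)[!reconMask(32)] == 0))
  ## reconstruction is quantitatively close to the phantom inside the circle
  truth <- values(phantomRecon(getSlice(ds, 1)$phantom))
  m <- reconMask(32, margin = 2)
  expect_gt(cor(values(rec)[m], truth[m]), 0.9)
})

test_that("fan-beam FBP reconstructs a centred disc", {
  n <- 64; r <- 18; mu <- 0.03
  ph <- discPhantom(n, r, mu)
  g <- scanGeometry("fan", 96L, 1.5, 240L, 1.5, sod = 200, sdd = 300)
  proj <- forwardProject(ph, g)
  rec <- fbp(proj$bins[[1]], g, filterSpec("ramp"), imageSize = n,
             pixelSize = 1)
  truth <- attenuation(ph)
  x <- seq_len(n) - (n + 1) / 2
  interior <- outer(x, x, function(a, b) sqrt(a^2 + b^2)) <= r - 4
  relL2 <- sqrt(sum((values(rec)[interior] - truth[interior])^2) /
                  sum(truth[interior]^2))
  expect_lt(relL2, 0.25)
})
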
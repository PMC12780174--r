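test_that("flat-field correction reproduces the worked example exactly", {
  g <- deskGeometry(nDetectorPixels = 4L, nProjections = 120L)
  s <- new("PhotonSinogram", counts = matrix(55, 120, 4), dark = rep(10, 4),
           flat = rep(100, 4), geometry = g, provenance = "experimental_clean")
  ili <- flatfieldCorrect(s)
  expect_equal(unique(as.numeric(values(ili))), 0.5, tolerance = 1e-15)
  expect_identical(provenance(ili), "experimental_clean")
})

test_that("flat-field correction is exact per pixel with distinct fields", {
  g <- deskGeometry(nDetectorPixels = 3L, nProjections = 120L)
  dark <- c(1, 2, 3); flat <- c(101, 52, 203)
  cnt <- matrix(rep(c(51, 27, 103), each = 120), 120, 3)
  s <- new("PhotonSinogram", counts = cnt, dark = dark, flat = flat,
           geometry = g, provenance = "experimental_noisy")
  expect_equal(values(flatfieldCorrect(s))[1, ], c(0.5, 0.5, 0.5),
               tolerance = 1e-12)
})

test_that("log transform round-trips to 1e-12 and records clamping", {
  g <- tinyGeometry()
  v <- matrix(runif(g@nProjections * g@nDetectorPixels, 0.05, 1),
              g@nProjections, g@nDetectorPixels)
  ili <- new("ILISinogram", values = v, geometry = g,
             provenance = "experimental_clean")
  y <- toAbsorption(ili)
  expect_identical(y@nClamped, 0L)
  back <- fromAbsorption(y)
  expect_lt(max(abs(values(back) - v)), 1e-12)
  ## overshoot above 1 and starvation below epsilon are both clamped
  v2 <- v; v2[1, 1] <- 1.04; v2[1, 2] <- -0.2
  ili2 <- new("ILISinogram", values = v2, geometry = g,
              provenance = "experimental_noisy")
  y2 <- toAbsorption(ili2, epsilon = 1e-6)
  expect_identical(y2@nClamped, 2L)
  expect_true(all(values(y2) >= 0))
  expect_equal(values(y2)[1, 1], 0)  # negative log clamped to zero
  expect_equal(values(y2)[1, 2], -log(1e-6))
})

test_that("denoising never consumes absorption sinograms", {
  g <- tinyGeometry()
  ili <- constantIli(0.5, g)
  y <- toAbsorption(ili)
  spec <- networkSpec("msdnet", nLayers = 2L, dilationCycle = 2L)
  pairs <- structure(list(inputs = list(values(ili)),
                          targets = list(values(ili)),
                          domain = "sinogram", trainingData = "experimental_noisy",
                          scale = 1, geometry = g, imageSize = 32L),
                     class = "trainingPairs")
  model <- trainDenoiser(buildNetwork(spec), pairs,
                         trainingConfig("sinogram", epochs = 1L),
                         valPairs = list(inputs = pairs$inputs,
                                         targets = pairs$targets))
  expect_error(denoiseSinogram(model, y), "pre-log")
  expect_error(denoiseReconstruction(model, y), "domain")
})
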
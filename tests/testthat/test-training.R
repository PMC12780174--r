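test_that("dataset splits are disjoint, exhaustive and sized by floor rule", {
  sp <- splitDataset(10, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(lengths(sp), c(train = 8L, validation = 1L, test = 1L))
  sp60 <- splitDataset(60, c(0.8, 0.1, 0.1), seed = 2)
  expect_identical(lengths(sp60), c(train = 48L, validation = 6L, test = 6L))
  all60 <- sort(unlist(sp60))
  expect_identical(as.integer(all60), 1:60, ignore_attr = TRUE)
  expect_identical(splitDataset(60, seed = 2), sp60)
  expect_false(identical(splitDataset(60, seed = 3)$test, sp60$test))
})

test_that("the documented benchmark split sizes are recorded", {
  expect_identical(tdetectSplitSizes,
                   c(train = 3930L, validation = 550L, test = 470L))
  expect_identical(sum(tdetectSplitSizes), 4950L)
})

test_that("epoch selection takes the validation-loss argmin", {
  expect_identical(selectEpoch(c(3, 2, 5)), 2L)
  expect_identical(selectEpoch(c(5, 4, 3, 2)), 4L)
  expect_identical(selectEpoch(c(1, 1, 2)), 1L)  # earliest on ties
})

test_that("training pairs carry the right targets, domains and scaling", {
  ds <- tinyDataset(nSlices = 3)
  pe <- makeTrainingPairs(ds, 1:2, "experimental", "sinogram")
  expect_identical(pe$trainingData, "experimental_noisy")
  expect_identical(pe$domain, "sinogram")
  ## targets are the clean ILI
  cleanIli <- flatfieldCorrect(getSlice(ds, 1)$clean)
  expect_identical(pe$targets[[1]], values(cleanIli))
  ps <- makeTrainingPairs(ds, 1:2, "simulated", "sinogram", i0 = 200)
  expect_identical(ps$trainingData, "simulated_noisy")
  expect_identical(ps$targets, pe$targets)       # same clean targets
  expect_false(identical(ps$inputs, pe$inputs))  # different noise
  pr <- makeTrainingPairs(ds, 1:2, "experimental", "reconstruction",
                          imageSize = 32L)
  expect_lte(max(abs(unlist(pr$targets))), 1 + 1e-12)
  expect_gt(pr$scale, 0)
})

test_that("a tiny training run descends and selects the best epoch", {
  ds <- tinyDataset(nSlices = 4)
  pairs <- makeTrainingPairs(ds, 1:3, "experimental", "sinogram")
  val <- makeTrainingPairs(ds, 4, "experimental", "sinogram")
  cfg <- trainingConfig("sinogram", epochs = 4L, batchSize = 2L, seed = 1L)
  model <- trainDenoiser(buildNetwork(networkSpec("msdnet", nLayers = 2L,
                                                  dilationCycle = 2L)),
                         pairs, cfg, valPairs = val)
  h <- trainingHistory(model)
  expect_identical(nrow(h), 4L)
  expect_lt(h$trainLoss[4], h$trainLoss[1])
  expect_identical(selectedEpoch(model), which.min(h$valLoss))
  expect_s4_class(model, "TrainedModel")
  ## domain mismatch is rejected
  expect_error(trainDenoiser(buildNetwork(networkSpec("msdnet")), pairs,
                             trainingConfig("reconstruction")),
               "domain")
})

test_that("sinogram denoising reduces the noise of a held-out slice", {
  ds <- tinyDataset(nSlices = 5, seed = 31)
  pairs <- makeTrainingPairs(ds, 1:4, "experimental", "sinogram")
  cfg <- trainingConfig("sinogram", epochs = 25L, batchSize = 2L, seed = 1L)
  model <- trainDenoiser(buildNetwork(networkSpec("msdnet", nLayers = 8L,
                                                  dilationCycle = 2L)),
                         pairs, cfg,
                         valPairs = makeTrainingPairs(ds, 5, "experimental",
                                                      "sinogram"))
  sl <- getSlice(ds, 5)
  noisy <- flatfieldCorrect(sl$noisy)
  clean <- flatfieldCorrect(sl$clean)
  den <- denoiseSinogram(model, noisy)
  expect_identical(provenance(den), "denoised")
  mseBefore <- mean((values(noisy) - values(clean))^2)
  mseAfter <- mean((values(den) - values(clean))^2)
  expect_lt(mseAfter, mseBefore)
})

test_that("training is deterministic given seeds", {
  ds <- tinyDataset(nSlices = 3)
  pairs <- makeTrainingPairs(ds, 1:2, "experimental", "sinogram")
  val <- makeTrainingPairs(ds, 3, "experimental", "sinogram")
  cfg <- trainingConfig("sinogram", epochs = 2L, seed = 9L)
  run <- function() trainDenoiser(
    buildNetwork(networkSpec("msdnet", nLayers = 2L, dilationCycle = 2L,
                             seed = 2L)), pairs, cfg, valPairs = val)
  m1 <- run(); m2 <- run()
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@network@params, m2@network@params)
})
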
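test_that("the published cross-evaluation table loads completely", {
  tab <- referenceCrossEvalTable()
  expect_identical(nrow(tab), 48L)
  expect_setequal(unique(tab$domain),
                  c("sinogram", "reconstruction_of_output",
                    "reconstruction_direct"))
  expect_setequal(unique(tab$architecture), c("unet", "msdnet"))
  ## every (arch, training, test, domain, metric) cell appears exactly once
  expect_identical(anyDuplicated(tab[, 1:5]), 0L)
})

test_that("gap statistics recover the headline differences of the benchmark", {
  gaps <- gapStatistics(referenceCrossEvalTable())
  cell <- function(stat, arch, td, te, dom, met) {
    r <- gaps[gaps$statistic == stat & gaps$architecture == arch &
                gaps$trainingData == td & gaps$testData == te &
                gaps$domain == dom & gaps$metric == met, "value"]
    expect_identical(length(r), 1L)
    r
  }
  expect_equal(cell("sim_to_real_gap", "unet", "simulated_noisy",
                    "simulated_vs_experimental", "sinogram", "ssim"),
               0.0522, tolerance = 1e-12)
  expect_equal(cell("sim_to_real_gap", "msdnet", "simulated_noisy",
                    "simulated_vs_experimental", "sinogram", "psnr"),
               21.7057, tolerance = 1e-12)
  expect_equal(cell("domain_improvement", "unet", "experimental_noisy",
                    "experimental", "reconstruction_direct_minus_of_output",
                    "ssim"),
               0.2027, tolerance = 1e-12)
  expect_equal(cell("domain_improvement", "msdnet", "simulated_noisy",
                    "simulated", "reconstruction_direct_minus_of_output",
                    "ssim"),
               0.1832, tolerance = 1e-12)
})

test_that("evaluateStudy produces a full matrix for a tiny model set", {
  ds <- tinyDataset(nSlices = 3, seed = 23)
  pairs <- makeTrainingPairs(ds, 1, "experimental", "sinogram")
  val <- makeTrainingPairs(ds, 2, "experimental", "sinogram")
  model <- trainDenoiser(
    buildNetwork(networkSpec("msdnet", nLayers = 2L, dilationCycle = 2L)),
    pairs, trainingConfig("sinogram", epochs = 1L), valPairs = val)
  rep <- evaluateStudy(ds, list(model), testIndices = 3, imageSize = 32L)
  tab <- reportTable(rep)
  ## one architecture x 2 test sets x 2 domains x 2 metrics = 8 rows
  expect_identical(nrow(tab), 8L)
  expect_setequal(unique(tab$testData), c("experimental", "simulated"))
  expect_setequal(unique(tab$domain),
                  c("sinogram", "reconstruction_of_output"))
  expect_true(all(is.finite(tab$mean)))
  expect_true(all(tab$n == 1))
})
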
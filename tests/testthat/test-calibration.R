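test_that("the published noise-level table loads with the documented shape", {
  tab <- referenceNoiseLevelTable()
  df <- calibrationTable(tab)
  expect_identical(nrow(df), 5L)
  expect_identical(sum(df$type == "experimental"), 1L)
  expect_equal(df$i0[df$type == "simulated"], c(200, 250, 300, 350),
               ignore_attr = TRUE)
  ## the documented trend: simulated sinogram PSNR increases with I0
  expect_true(all(diff(df$psnrSino[df$type == "simulated"]) > 0))
})

test_that("selectI0 picks the nearest candidate and breaks ties downward", {
  tab <- noiseLevelTable(data.frame(
    type = c("experimental", "simulated", "simulated", "simulated"),
    i0 = c(NA, 100, 150, 200),
    ssimSino = c(0.30, 0.10, 0.31, 0.50),
    psnrSino = c(20, 15, 19, 25),
    ssimRecon = c(0.20, 0.10, 0.19, 0.40),
    psnrRecon = c(22, 20, 24, 26)))
  expect_equal(as.numeric(selectI0(tab, "psnr", "reconstruction")), 100)
  expect_equal(as.numeric(selectI0(tab, "ssim", "reconstruction")), 150)
  expect_equal(as.numeric(selectI0(tab, "psnr", "sinogram")), 150)
  ## exact tie (distance 2 for both 100 and 150 in recon PSNR) -> smaller I0
  tie <- noiseLevelTable(data.frame(
    type = c("experimental", "simulated", "simulated"),
    i0 = c(NA, 100, 150),
    ssimSino = c(0.3, 0.2, 0.4), psnrSino = c(20, 18, 22),
    ssimRecon = c(0.2, 0.1, 0.3), psnrRecon = c(22, 20, 24)))
  expect_equal(as.numeric(selectI0(tie, "psnr", "reconstruction")), 100)
  ## tables need simulated rows and a finite experimental value
  noSim <- data.frame(type = "experimental", i0 = NA, ssimSino = 1,
                      psnrSino = 1, ssimRecon = 1, psnrRecon = 1)
  expect_error(selectI0(noiseLevelTable(noSim)), "simulated")
})

test_that("measured noise levels track the injected noise ordering", {
  ds <- tinyDataset(nSlices = 2, seed = 17)
  tab <- calibrationTable(measureNoiseLevels(ds, i0Grid = c(50, 200, 800),
                                             seed = 5, imageSize = 32L))
  sim <- tab[tab$type == "simulated", ]
  expect_true(all(diff(sim$psnrSino) > 0))   # less noise, higher PSNR
  expect_true(all(diff(sim$ssimSino) > 0))
  expect_identical(sum(tab$type == "experimental"), 1L)
})
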
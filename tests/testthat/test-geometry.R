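test_that("geometry validity enforces angular coverage and fan distances", {
  expect_error(scanGeometry("parallel", 96, 1, 60, 1.5), "coverage")
  expect_error(scanGeometry("fan", 96, 1, 120, 1.5, sod = 400, sdd = 500),
               "coverage")
  expect_error(scanGeometry("fan", 96, 1, 360, 1, sod = 500, sdd = 400),
               "SOD")
  expect_s4_class(deskGeometry(), "ScanGeometry")
})

test_that("the benchmark fan geometry preset carries the documented values", {
  g <- tdetectGeometry()
  expect_identical(g@beamType, "fan")
  expect_identical(g@nDetectorPixels, 956L)
  expect_equal(g@detectorPixelSize, 0.1496)
  expect_identical(g@nProjections, 3601L)
  expect_equal(g@angularIncrement, 0.1)
  expect_equal(g@sod, 431.020)
  expect_equal(g@sdd, 529.000)
})

test_that("dose scale factor reproduces the x30 tube-current pairing", {
  clean <- acquisitionParams(tubeCurrent = 1000, nProj = 3601,
                             fluxInVacuum = 6000)
  noisy <- acquisitionParams(tubeCurrent = 1000 / 30, nProj = 3601,
                             fluxInVacuum = 200)
  expect_equal(clean@tubeCurrent / noisy@tubeCurrent, 30)
  expect_equal(doseScaleFactor(noisy, clean), sqrt(30), tolerance = 1e-12)
  ## noise factor is invariant under changes that cancel in the ratio
  expect_equal(doseScaleFactor(clean, clean), 1)
})

test_that("source spectra are normalized and mode-consistent", {
  mono <- sourceSpectrum()
  expect_identical(length(mono@energies), 1L)
  expect_equal(sum(mono@weights), 1)
  surro <- sourceSpectrum("two_energy_surrogate")
  expect_identical(length(surro@energies), 2L)
  expect_equal(sum(surro@weights), 1)
})
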
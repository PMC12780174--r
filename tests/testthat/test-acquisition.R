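test_that("forward projection reproduces the chord length of a disc", {
  n <- 64; r <- 20; mu <- 0.05
  ph <- discPhantom(n, r, mu)
  g <- deskGeometry(nDetectorPixels = 64L, nProjections = 60L)
  proj <- forwardProject(ph, g)
  ## central ray passes through the disc centre: line integral = 2 r mu
  central <- proj$bins[[1]][, g@nDetectorPixels / 2 + c(0L, 1L)]
  expect_equal(mean(central), 2 * r * mu, tolerance = 0.04)
})

test_that("forward projection is linear in the phantom", {
  g <- deskGeometry(nDetectorPixels = 48L, nProjections = 60L)
  p1 <- discPhantom(48, 12, 0.02)
  p2 <- discPhantom(48, 12, 0.06)
  a1 <- forwardProject(p1, g)$bins[[1]]
  a2 <- forwardProject(p2, g)$bins[[1]]
  expect_equal(a2, 3 * a1, tolerance = 1e-10)
})

test_that("expected counts follow Beer-Lambert and reject negative integrals", {
  L <- matrix(c(0, 1, 2), 1, 3)
  a <- expectedCounts(L, fluxInVacuum = 1000)
  expect_equal(as.numeric(a), 1000 * exp(-c(0, 1, 2)))
  expect_equal(attr(a, "flux"), 1000)
  expect_error(expectedCounts(matrix(-0.1, 1, 1), 1000), "nonnegative")
})

test_that("the two-energy surrogate produces beam hardening", {
  ## effective attenuation grows sublinearly with thickness
  sp <- sourceSpectrum("two_energy_surrogate")
  mkProj <- function(scale) list(bins = list(matrix(scale * 1.0, 1, 1),
                                             matrix(scale * 0.5, 1, 1)),
                                 spectrum = sp)
  eff <- function(scale)
    -log(as.numeric(expectedCounts(mkProj(scale), 1)) )
  expect_lt(eff(2), 2 * eff(1))
  expect_gt(eff(2), eff(1))
})

test_that("acquired counts have the expected first two moments", {
  g <- tinyGeometry()
  L <- matrix(0.5, g@nProjections, g@nDetectorPixels)
  a <- expectedCounts(L, fluxInVacuum = 400)
  dark <- rep(4, g@nDetectorPixels)
  flat <- rep(404, g@nDetectorPixels)
  s <- acquire(a, dark, flat, noiseParams(sigmaCrosstalk = 0), seed = 3,
               geometry = g, provenance = "experimental_noisy")
  rate <- 400 * exp(-0.5)
  expect_equal(mean(counts(s)), rate + 4, tolerance = 0.01)
  expect_equal(var(as.numeric(counts(s))), rate, tolerance = 0.05)
})

test_that("paired datasets enforce the only-tube-current-differs contract", {
  g <- tinyGeometry()
  clean <- acquisitionParams(tubeCurrent = 1000, nProj = g@nProjections,
                             fluxInVacuum = 6000)
  badVoltage <- acquisitionParams(tubeVoltage = 60, tubeCurrent = 1000 / 30,
                                  nProj = g@nProjections, fluxInVacuum = 200)
  badFlux <- acquisitionParams(tubeCurrent = 1000 / 30,
                               nProj = g@nProjections, fluxInVacuum = 500)
  expect_error(makePairedDataset(1, g, cleanParams = clean,
                                 noisyParams = badVoltage, seed = 1,
                                 imageSize = 32L),
               "tube current")
  expect_error(makePairedDataset(1, g, cleanParams = clean,
                                 noisyParams = badFlux, seed = 1,
                                 imageSize = 32L),
               "proportional")
})

test_that("paired slices share the phantom and differ only in dose", {
  ds <- tinyDataset(nSlices = 2)
  expect_identical(nSlices(ds), 2L)
  sl <- getSlice(ds, 1)
  expect_s4_class(sl$phantom, "Phantom")
  expect_identical(provenance(sl$clean), "experimental_clean")
  expect_identical(provenance(sl$noisy), "experimental_noisy")
  ## same object, 30x flux: clean counts are about 30x noisy counts
  expect_equal(mean(counts(sl$clean)) / mean(counts(sl$noisy)), 30,
               tolerance = 0.1)
  ## regenerating with the same seed reproduces the dataset exactly
  ds2 <- tinyDataset(nSlices = 2)
  expect_identical(counts(getSlice(ds2, 1)$noisy), counts(sl$noisy))
})
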
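test_that("cross-talk operator is row-stochastic with the documented band", {
  op <- crosstalkOperator(9, 0.05)
  m <- as.matrix(op@matrix)
  expect_equal(unname(rowSums(m)), rep(1, 9), tolerance = 1e-14)
  expect_equal(unname(m[5, 4:6]), c(0.025, 0.95, 0.025), tolerance = 1e-14)
  expect_true(all(m >= 0))
  ## sigma = 0 is the identity
  id <- as.matrix(crosstalkOperator(9, 0)@matrix)
  expect_equal(id, diag(9), tolerance = 1e-14, ignore_attr = TRUE)
  x <- matrix(rnorm(18), 2, 9)
  expect_equal(applyCrosstalk(crosstalkOperator(9, 0), x), x,
               tolerance = 1e-14)
  expect_error(crosstalkOperator(9, 1), "sigma")
})

test_that("Poisson component has zero mean and rate variance at several rates", {
  for (lambda in c(5, 50, 500)) {
    i0 <- 1000
    ili <- lambda / i0
    p <- poissonNoiseComponent(matrix(ili, 200, 200), i0, seed = lambda)
    expect_lt(abs(mean(p)) / sqrt(lambda / length(p)), 4)  # 4 sigma
    expect_equal(var(as.numeric(p)), lambda, tolerance = 0.05)
  }
})

test_that("simulated ILI noise std scales as I0^(-1/2)", {
  g <- tinyGeometry()
  ili <- constantIli(0.5, g)
  i0s <- c(50, 100, 200, 400, 800)
  sds <- vapply(i0s, function(i0) {
    reps <- vapply(1:4, function(r) {
      noisy <- simulateNoisyIli(ili, noiseParams(i0 = i0, sigmaCrosstalk = 0,
                                                 seed = deriveSeed(5L, i0, r)))
      sd(values(noisy) - values(ili))
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  fit <- lm(log(sds) ~ log(i0s))
  expect_gt(coef(fit)[2], -0.55)
  expect_lt(coef(fit)[2], -0.45)
})

test_that("cross-talk induces the expected lag-1 noise correlation", {
  g <- deskGeometry(nDetectorPixels = 96L, nProjections = 120L)
  ili <- constantIli(0.5, g)
  lag1 <- function(sigma, split = "total") {
    noise <- sinogap:::withSeed(21L, matrix(rnorm(120 * 96), 120, 96))
    if (sigma > 0)
      noise <- applyCrosstalk(crosstalkOperator(96, sigma, split), noise)
    cor(as.numeric(noise[, -96]), as.numeric(noise[, -1]))
  }
  expect_lt(abs(lag1(0)), 0.02)
  ## per-neighbour share sigma: analytic corr 2s(1-2s)/((1-2s)^2+2s^2) ~ 0.11
  expect_gt(lag1(0.05, "per_neighbor"), 0.1)
  ## total-split kernel (the default): analytic corr ~ 0.053
  expect_gt(lag1(0.05, "total"), 0.03)
  expect_lt(lag1(0.05, "total"), 0.08)
  ## the simulated-noise path shows the same structure
  noisy <- simulateNoisyIli(ili, noiseParams(i0 = 200, sigmaCrosstalk = 0.05,
                                             seed = 21L))
  e <- values(noisy) - values(ili)
  expect_gt(cor(as.numeric(e[, -96]), as.numeric(e[, -1])), 0.03)
})

test_that("noise simulation preserves the clean signal and its provenance rules", {
  g <- tinyGeometry()
  ili <- constantIli(0.7, g)
  noisy <- simulateNoisyIli(ili, noiseParams(i0 = 200, seed = 4L))
  expect_identical(provenance(noisy), "simulated_noisy")
  expect_equal(mean(values(noisy)), 0.7, tolerance = 0.01)
  ## noisy inputs must not be re-noised
  expect_error(simulateNoisyIli(noisy, noiseParams()), "clean")
  ## same seed, same draw; different seed, different draw
  again <- simulateNoisyIli(ili, noiseParams(i0 = 200, seed = 4L))
  expect_identical(values(again), values(noisy))
  other <- simulateNoisyIli(ili, noiseParams(i0 = 200, seed = 5L))
  expect_false(identical(values(other), values(noisy)))
})
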
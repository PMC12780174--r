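test_that("MSD dilation schedule cycles as documented", {
  expect_identical(msdDilations(20, 10), rep(1:10, 2))
  expect_identical(msdDilations(8, 4), rep(1:4, 2))
  expect_identical(msdDilations(3, 10), 1:3)
})

test_that("parameter counts reflect the architecture scale ordering", {
  unetBig <- buildNetwork(networkSpec("unet", depth = 3L, baseChannels = 16L))
  msdSmall <- buildNetwork(networkSpec("msdnet", nLayers = 30L,
                                       dilationCycle = 10L))
  expect_gt(numParameters(unetBig), 10 * numParameters(msdSmall))
  ## analytic count for a small MSD net: layer j has 9j + 1 params,
  ## head has (n + 1) + 1
  n <- 8L
  msd <- buildNetwork(networkSpec("msdnet", nLayers = n, dilationCycle = 4L))
  expected <- sum(9 * seq_len(n) + 1) + (n + 1) + 1 + n  # + n dilation markers
  expect_identical(numParameters(msd), as.integer(expected))
})

test_that("network weights are a pure function of the spec seed", {
  a <- buildNetwork(networkSpec("unet", seed = 3L))
  b <- buildNetwork(networkSpec("unet", seed = 3L))
  c <- buildNetwork(networkSpec("unet", seed = 4L))
  expect_identical(a@params, b@params)
  expect_false(identical(a@params, c@params))
})

test_that("residual networks start close to the identity", {
  x <- matrix(rnorm(16 * 16), 16, 16)
  for (spec in list(networkSpec("unet", depth = 2L, baseChannels = 4L),
                    networkSpec("msdnet", nLayers = 4L, dilationCycle = 2L))) {
    y <- applyNetwork(buildNetwork(spec), x)
    expect_lt(mean((y - x)^2) / mean(x^2), 0.5)
  }
})

test_that("analytic gradients match numeric gradients", {
  worstU <- checkNetworkGradients(networkSpec("unet", depth = 2L,
                                              baseChannels = 2L, seed = 5L))
  expect_lt(worstU, 1e-4)
  worstM <- checkNetworkGradients(networkSpec("msdnet", nLayers = 3L,
                                              dilationCycle = 2L, seed = 5L))
  expect_lt(worstM, 1e-4)
})

test_that("U-Nets reject inputs not divisible by their pooling factor", {
  net <- buildNetwork(networkSpec("unet", depth = 3L, baseChannels = 2L))
  expect_error(applyNetwork(net, matrix(0, 30, 30)), "divisible")
  expect_silent(applyNetwork(net, matrix(0, 32, 32)))
})
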
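test_that("deriveSeed is deterministic, in range, and index-sensitive", {
  expect_identical(deriveSeed(42L, 1L, 2L), deriveSeed(42L, 1L, 2L))
  s <- vapply(1:500, function(i) deriveSeed(42L, i), numeric(1))
  expect_true(all(s >= 1 & s <= 2^31 - 1))
  expect_identical(length(unique(s)), 500L)
  expect_false(deriveSeed(42L, 1L, 2L) == deriveSeed(42L, 2L, 1L))
  expect_false(deriveSeed(42L) == deriveSeed(43L))
})

test_that("withSeed gives reproducible draws and preserves the caller RNG", {
  set.seed(1)
  before <- .Random.seed
  a <- sinogap:::withSeed(7, rnorm(5))
  expect_identical(.Random.seed, before)
  b <- sinogap:::withSeed(7, rnorm(5))
  expect_identical(a, b)
})

test_that("role codes are stable and unknown roles error", {
  expect_identical(sinogap:::.roleCode("phantom"), 1L)
  expect_identical(sinogap:::.roleCode("test_sim"), 9L)
  expect_error(sinogap:::.roleCode("nope"), "unknown RNG role")
})
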
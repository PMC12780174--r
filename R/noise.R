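#' Construct noise-model parameters
#'
#' @param i0 photons-in-vacuum scale of the Poisson component (default 200,
#'   the noise level empirically calibrated against 2DeteCT-like
#'   experimental noise by reconstruction-domain PSNR agreement).
#' @param sigmaElectronic electronic-noise standard deviation in
#'   photon-count units (default 0; usually negligible away from the
#'   photon-starvation floor, kept configurable).
#' @param sigmaCrosstalk total signal fraction shared with the two adjacent
#'   detector pixels (default 0.05).
#' @param seed RNG seed for the noise draws.
#' @return a [NoiseParams-class].
#' @export
noiseParams <- function(i0 = 200, sigmaElectronic = 0, sigmaCrosstalk = 0.05,
                        seed = 1L) {
  new("NoiseParams", i0 = i0, sigmaElectronic = sigmaElectronic,
      sigmaCrosstalk = sigmaCrosstalk, seed = as.integer(seed))
}

#' Build the detector cross-talk operator
#'
#' A banded row-stochastic mixing matrix along the detector axis. Whether a
#' detector's published cross-talk fraction counts the total shared signal
#' or the share per neighbour is a convention; both are supported. With the
#' default `split = "total"` interior rows are
#' `(sigma/2, 1 - sigma, sigma/2)` -- the fraction `sigma` split equally
#' between the two adjacent pixels; with `split = "per_neighbor"` they are
#' `(sigma, 1 - 2 sigma, sigma)`. The two boundary rows are renormalized to
#' sum to one, and `sigma = 0` yields the identity either way.
#'
#' @param nPixels detector pixel count (>= 1).
#' @param sigma shared signal fraction, in `[0, 1)` (for
#'   `"per_neighbor"`, `2 * sigma` must stay below 1).
#' @param split `"total"` or `"per_neighbor"`, see above.
#' @return a [CrosstalkOperator-class].
#' @examples
#' op <- crosstalkOperator(5, 0.05)
#' as.matrix(op@matrix)[3, 2:4]  # 0.025 0.950 0.025
#' @export
crosstalkOperator <- function(nPixels, sigma = 0.05,
                              split = c("total", "per_neighbor")) {
  split <- match.arg(split)
  if (sigma < 0 || sigma >= 1) stop("sigma must lie in [0, 1)")
  side <- if (identical(split, "total")) sigma / 2 else sigma
  if (2 * side >= 1) stop("per-neighbour share too large")
  n <- as.integer(nPixels)
  if (n < 1L) stop("nPixels must be >= 1")
  if (n == 1L) {
    m <- Matrix::Matrix(1, 1, 1, sparse = TRUE)
  } else {
    m <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
      diagonals = list(rep(side, n - 1), rep(1 - 2 * side, n),
                       rep(side, n - 1)))
    rs <- Matrix::rowSums(m)
    m <- Matrix::Diagonal(x = 1 / rs) %*% m
  }
  new("CrosstalkOperator", size = n, sigma = sigma, matrix = m)
}

#' Apply cross-talk along the detector axis of a sinogram
#'
#' @param operator a [CrosstalkOperator-class].
#' @param x sinogram-shaped matrix (projections in rows, detector pixels in
#'   columns) or a detector vector.
#' @return the mixed matrix/vector.
#' @export
applyCrosstalk <- function(operator, x) {
  stopifnot(is(operator, "CrosstalkOperator"))
  if (is.matrix(x)) {
    if (ncol(x) != operator@size) stop("detector axis does not match operator size")
    as.matrix(x %*% Matrix::t(operator@matrix))
  } else {
    if (length(x) != operator@size) stop("vector length does not match operator size")
    as.numeric(operator@matrix %*% x)
  }
}

#' Poisson noise component of a simulated low-dose acquisition
#'
#' The signed photon-count deviation
#' `P = I0 * ILI - Poisson(I0 * ILI)` computed per pixel from a clean ILI
#' clamped to `[0, 1]`. Its expectation is zero and its variance equals the
#' Poisson rate `I0 * ILI`.
#'
#' @param iliClean clean [ILISinogram-class] or matrix.
#' @param i0 photons-in-vacuum scale (> 0).
#' @param seed RNG seed.
#' @return matrix of signed photon-count deviations.
#' @export
poissonNoiseComponent <- function(iliClean, i0, seed) {
  v <- if (is(iliClean, "ILISinogram")) iliClean@values else iliClean
  stopifnot(i0 > 0)
  rate <- i0 * clamp(v, 0, 1)
  draw <- withSeed(seed, matrix(rpois(length(rate), rate), nrow(rate), ncol(rate)))
  rate - draw
}

#' Simulate a noisy ILI sinogram from a clean one
#'
#' The chosen noise simulation for paired training data: the clean signal is
#' kept untouched and only the noise component is added,
#' `ILI_noisy = ILI_clean + Gamma (P + N(sigmaElectronic)) / I0`,
#' where `P` is the Poisson component of [poissonNoiseComponent()], `N` is
#' optional electronic noise in photon-count units, and `Gamma` is the
#' detector cross-talk operator applied along the detector axis of each
#' projection. The output may leave `[0, 1]`; overshoot is retained.
#'
#' @param iliClean a clean [ILISinogram-class]
#'   (provenance `"experimental_clean"`).
#' @param params a [NoiseParams-class]; its `seed` drives the draws.
#' @return an [ILISinogram-class] with provenance `"simulated_noisy"`.
#' @export
simulateNoisyIli <- function(iliClean, params = noiseParams()) {
  stopifnot(is(iliClean, "ILISinogram"), is(params, "NoiseParams"))
  if (!identical(iliClean@provenance, "experimental_clean"))
    stop("simulateNoisyIli expects a clean ILI (provenance 'experimental_clean')")
  p <- poissonNoiseComponent(iliClean, params@i0, params@seed)
  if (params@sigmaElectronic > 0) {
    p <- p + withSeed(deriveSeed(params@seed, 17L),
                      matrix(rnorm(length(p), 0, params@sigmaElectronic),
                             nrow(p), ncol(p)))
  }
  if (params@sigmaCrosstalk > 0) {
    op <- crosstalkOperator(ncol(p), params@sigmaCrosstalk)
    p <- applyCrosstalk(op, p)
  }
  new("ILISinogram", values = iliClean@values + p / params@i0,
      geometry = iliClean@geometry, provenance = "simulated_noisy")
}
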
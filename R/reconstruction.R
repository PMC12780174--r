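#' Construct an FBP filter specification
#'
#' @param kind `"ramp"` (Ram-Lak, the default and canonical choice),
#'   `"shepp-logan"` or `"hann"`.
#' @param cutoff cutoff as a fraction of the Nyquist frequency in `(0, 1]`.
#' @return a [FilterSpec-class].
#' @export
filterSpec <- function(kind = c("ramp", "shepp-logan", "hann"), cutoff = 1) {
  new("FilterSpec", kind = match.arg(kind), cutoff = cutoff)
}

## Frequency response of the reconstruction filter on the padded grid.
## f: frequencies in cycles/sample (|f| <= 0.5).
.filterResponse <- function(f, spec) {
  nyq <- 0.5 * spec@cutoff
  resp <- 2 * abs(f)
  win <- switch(spec@kind,
    "ramp" = 1,
    "shepp-logan" = {
      x <- pi * f / (2 * nyq)
      w <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
      w
    },
    "hann" = 0.5 * (1 + cos(pi * f / nyq)))
  resp <- resp * win
  resp[abs(f) > nyq] <- 0
  resp
}

## Apply the ramp filter along the detector axis of a sinogram
## (nProj x nDet), returning the filtered sinogram.
.rampFilter <- function(sino, spec) {
  nDet <- ncol(sino)
  npad <- 2^ceiling(log2(max(64, 2 * nDet)))
  f <- c(seq(0, npad / 2 - 1), seq(-npad / 2, -1)) / npad
  resp <- .filterResponse(f, spec)
  p <- matrix(0, npad, nrow(sino))
  p[seq_len(nDet), ] <- t(sino)
  q <- Re(mvfft(mvfft(p) * resp, inverse = TRUE)) / npad
  t(q[seq_len(nDet), , drop = FALSE])
}

## Rebin a fan-beam sinogram to parallel geometry. Returns list(sino,
## angles, detSpacing) with detector spacing at the isocentre.
.rebinFanToParallel <- function(sino, geometry) {
  betas <- projectionAngles(geometry)
  nDet <- geometry@nDetectorPixels
  u <- (seq_len(nDet) - (nDet + 1) / 2) * geometry@detectorPixelSize
  gam <- atan(u / geometry@sdd)              # fan angles per detector pixel
  sIso <- geometry@sod * sin(gam)            # parallel offsets
  dsIso <- geometry@detectorPixelSize * geometry@sod / geometry@sdd
  sTarget <- (seq_len(nDet) - (nDet + 1) / 2) * dsIso
  nPhi <- max(180L, as.integer(round(geometry@nProjections / 2)))
  phiTarget <- seq(0, pi, length.out = nPhi + 1L)[seq_len(nPhi)]
  out <- matrix(0, nPhi, nDet)
  twopi <- 2 * pi
  interpBeta <- function(b) {
    ## fractional index into the beta grid (periodic)
    (b %% twopi) / (geometry@angularIncrement * pi / 180)
  }
  for (j in seq_len(nDet)) {
    g <- asin(clamp(sTarget[j] / geometry@sod, -1, 1))
    ## both half-turns measure the same parallel ray; average the two
    for (sgn in c(1, -1)) {
      gs <- sgn * g
      us <- geometry@sdd * tan(gs)
      b <- if (sgn > 0) phiTarget - gs else phiTarget - gs + pi
      bi <- interpBeta(b)
      i0 <- floor(bi)
      w <- bi - i0
      i1 <- (i0 %% geometry@nProjections) + 1
      i2 <- ((i0 + 1) %% geometry@nProjections) + 1
      ui <- (us / geometry@detectorPixelSize) + (nDet + 1) / 2
      j0 <- floor(ui)
      wj <- ui - j0
      if (j0 < 1 || j0 >= nDet) next
      v <- (1 - w) * ((1 - wj) * sino[i1, j0] + wj * sino[i1, j0 + 1]) +
        w * ((1 - wj) * sino[i2, j0] + wj * sino[i2, j0 + 1])
      out[, j] <- out[, j] + 0.5 * v
    }
  }
  list(sino = out, angles = phiTarget, detSpacing = dsIso)
}

#' Filtered backprojection
#'
#' Reconstructs an attenuation image from an absorption sinogram by
#' frequency-domain ramp filtering of each projection followed by
#' backprojection. Parallel-beam data are handled natively; fan-beam data
#' are rebinned to parallel geometry first (bilinear interpolation in the
#' angle/offset plane). Pixels outside the inscribed circle are masked to
#' zero. The operator is linear in its input.
#'
#' @param y an [AbsorptionSinogram-class] (or plain matrix with `geometry`
#'   supplied).
#' @param geometry the acquisition [ScanGeometry-class].
#' @param filter a [FilterSpec-class].
#' @param imageSize output image edge length in pixels (>= 16).
#' @param pixelSize reconstruction pixel size; defaults to the detector
#'   spacing at the isocentre, so attenuation stays per pixel length.
#' @return a [ReconImage-class].
#' @export
fbp <- function(y, geometry = NULL, filter = filterSpec(), imageSize = NULL,
                pixelSize = NULL) {
  prov <- "fbp_of_noisy"
  if (is(y, "AbsorptionSinogram")) {
    if (is.null(geometry)) geometry <- y@geometry
    prov <- switch(y@provenance, experimental_clean = "fbp_of_clean",
                   denoised = "fbp_of_denoised", "fbp_of_noisy")
    y <- y@values
  }
  if (is.null(geometry)) stop("geometry required")
  if (!all(dim(y) == c(geometry@nProjections, geometry@nDetectorPixels)))
    stop("sinogram shape does not match geometry")
  if (identical(geometry@beamType, "fan")) {
    rb <- .rebinFanToParallel(y, geometry)
    sino <- rb$sino
    angles <- rb$angles
    ds <- rb$detSpacing
  } else {
    sino <- y
    angles <- projectionAngles(geometry)
    ds <- geometry@detectorPixelSize
  }
  if (is.null(pixelSize)) pixelSize <- ds
  if (is.null(imageSize)) imageSize <- ncol(sino)
  if (imageSize < 16) stop("imageSize must be at least 16")
  dsPx <- ds / pixelSize
  filtered <- .rampFilter(sino, filter)
  img <- cpp_backproject_parallel(filtered, angles, as.integer(imageSize), dsPx)
  img <- img * pi / (2 * length(angles)) / dsPx
  img <- img * .reconMask(imageSize)
  new("ReconImage", values = img, pixelSize = pixelSize, provenance = prov)
}

## logical mask of the inscribed reconstruction circle
.reconMask <- function(n, margin = 0) {
  x <- seq_len(n) - (n + 1) / 2
  r <- outer(x, x, function(a, b) sqrt(a^2 + b^2))
  r <= (n / 2 - margin)
}

#' Reconstruction circle mask
#'
#' Logical mask of the inscribed circle on an `n x n` grid; metrics in the
#' reconstruction domain are computed inside this support only.
#'
#' @param n grid edge length.
#' @param margin pixels to shave off the circle boundary.
#' @return logical matrix.
#' @export
reconMask <- function(n, margin = 0) .reconMask(n, margin)

#' Standard evaluation path: ILI to reconstruction
#'
#' Composes [toAbsorption()] and [fbp()]: the reconstruction used whenever
#' sinogram-domain data (clean, noisy or denoised) are evaluated in the
#' reconstruction domain ("FBP of model output").
#'
#' @param ili an [ILISinogram-class].
#' @param geometry acquisition geometry (defaults to the ILI's).
#' @param filter a [FilterSpec-class].
#' @param imageSize output image size.
#' @param epsilon log clamping floor, see [toAbsorption()].
#' @return a [ReconImage-class] whose provenance records the input tag.
#' @export
reconstructPipeline <- function(ili, geometry = NULL, filter = filterSpec(),
                                imageSize = NULL, epsilon = 1e-6) {
  stopifnot(is(ili, "ILISinogram"))
  if (is.null(geometry)) geometry <- ili@geometry
  fbp(toAbsorption(ili, epsilon), geometry, filter, imageSize)
}

#' Phantom as ground-truth reconstruction
#'
#' Wraps a phantom's effective attenuation map as a [ReconImage-class] with
#' provenance `"ground_truth_phantom"`, masked to the reconstruction
#' circle: the exact synthetic analogue of a reference reconstruction.
#'
#' @param phantom a [Phantom-class].
#' @return a [ReconImage-class].
#' @export
phantomRecon <- function(phantom) {
  img <- attenuation(phantom)
  img <- img * .reconMask(nrow(img))
  new("ReconImage", values = img, pixelSize = phantom@pixelSize,
      provenance = "ground_truth_phantom")
}
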
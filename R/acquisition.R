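#' Forward projection of a phantom
#'
#' Computes line integrals of the phantom's attenuation along the rays of
#' the given geometry, one sinogram per spectrum energy bin. For a
#' monochromatic spectrum the effective (bin-averaged) attenuation map is
#' projected; for the two-energy surrogate each energy layer is projected
#' separately. The projector is ray-driven with bilinear sampling and is
#' linear in the phantom.
#'
#' @param phantom a [Phantom-class].
#' @param geometry a [ScanGeometry-class].
#' @param spectrum a [SourceSpectrum-class].
#' @param step ray sampling step in pixel units.
#' @return a list with elements `bins` (list of nProjections x
#'   nDetectorPixels line-integral matrices, one per energy bin),
#'   `spectrum` and `geometry`.
#' @export
forwardProject <- function(phantom, geometry, spectrum = sourceSpectrum(),
                           step = 0.5) {
  stopifnot(is(phantom, "Phantom"), is(geometry, "ScanGeometry"),
            is(spectrum, "SourceSpectrum"))
  maps <- if (identical(spectrum@mode, "monochromatic")) {
    list(attenuation(phantom))
  } else {
    lapply(seq_along(spectrum@energies), function(k) attenuation(phantom, k))
  }
  angles <- projectionAngles(geometry)
  detSpacingPx <- geometry@detectorPixelSize / phantom@pixelSize
  bins <- lapply(maps, function(img) {
    if (identical(geometry@beamType, "parallel")) {
      cpp_forward_project_parallel(img, angles, geometry@nDetectorPixels,
                                   detSpacingPx, step)
    } else {
      cpp_forward_project_fan(img, angles, geometry@nDetectorPixels,
                              detSpacingPx, geometry@sod / phantom@pixelSize,
                              geometry@sdd / phantom@pixelSize, step)
    }
  })
  list(bins = bins, spectrum = spectrum, geometry = geometry)
}

#' Expected photon counts behind the object
#'
#' Applies the Beer-Lambert law to line integrals: with a monochromatic
#' spectrum `A = flux * exp(-L)`; with a multi-energy spectrum
#' `A = flux * sum_k w_k * exp(-L_k)`, whose effective attenuation
#' `-log(A/flux)` grows sublinearly in object thickness (beam hardening).
#'
#' @param lineIntegrals the result of [forwardProject()], or a single
#'   line-integral matrix (treated as monochromatic).
#' @param fluxInVacuum expected photons per detector pixel with no object.
#' @param spectrum a [SourceSpectrum-class]; taken from `lineIntegrals` when
#'   available.
#' @return matrix of expected counts in `(0, flux]`, with the flux attached
#'   as attribute `"flux"`.
#' @export
expectedCounts <- function(lineIntegrals, fluxInVacuum, spectrum = NULL) {
  if (is.matrix(lineIntegrals))
    lineIntegrals <- list(bins = list(lineIntegrals),
                          spectrum = sourceSpectrum())
  if (is.null(spectrum)) spectrum <- lineIntegrals$spectrum
  stopifnot(fluxInVacuum > 0)
  bins <- lineIntegrals$bins
  if (length(bins) != length(spectrum@weights))
    stop("one line-integral matrix per spectrum bin required")
  if (any(vapply(bins, function(b) any(b < 0), logical(1))))
    stop("line integrals must be nonnegative")
  a <- 0
  for (k in seq_along(bins)) a <- a + spectrum@weights[k] * exp(-bins[[k]])
  structure(fluxInVacuum * a, flux = fluxInVacuum)
}

#' Smooth per-pixel flat-field gains
#'
#' A smooth detector sensitivity profile in `[0.9, 1.1]`, built from a few
#' low-order random harmonics, shared between the acquisitions of one
#' instrument.
#'
#' @param nPixels detector pixel count.
#' @param seed RNG seed.
#' @return numeric vector of gains.
#' @export
flatFieldGains <- function(nPixels, seed) {
  withSeed(seed, {
    x <- seq(0, 1, length.out = nPixels)
    g <- rep(0, nPixels)
    for (h in 1:4) g <- g + rnorm(1) * sin(pi * h * x + runif(1, 0, 2 * pi)) / h
    g <- g / max(abs(g), 1e-12)
    1 + 0.1 * g
  })
}

#' Simulate a raw photon-count acquisition
#'
#' The full detector path of the simplified noise model: per-pixel Poisson
#' draws of the expected counts (with flat-field gains and an optional
#' constant scatter floor applied), plus zero-mean Gaussian electronic
#' noise, mixed by the detector cross-talk operator, plus the dark offset.
#' Counts are floored at zero.
#'
#' @param expected expected ideal counts from [expectedCounts()] (flux
#'   attached as attribute).
#' @param dark,flat per-detector-pixel dark and flat fields. The gain
#'   profile is recovered as `(flat - dark) / flux`.
#' @param noiseParams a [NoiseParams-class]; only `sigmaElectronic` and
#'   `sigmaCrosstalk` are used here (the Poisson scale is the flux itself).
#' @param seed RNG seed for the draws.
#' @param geometry the acquisition [ScanGeometry-class].
#' @param scatterFraction constant scatter floor as a fraction of flux.
#' @param provenance `"experimental_clean"` or `"experimental_noisy"`.
#' @return a [PhotonSinogram-class].
#' @export
acquire <- function(expected, dark, flat, noiseParams, seed, geometry,
                    scatterFraction = 0,
                    provenance = c("experimental_noisy", "experimental_clean")) {
  provenance <- match.arg(provenance)
  flux <- attr(expected, "flux")
  if (is.null(flux)) stop("expected counts must carry a 'flux' attribute")
  if (any(expected < 0)) stop("negative expected counts")
  gains <- (flat - dark) / flux
  a <- sweep(unclass(expected) + flux * scatterFraction, 2, gains, `*`)
  counts <- withSeed(seed, {
    s <- matrix(rpois(length(a), a), nrow(a), ncol(a))
    if (noiseParams@sigmaElectronic > 0)
      s <- s + matrix(rnorm(length(a), 0, noiseParams@sigmaElectronic),
                      nrow(a), ncol(a))
    s
  })
  if (noiseParams@sigmaCrosstalk > 0) {
    gamma <- crosstalkOperator(ncol(counts), noiseParams@sigmaCrosstalk)
    counts <- applyCrosstalk(gamma, counts)
  }
  counts <- pmax(sweep(counts, 2, dark, `+`), 0)
  new("PhotonSinogram", counts = counts, dark = dark, flat = flat,
      geometry = geometry, provenance = provenance)
}

#' Generate a paired clean/noisy dataset
#'
#' Emulates paired two-dose acquisitions of the same slices: for each slice
#' one phantom is generated and projected once, then acquired twice with
#' parameters differing only in tube current (hence flux). In
#' `"experimental_surrogate"` mode the two-energy spectrum (beam hardening)
#' and a constant scatter floor are active -- physics the monochromatic
#' noise model cannot express -- so a sim-to-real gap is observable against
#' noise simulated by [simulateNoisyIli()]. Per-slice RNG streams are
#' derived from the master seed, with independent clean/noisy draws.
#'
#' @param nSlices number of slices (>= 1).
#' @param geometry a [ScanGeometry-class].
#' @param surrogateMode `"monochromatic"` or `"experimental_surrogate"`.
#' @param cleanParams,noisyParams [AcquisitionParams-class] differing only
#'   in tube current, with flux proportional to current.
#' @param seed master seed.
#' @param content a [phantomContent()] spec.
#' @param detector [NoiseParams-class] of the detector (electronic noise,
#'   cross-talk) used for both acquisitions.
#' @param scatterFraction scatter floor (surrogate mode only).
#' @param imageSize phantom grid size in pixels.
#' @return a [PairedDataset-class].
#' @export
makePairedDataset <- function(nSlices, geometry = deskGeometry(),
                              surrogateMode = c("experimental_surrogate",
                                                "monochromatic"),
                              cleanParams, noisyParams, seed,
                              content = phantomContent(),
                              detector = noiseParams(sigmaElectronic = 3),
                              scatterFraction = 0.01, imageSize = 64L) {
  surrogateMode <- match.arg(surrogateMode)
  if (nSlices < 1) stop("nSlices must be at least 1")
  .checkPairing(cleanParams, noisyParams)
  spectrum <- if (identical(surrogateMode, "experimental_surrogate"))
    sourceSpectrum("two_energy_surrogate") else sourceSpectrum("monochromatic")
  scatter <- if (identical(surrogateMode, "experimental_surrogate"))
    scatterFraction else 0
  nDet <- geometry@nDetectorPixels
  gains <- flatFieldGains(nDet, deriveSeed(seed, .roleCode("flat")))
  mkFields <- function(flux) {
    dark <- rep(0.01 * flux, nDet)
    list(dark = dark, flat = flux * gains + dark)
  }
  fClean <- mkFields(cleanParams@fluxInVacuum)
  fNoisy <- mkFields(noisyParams@fluxInVacuum)
  slices <- lapply(seq_len(nSlices), function(i) {
    ph <- generatePhantom(content, imageSize,
                          deriveSeed(seed, i, .roleCode("phantom")))
    proj <- forwardProject(ph, geometry, spectrum)
    expClean <- expectedCounts(proj, cleanParams@fluxInVacuum)
    expNoisy <- expectedCounts(proj, noisyParams@fluxInVacuum)
    clean <- acquire(expClean, fClean$dark, fClean$flat, detector,
                     deriveSeed(seed, i, .roleCode("clean")), geometry,
                     scatter, provenance = "experimental_clean")
    noisy <- acquire(expNoisy, fNoisy$dark, fNoisy$flat, detector,
                     deriveSeed(seed, i, .roleCode("noisy")), geometry,
                     scatter, provenance = "experimental_noisy")
    list(phantom = ph, clean = clean, noisy = noisy)
  })
  new("PairedDataset", slices = slices, geometry = geometry,
      spectrum = spectrum, surrogateMode = surrogateMode,
      cleanParams = cleanParams, noisyParams = noisyParams,
      seed = as.integer(seed))
}

.checkPairing <- function(cleanParams, noisyParams) {
  same <- isTRUE(all.equal(cleanParams@tubeVoltage, noisyParams@tubeVoltage)) &&
    isTRUE(all.equal(cleanParams@exposureTime, noisyParams@exposureTime)) &&
    isTRUE(all.equal(cleanParams@nProj, noisyParams@nProj)) &&
    isTRUE(all.equal(cleanParams@nAvim, noisyParams@nAvim))
  if (!same)
    stop("paired acquisitions must differ only in tube current")
  ratioI <- cleanParams@tubeCurrent / noisyParams@tubeCurrent
  ratioF <- cleanParams@fluxInVacuum / noisyParams@fluxInVacuum
  if (abs(ratioI / ratioF - 1) > 0.05)
    stop("flux must be proportional to tube current")
  invisible(TRUE)
}

#' Default paired acquisition parameters
#'
#' Clean and noisy acquisition settings for the surrogate instrument: 90 kV,
#' 50 ms, identical in everything but tube current (1000 uA vs 33.3 uA, a
#' factor 30), with flux in vacuum 6000 and 200 photons per pixel
#' respectively.
#'
#' @param geometry geometry supplying the projection count.
#' @param fluxNoisy noisy-mode flux; the clean mode has 30 times more.
#' @return list with elements `clean` and `noisy`.
#' @export
pairedAcquisitionParams <- function(geometry = deskGeometry(), fluxNoisy = 200) {
  np <- geometry@nProjections
  list(clean = acquisitionParams(tubeCurrent = 1000, nProj = np,
                                 fluxInVacuum = 30 * fluxNoisy),
       noisy = acquisitionParams(tubeCurrent = 1000 / 30, nProj = np,
                                 fluxInVacuum = fluxNoisy))
}
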
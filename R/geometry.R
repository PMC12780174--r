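#' Construct a scan geometry
#'
#' @param beamType `"parallel"` or `"fan"`.
#' @param nDetectorPixels number of (binned) detector pixels.
#' @param detectorPixelSize detector pixel pitch in mm.
#' @param nProjections number of projection angles.
#' @param angularIncrement angular step in degrees. The angular coverage
#'   `nProjections * angularIncrement` must reach 180 degrees for parallel
#'   beams and 360 degrees for fan beams.
#' @param sod,sdd source-object / source-detector distance in mm (fan only).
#' @return a [ScanGeometry-class].
#' @examples
#' scanGeometry("parallel", 96, 1, 120, 1.5)
#' @export
scanGeometry <- function(beamType = c("parallel", "fan"), nDetectorPixels,
                         detectorPixelSize, nProjections, angularIncrement,
                         sod = NA_real_, sdd = NA_real_) {
  beamType <- match.arg(beamType)
  new("ScanGeometry", beamType = beamType,
      nDetectorPixels = as.integer(nDetectorPixels),
      detectorPixelSize = as.numeric(detectorPixelSize),
      nProjections = as.integer(nProjections),
      angularIncrement = as.numeric(angularIncrement),
      sod = as.numeric(sod), sdd = as.numeric(sdd))
}

#' Desk-scale parallel-beam geometry
#'
#' The default geometry for CPU-scale experiments: parallel beam, 96
#' detector pixels of unit pitch, 120 projections over 180 degrees. Unit
#' pitch means detector samples coincide with phantom pixels, so attenuation
#' is expressed per pixel length throughout.
#'
#' @param nDetectorPixels,nProjections override the defaults.
#' @return a [ScanGeometry-class].
#' @export
deskGeometry <- function(nDetectorPixels = 96L, nProjections = 120L) {
  scanGeometry("parallel", nDetectorPixels, 1, nProjections,
               180 / nProjections)
}

#' 2DeteCT-like fan-beam geometry
#'
#' The acquisition geometry of the 2DeteCT experimental collection, kept as
#' a named preset: fan beam, 956 binned detector pixels of 149.6 um, 3601
#' projections at 0.1 degree increments, SOD 431.020 mm, SDD 529.000 mm.
#'
#' @return a [ScanGeometry-class].
#' @export
tdetectGeometry <- function() {
  scanGeometry("fan", 956L, 0.1496, 3601L, 0.1, sod = 431.020, sdd = 529.000)
}

## Projection angles in radians, one per sinogram row.
projectionAngles <- function(geometry) {
  (seq_len(geometry@nProjections) - 1) * geometry@angularIncrement * pi / 180
}

#' Construct a source spectrum
#'
#' @param mode `"monochromatic"` (one energy bin; the standard Radon /
#'   Beer-Lambert model, no beam hardening) or `"two_energy_surrogate"` (two
#'   bins; with energy-dependent attenuation this produces beam hardening,
#'   the polychromatic effect that separates the surrogate "experimental"
#'   physics from what the monochromatic noise model can express).
#' @param energies,weights bin energies (keV, nominal) and weights; defaults
#'   are 60 keV for monochromatic mode and (40, 80) keV at equal weight for
#'   the surrogate mode.
#' @return a [SourceSpectrum-class].
#' @export
sourceSpectrum <- function(mode = c("monochromatic", "two_energy_surrogate"),
                           energies = NULL, weights = NULL) {
  mode <- match.arg(mode)
  if (is.null(energies))
    energies <- if (identical(mode, "monochromatic")) 60 else c(40, 80)
  if (is.null(weights)) weights <- rep(1 / length(energies), length(energies))
  new("SourceSpectrum", energies = as.numeric(energies),
      weights = as.numeric(weights), mode = mode)
}

#' Construct acquisition parameters
#'
#' @param tubeVoltage tube voltage in kV (default 90, as for 2DeteCT).
#' @param tubeCurrent tube current in uA.
#' @param exposureTime exposure time in ms (default 50).
#' @param nProj number of projections.
#' @param nAvim number of averaged images (default 1).
#' @param fluxInVacuum expected photons per detector pixel with no object in
#'   the beam; proportional to tube current for fixed voltage.
#' @return an [AcquisitionParams-class].
#' @export
acquisitionParams <- function(tubeVoltage = 90, tubeCurrent, exposureTime = 50,
                              nProj, nAvim = 1, fluxInVacuum) {
  new("AcquisitionParams", tubeVoltage = tubeVoltage, tubeCurrent = tubeCurrent,
      exposureTime = exposureTime, nProj = nProj, nAvim = nAvim,
      fluxInVacuum = fluxInVacuum)
}

#' Relative quantum-noise factor between two acquisitions
#'
#' The quantum-noise level of a reconstructed CT slice scales as
#' `V^1.3 / sqrt(I * t * n_proj * n_avim)` in the acquisition parameters
#' (tube voltage V, tube current I, exposure time t, projection count and
#' image averaging count). `doseScaleFactor` returns the ratio of this
#' factor between two acquisitions, i.e. how much noisier (> 1) or cleaner
#' (< 1) acquisition `a` is than acquisition `b`.
#'
#' Dividing the tube current by 30 while holding everything else fixed -- the
#' clean/noisy pairing used for 2DeteCT-like paired scans -- multiplies the
#' noise factor by `sqrt(30) ~ 5.48`.
#'
#' @param paramsA,paramsB two [AcquisitionParams-class] objects.
#' @return the scalar ratio `factor(paramsA) / factor(paramsB)`.
#' @examples
#' clean <- acquisitionParams(tubeCurrent = 1000, nProj = 3601, fluxInVacuum = 6000)
#' noisy <- acquisitionParams(tubeCurrent = 1000 / 30, nProj = 3601, fluxInVacuum = 200)
#' doseScaleFactor(noisy, clean)  # sqrt(30)
#' @export
doseScaleFactor <- function(paramsA, paramsB) {
  stopifnot(is(paramsA, "AcquisitionParams"), is(paramsB, "AcquisitionParams"))
  f <- function(p) p@tubeVoltage^1.3 /
    sqrt(p@tubeCurrent * p@exposureTime * p@nProj * p@nAvim)
  f(paramsA) / f(paramsB)
}
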
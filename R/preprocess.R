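#' Flat-field correction: counts to beam intensity loss image
#'
#' Converts raw counts to the beam intensity loss image
#' `ILI = (S - D) / (F - D)`, the fraction of beam intensity surviving along
#' each ray. Noise may push individual values slightly outside `[0, 1]`;
#' such overshoot is retained (it belongs to the noise distribution the
#' denoisers must learn) and only resolved at the log step.
#'
#' @param sinogram a [PhotonSinogram-class] with `flat > dark` per pixel.
#' @return an [ILISinogram-class] with the provenance of its input.
#' @examples
#' g <- deskGeometry(nDetectorPixels = 4, nProjections = 120)
#' s <- new("PhotonSinogram", counts = matrix(55, 120, 4), dark = rep(10, 4),
#'          flat = rep(100, 4), geometry = g, provenance = "experimental_clean")
#' range(values(flatfieldCorrect(s)))  # 0.5
#' @export
flatfieldCorrect <- function(sinogram) {
  stopifnot(is(sinogram, "PhotonSinogram"))
  d <- sinogram@flat - sinogram@dark
  if (any(d <= 0)) stop("flat field must exceed dark field at every pixel")
  ili <- sweep(sweep(sinogram@counts, 2, sinogram@dark, `-`), 2, d, `/`)
  new("ILISinogram", values = ili, geometry = sinogram@geometry,
      provenance = sinogram@provenance)
}

#' Negative-log transform: ILI to absorption sinogram
#'
#' Applies the Beer-Lambert negative logarithm,
#' `y = -log(max(ILI, epsilon))`, yielding the line integrals of attenuation
#' used by reconstruction. Values below `epsilon` are floored before the log
#' (keeping y finite under photon starvation); ILI overshoot above 1 passes
#' through the log and the resulting small negative y is clamped to zero.
#' The number of pixels touched by either clamp is recorded.
#'
#' @param ili an [ILISinogram-class].
#' @param epsilon positive clamping floor (default `1e-6`).
#' @return an [AbsorptionSinogram-class].
#' @export
toAbsorption <- function(ili, epsilon = 1e-6) {
  stopifnot(is(ili, "ILISinogram"), epsilon > 0)
  v <- ili@values
  nClamped <- sum(v < epsilon) + sum(v > 1)
  y <- -log(pmax(v, epsilon))
  y[y < 0] <- 0
  new("AbsorptionSinogram", values = y, epsilon = epsilon,
      nClamped = as.integer(nClamped), geometry = ili@geometry,
      provenance = ili@provenance)
}

#' Inverse of the negative-log transform
#'
#' `ILI = exp(-y)`; for nonnegative `y` this inverts [toAbsorption()] to
#' machine precision.
#'
#' @param y an [AbsorptionSinogram-class] or a numeric matrix.
#' @param geometry,provenance required when `y` is a plain matrix.
#' @return an [ILISinogram-class].
#' @export
fromAbsorption <- function(y, geometry = NULL, provenance = NULL) {
  if (is(y, "AbsorptionSinogram")) {
    geometry <- y@geometry
    provenance <- y@provenance
    y <- y@values
  }
  stopifnot(all(is.finite(y)))
  new("ILISinogram", values = exp(-y), geometry = geometry,
      provenance = provenance)
}
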
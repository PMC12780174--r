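#' Peak signal-to-noise ratio
#'
#' `PSNR = 20 * log10(range / sqrt(MSE))` in dB. CT images are unbounded,
#' so the data-range convention materially affects reported values; the
#' policy here is explicit: by default the range is `max - min` of the
#' reference image (`"gt_range"`), values are never clipped, and a fixed
#' numeric range can be supplied instead. Identical images give `Inf`
#' (flagged, not an error).
#'
#' @param reference,test numeric matrices (or objects with [values()]) of
#'   equal shape; `reference` defines the data range.
#' @param dataRange fixed numeric range, or `NULL` for the gt_range policy.
#' @param mask optional logical matrix restricting the pixels compared
#'   (e.g. the reconstruction circle).
#' @return PSNR in dB, with attribute `dataRange`.
#' @export
psnr <- function(reference, test, dataRange = NULL, mask = NULL) {
  r <- if (is.matrix(reference)) reference else values(reference)
  t <- if (is.matrix(test)) test else values(test)
  if (!all(dim(r) == dim(t))) stop("shape mismatch")
  if (is.null(dataRange)) dataRange <- max(r) - min(r)
  if (dataRange <= 0) stop("zero data range")
  if (!is.null(mask)) {
    r <- r[mask]
    t <- t[mask]
  }
  mse <- mean((r - t)^2)
  out <- if (mse == 0) Inf else 20 * log10(dataRange / sqrt(mse))
  structure(out, dataRange = dataRange)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard luminance/contrast/structure terms:
#' uniform square window (default 7x7), stabilization constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` scaled by the data range `L`, and
#' unbiased local covariance. The local map is computed over windows fully
#' inside the image; identical images give exactly 1.
#'
#' @param reference,test numeric matrices (or objects with [values()]).
#' @param window odd window side length; must fit inside the image.
#' @param dataRange fixed range `L`, or `NULL` for `max - min` of the
#'   reference.
#' @param mask optional logical matrix; only windows centred inside the
#'   mask contribute to the mean.
#' @return the mean SSIM value.
#' @export
ssim <- function(reference, test, window = 7L, dataRange = NULL, mask = NULL) {
  r <- if (is.matrix(reference)) reference else values(reference)
  t <- if (is.matrix(test)) test else values(test)
  if (!all(dim(r) == dim(t))) stop("shape mismatch")
  if (window > min(dim(r))) stop("window larger than image")
  if (is.null(dataRange)) dataRange <- max(r) - min(r)
  np <- window * window
  covNorm <- np / (np - 1)                 # unbiased covariance
  mu1 <- cpp_boxsum_valid(r, window) / np
  mu2 <- cpp_boxsum_valid(t, window) / np
  s11 <- covNorm * (cpp_boxsum_valid(r * r, window) / np - mu1 * mu1)
  s22 <- covNorm * (cpp_boxsum_valid(t * t, window) / np - mu2 * mu2)
  s12 <- covNorm * (cpp_boxsum_valid(r * t, window) / np - mu1 * mu2)
  c1 <- (0.01 * dataRange)^2
  c2 <- (0.03 * dataRange)^2
  smap <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  if (!is.null(mask)) {
    pad <- (window - 1) / 2
    n <- nrow(mask)
    ctr <- mask[(pad + 1):(n - pad), (pad + 1):(ncol(mask) - pad)]
    mean(smap[ctr])
  } else {
    mean(smap)
  }
}

## both metrics of one reconstruction-domain comparison inside the circle
.reconMetrics <- function(reference, test, window = 7L) {
  r <- if (is.matrix(reference)) reference else values(reference)
  t <- if (is.matrix(test)) test else values(test)
  mask <- .reconMask(nrow(r), margin = 1)
  list(ssim = ssim(r, t, window = window, mask = mask),
       psnr = as.numeric(psnr(r, t, mask = mask)))
}
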
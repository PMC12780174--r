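#' Construct a noise-level comparison table
#'
#' Bundles per-dose noise-level statistics (mean and standard deviation of
#' SSIM and PSNR against a low-noise reference, in the sinogram and the
#' reconstruction domain) for one experimental condition and a grid of
#' simulated photon-count settings.
#'
#' @param table a `data.frame` with columns `type` (`"experimental"` or
#'   `"simulated"`), `i0` (photon count per detector pixel; `NA` for the
#'   experimental row), `ssimSino`, `ssimSinoSd`, `psnrSino`, `psnrSinoSd`,
#'   `ssimRecon`, `ssimReconSd`, `psnrRecon`, `psnrReconSd`.
#' @return a [NoiseLevelTable-class].
#' @export
noiseLevelTable <- function(table) {
  new("NoiseLevelTable", table = as.data.frame(table))
}

#' Published dose-calibration benchmark table
#'
#' Loads the reference noise-level table measured on a real slab-scanner
#' low-dose dataset: one experimental low-dose row and simulated rows at
#' photon counts 200-350. Shipped as plain text in `extdata` so the
#' calibration rule can be exercised and documented without recomputing the
#' underlying scans.
#'
#' @return a [NoiseLevelTable-class].
#' @examples
#' tab <- referenceNoiseLevelTable()
#' selectI0(tab, metric = "psnr", domain = "reconstruction")
#' @export
referenceNoiseLevelTable <- function() {
  path <- system.file("extdata", "tdetect_noise_level_reference.csv",
                      package = "sinogap", mustWork = TRUE)
  noiseLevelTable(read.csv(path))
}

#' Select the simulated photon count matching an experimental noise level
#'
#' The dose-calibration rule: among the simulated rows of a noise-level
#' table, pick the photon count `I0` whose mean metric value is closest to
#' the experimental row's mean, for a chosen metric and domain. Ties break
#' toward the smaller `I0` (the more conservative, noisier setting).
#'
#' @param table a [NoiseLevelTable-class].
#' @param metric `"psnr"` or `"ssim"`.
#' @param domain `"reconstruction"` or `"sinogram"`.
#' @return the selected photon count (numeric scalar), with attribute
#'   `distance` giving the absolute mean-metric gap at the selection.
#' @export
selectI0 <- function(table, metric = c("psnr", "ssim"),
                     domain = c("reconstruction", "sinogram")) {
  stopifnot(is(table, "NoiseLevelTable"))
  metric <- match.arg(metric)
  domain <- match.arg(domain)
  col <- paste0(metric, if (identical(domain, "reconstruction")) "Recon" else "Sino")
  tab <- table@table
  expRow <- tab[tab$type == "experimental", , drop = FALSE]
  simRows <- tab[tab$type == "simulated", , drop = FALSE]
  if (nrow(simRows) == 0L) stop("no simulated rows to select from")
  target <- expRow[[col]]
  if (!is.finite(target)) stop("experimental reference value is not finite")
  dist <- abs(simRows[[col]] - target)
  ## order by distance, then by i0, so ties resolve to the smaller dose
  ord <- order(dist, simRows$i0)
  sel <- ord[1L]
  structure(simRows$i0[sel], distance = dist[sel])
}

#' Measure noise-level statistics for a paired dataset
#'
#' Computes the empirical counterpart of the published calibration table on
#' a synthetic [PairedDataset-class]: for the experimental low-flux
#' acquisition and for monochromatic simulations at each candidate photon
#' count, SSIM and PSNR of the noisy data against the clean reference are
#' averaged over slices, in both the sinogram domain (intensity images)
#' and the reconstruction domain (filtered backprojections).
#'
#' @param dataset a [PairedDataset-class] built by [makePairedDataset()].
#' @param i0Grid numeric vector of candidate simulated photon counts.
#' @param sigmaCrosstalk detector cross-talk fraction used in the simulated
#'   rows.
#' @param seed master seed for the simulated noise draws.
#' @param imageSize reconstruction grid side length.
#' @param filter a [filterSpec()] for the reconstructions.
#' @return a [NoiseLevelTable-class] with one experimental row and one
#'   simulated row per element of `i0Grid`.
#' @export
measureNoiseLevels <- function(dataset, i0Grid = c(100, 150, 200),
                               sigmaCrosstalk = 0.05, seed = 1L,
                               imageSize = 64L,
                               filter = filterSpec("shepp-logan")) {
  stopifnot(is(dataset, "PairedDataset"))
  n <- nSlices(dataset)
  recon <- function(ili) values(reconstructPipeline(
    ili, imageSize = imageSize, filter = filter))
  ## per-slice clean references (shared by all rows)
  cleanIli <- lapply(seq_len(n), function(i)
    flatfieldCorrect(getSlice(dataset, i)$clean))
  cleanRec <- lapply(cleanIli, recon)
  mask <- reconMask(imageSize, margin = 1)

  rowFor <- function(type, i0, noisyIli) {
    sS <- pS <- sR <- pR <- numeric(n)
    for (i in seq_len(n)) {
      vClean <- values(cleanIli[[i]])
      vNoisy <- values(noisyIli[[i]])
      sS[i] <- ssim(vClean, vNoisy)
      pS[i] <- as.numeric(psnr(vClean, vNoisy))
      rNoisy <- recon(noisyIli[[i]])
      sR[i] <- ssim(cleanRec[[i]], rNoisy, mask = mask)
      pR[i] <- as.numeric(psnr(cleanRec[[i]], rNoisy, mask = mask))
    }
    data.frame(type = type, i0 = i0,
               ssimSino = mean(sS), ssimSinoSd = sd(sS),
               psnrSino = mean(pS), psnrSinoSd = sd(pS),
               ssimRecon = mean(sR), ssimReconSd = sd(sR),
               psnrRecon = mean(pR), psnrReconSd = sd(pR))
  }

  noisyIli <- lapply(seq_len(n), function(i)
    flatfieldCorrect(getSlice(dataset, i)$noisy))
  rows <- list(rowFor("experimental", NA_real_, noisyIli))
  for (i0 in i0Grid) {
    simIli <- lapply(seq_len(n), function(i) {
      np <- noiseParams(i0 = i0, sigmaCrosstalk = sigmaCrosstalk,
                        seed = deriveSeed(seed, round(i0), i, .roleCode("sim")))
      simulateNoisyIli(cleanIli[[i]], np)
    })
    rows[[length(rows) + 1L]] <- rowFor("simulated", i0, simIli)
  }
  noiseLevelTable(do.call(rbind, rows))
}

#' Calibrate the simulated photon count against an experimental dataset
#'
#' Convenience wrapper: measure noise levels with [measureNoiseLevels()]
#' and apply [selectI0()].
#'
#' @inheritParams measureNoiseLevels
#' @inheritParams selectI0
#' @return the selected photon count, with the measured table attached as
#'   attribute `table`.
#' @export
calibrateI0 <- function(dataset, i0Grid = c(100, 150, 200),
                        metric = "psnr", domain = "reconstruction",
                        sigmaCrosstalk = 0.05, seed = 1L, imageSize = 64L,
                        filter = filterSpec("shepp-logan")) {
  tab <- measureNoiseLevels(dataset, i0Grid = i0Grid,
                            sigmaCrosstalk = sigmaCrosstalk, seed = seed,
                            imageSize = imageSize, filter = filter)
  sel <- selectI0(tab, metric = metric, domain = domain)
  structure(as.numeric(sel), distance = attr(sel, "distance"), table = tab)
}
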
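## Plain-file serialization: datasets as TIFF images plus a JSON manifest,
## reports as CSV/JSON. No binary container formats are used, so datasets
## remain inspectable with standard image and text tools.

.geometryToList <- function(g) {
  list(beamType = g@beamType, nDetectorPixels = g@nDetectorPixels,
       detectorPixelSize = g@detectorPixelSize, nProjections = g@nProjections,
       angularIncrement = g@angularIncrement, sod = g@sod, sdd = g@sdd)
}

.geometryFromList <- function(l) {
  scanGeometry(beamType = l$beamType, nDetectorPixels = l$nDetectorPixels,
               detectorPixelSize = l$detectorPixelSize,
               nProjections = l$nProjections,
               angularIncrement = l$angularIncrement,
               sod = if (is.null(l$sod)) NA_real_ else l$sod,
               sdd = if (is.null(l$sdd)) NA_real_ else l$sdd)
}

.paramsToList <- function(p) {
  list(tubeVoltage = p@tubeVoltage, tubeCurrent = p@tubeCurrent,
       exposureTime = p@exposureTime, nProj = p@nProj, nAvim = p@nAvim,
       fluxInVacuum = p@fluxInVacuum)
}

.paramsFromList <- function(l) {
  acquisitionParams(tubeVoltage = l$tubeVoltage, tubeCurrent = l$tubeCurrent,
                    exposureTime = l$exposureTime, nProj = l$nProj,
                    nAvim = l$nAvim, fluxInVacuum = l$fluxInVacuum)
}

## TIFF stores [0, 1]; scale each image by its max and record the scale
.writeScaledTiff <- function(m, path) {
  mx <- max(m, 1e-12)
  tiff::writeTIFF(m / mx, path, bits.per.sample = 16L)
  mx
}

.readScaledTiff <- function(path, scale) {
  m <- tiff::readTIFF(path)
  if (is.list(m)) m <- m[[1L]]
  m * scale
}

#' Write a paired dataset to a directory of TIFF + JSON files
#'
#' Each slice is stored as three TIFF images (phantom attenuation layers,
#' clean counts, noisy counts; 16-bit, each scaled by its recorded maximum)
#' next to a single `manifest.json` holding the geometry, spectrum,
#' acquisition parameters, calibration fields, per-image scales and the
#' phantom object tables. [readPairedDataset()] inverts this exactly up to
#' the 16-bit quantization of the TIFF samples.
#'
#' @param dataset a [PairedDataset-class].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writePairedDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "PairedDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nSlices(dataset)
  slices <- vector("list", n)
  for (i in seq_len(n)) {
    sl <- getSlice(dataset, i)
    base <- sprintf("slice%03d", i)
    nE <- dim(sl$phantom@mu)[3]
    muScales <- numeric(nE)
    for (k in seq_len(nE)) {
      muScales[k] <- .writeScaledTiff(
        sl$phantom@mu[, , k],
        file.path(dir, sprintf("%s_mu%d.tif", base, k)))
    }
    cleanScale <- .writeScaledTiff(sl$clean@counts,
                                   file.path(dir, paste0(base, "_clean.tif")))
    noisyScale <- .writeScaledTiff(sl$noisy@counts,
                                   file.path(dir, paste0(base, "_noisy.tif")))
    slices[[i]] <- list(
      base = base, muScales = muScales, cleanScale = cleanScale,
      noisyScale = noisyScale,
      phantom = list(pixelSize = sl$phantom@pixelSize,
                     energies = sl$phantom@energies,
                     objects = sl$phantom@objects),
      clean = list(dark = sl$clean@dark, flat = sl$clean@flat,
                   provenance = sl$clean@provenance),
      noisy = list(dark = sl$noisy@dark, flat = sl$noisy@flat,
                   provenance = sl$noisy@provenance))
  }
  manifest <- list(
    format = "sinogap-paired-dataset", version = 1L,
    geometry = .geometryToList(dataset@geometry),
    spectrum = list(energies = dataset@spectrum@energies,
                    weights = dataset@spectrum@weights,
                    mode = dataset@spectrum@mode),
    surrogateMode = dataset@surrogateMode,
    cleanParams = .paramsToList(dataset@cleanParams),
    noisyParams = .paramsToList(dataset@noisyParams),
    seed = dataset@seed, nSlices = n, slices = slices)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}

#' Read a paired dataset written by [writePairedDataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return a [PairedDataset-class].
#' @export
readPairedDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  if (!identical(manifest$format, "sinogap-paired-dataset"))
    stop("not a sinogap paired-dataset directory")
  num <- function(x) as.numeric(unlist(x))
  geometry <- .geometryFromList(lapply(manifest$geometry, function(x)
    if (is.null(x)) NA_real_ else unlist(x)))
  spectrum <- new("SourceSpectrum", energies = num(manifest$spectrum$energies),
                  weights = num(manifest$spectrum$weights),
                  mode = manifest$spectrum$mode)
  slices <- lapply(seq_len(manifest$nSlices), function(i) {
    sl <- manifest$slices[[i]]
    base <- sl$base
    muScales <- num(sl$muScales)
    nE <- length(muScales)
    layers <- lapply(seq_len(nE), function(k)
      .readScaledTiff(file.path(dir, sprintf("%s_mu%d.tif", base, k)),
                      muScales[k]))
    n <- nrow(layers[[1L]])
    mu <- array(unlist(layers), c(n, n, nE))
    obj <- sl$phantom$objects
    objects <- if (length(obj) == 0L) {
      data.frame(class = character(), cx = numeric(), cy = numeric(),
                 r = numeric(), mu = numeric(), hardening = numeric())
    } else {
      do.call(rbind, lapply(obj, function(o) data.frame(
        class = o$class, cx = o$cx, cy = o$cy, r = o$r, mu = o$mu,
        hardening = o$hardening)))
    }
    ph <- new("Phantom", mu = mu, pixelSize = num(sl$phantom$pixelSize),
              energies = num(sl$phantom$energies), objects = objects)
    mkSino <- function(tag, meta, scale) {
      new("PhotonSinogram",
          counts = .readScaledTiff(file.path(dir, sprintf("%s_%s.tif", base, tag)),
                                   scale),
          dark = num(meta$dark), flat = num(meta$flat), geometry = geometry,
          provenance = meta$provenance)
    }
    list(phantom = ph, clean = mkSino("clean", sl$clean, num(sl$cleanScale)),
         noisy = mkSino("noisy", sl$noisy, num(sl$noisyScale)))
  })
  new("PairedDataset", slices = slices, geometry = geometry,
      spectrum = spectrum, surrogateMode = manifest$surrogateMode,
      cleanParams = .paramsFromList(manifest$cleanParams),
      noisyParams = .paramsFromList(manifest$noisyParams),
      seed = as.integer(manifest$seed))
}

#' Export a study report as plain files
#'
#' Writes `<prefix>_table.csv` (the cross-evaluation matrix),
#' `<prefix>_gaps.csv` (the derived gap statistics) and `<prefix>.json`
#' (both tables plus run metadata).
#'
#' @param report a [StudyReport-class].
#' @param prefix output path prefix.
#' @return the three file paths, invisibly.
#' @export
writeStudyReport <- function(report, prefix) {
  stopifnot(is(report, "StudyReport"))
  d <- dirname(prefix)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  fTable <- paste0(prefix, "_table.csv")
  fGaps <- paste0(prefix, "_gaps.csv")
  fJson <- paste0(prefix, ".json")
  write.csv(report@table, fTable, row.names = FALSE)
  write.csv(report@gaps, fGaps, row.names = FALSE)
  jsonlite::write_json(list(table = report@table, gaps = report@gaps,
                            meta = report@meta),
                       fJson, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(c(table = fTable, gaps = fGaps, json = fJson))
}
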
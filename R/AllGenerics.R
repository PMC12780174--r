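## Generics, accessors and show methods.

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname accessors
#' @param i slice index.
#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))
#' @rdname accessors
#' @export
setGeneric("numParameters", function(x) standardGeneric("numParameters"))
#' @rdname accessors
#' @export
setGeneric("selectedEpoch", function(x) standardGeneric("selectedEpoch"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
#' @rdname accessors
#' @export
setGeneric("calibrationTable", function(x) standardGeneric("calibrationTable"))

#' Accessors for sinogap objects
#'
#' `values()` returns the numeric matrix of an [ILISinogram-class],
#' [AbsorptionSinogram-class] or [ReconImage-class]; `counts()` the raw
#' counts of a [PhotonSinogram-class]; `geometry()`, `provenance()`,
#' `pixelSize()` the corresponding slots; `nSlices()`/`getSlice()` access a
#' [PairedDataset-class]; `numParameters()` counts trainable parameters of a
#' network; `selectedEpoch()`/`trainingHistory()` query a
#' [TrainedModel-class]; `reportTable()` and `calibrationTable()` return the
#' underlying data.frames of a [StudyReport-class] and
#' [NoiseLevelTable-class].
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("values", "ILISinogram", function(x) x@values)
#' @rdname accessors
setMethod("values", "AbsorptionSinogram", function(x) x@values)
#' @rdname accessors
setMethod("values", "ReconImage", function(x) x@values)
#' @rdname accessors
setMethod("counts", "PhotonSinogram", function(x) x@counts)
#' @rdname accessors
setMethod("geometry", "PhotonSinogram", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "ILISinogram", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "AbsorptionSinogram", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "PairedDataset", function(x) x@geometry)
#' @rdname accessors
setMethod("provenance", "PhotonSinogram", function(x) x@provenance)
#' @rdname accessors
setMethod("provenance", "ILISinogram", function(x) x@provenance)
#' @rdname accessors
setMethod("provenance", "AbsorptionSinogram", function(x) x@provenance)
#' @rdname accessors
setMethod("provenance", "ReconImage", function(x) x@provenance)
#' @rdname accessors
setMethod("pixelSize", "Phantom", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "ReconImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("nSlices", "PairedDataset", function(x) length(x@slices))
#' @rdname accessors
setMethod("getSlice", "PairedDataset", function(x, i) x@slices[[i]])
#' @rdname accessors
setMethod("numParameters", "DenoisingNetwork", function(x) {
  sum(unlist(rapply(x@params, length, how = "unlist")))
})
#' @rdname accessors
setMethod("numParameters", "TrainedModel", function(x) numParameters(x@network))
#' @rdname accessors
setMethod("selectedEpoch", "TrainedModel", function(x) x@selectedEpoch)
#' @rdname accessors
setMethod("trainingHistory", "TrainedModel", function(x) x@history)
#' @rdname accessors
setMethod("reportTable", "StudyReport", function(x) x@table)
#' @rdname accessors
setMethod("calibrationTable", "NoiseLevelTable", function(x) x@table)

#' @export
setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: %s beam, %d detector px (%.4g mm), %d projections x %.3g deg\n",
              object@beamType, object@nDetectorPixels, object@detectorPixelSize,
              object@nProjections, object@angularIncrement))
  if (identical(object@beamType, "fan"))
    cat(sprintf("  SOD %.3f mm, SDD %.3f mm\n", object@sod, object@sdd))
})

#' @export
setMethod("show", "Phantom", function(object) {
  d <- dim(object@mu)
  cat(sprintf("Phantom: %d x %d px, %d energy layer(s), %d object(s)\n",
              d[1], d[2], d[3], nrow(object@objects)))
  if (nrow(object@objects) > 0)
    print(table(object@objects$class))
})

#' @export
setMethod("show", "PhotonSinogram", function(object) {
  cat(sprintf("PhotonSinogram [%s]: %d x %d counts, mean %.2f\n",
              object@provenance, nrow(object@counts), ncol(object@counts),
              mean(object@counts)))
})

#' @export
setMethod("show", "ILISinogram", function(object) {
  cat(sprintf("ILISinogram [%s]: %d x %d, range [%.4f, %.4f]\n",
              object@provenance, nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

#' @export
setMethod("show", "AbsorptionSinogram", function(object) {
  cat(sprintf("AbsorptionSinogram [%s]: %d x %d, %d clamped px\n",
              object@provenance, nrow(object@values), ncol(object@values),
              object@nClamped))
})

#' @export
setMethod("show", "ReconImage", function(object) {
  cat(sprintf("ReconImage [%s]: %d x %d px\n", object@provenance,
              nrow(object@values), ncol(object@values)))
})

#' @export
setMethod("show", "DenoisingNetwork", function(object) {
  s <- object@spec
  arch <- if (identical(s@family, "unet"))
    sprintf("U-Net (depth %d, base %d)", s@depth, s@baseChannels)
  else
    sprintf("MSD-Net (%d layers, dilation cycle %d)", s@nLayers, s@dilationCycle)
  cat(sprintf("DenoisingNetwork: %s, %d parameters\n", arch, numParameters(object)))
})

#' @export
setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s domain, trained on %s\n", object@domain,
              object@trainingData))
  show(object@network)
  if (nrow(object@history) > 0)
    cat(sprintf("  selected epoch %d / %d (val loss %.4g)\n", object@selectedEpoch,
                nrow(object@history), min(object@history$valLoss)))
})

#' @export
setMethod("show", "PairedDataset", function(object) {
  cat(sprintf("PairedDataset: %d slice(s), %s physics, flux clean/noisy = %.0f/%.0f\n",
              length(object@slices), object@surrogateMode,
              object@cleanParams@fluxInVacuum, object@noisyParams@fluxInVacuum))
})

#' @export
setMethod("show", "NoiseLevelTable", function(object) {
  cat("NoiseLevelTable:\n")
  print(object@table, digits = 4, row.names = FALSE)
})

#' @export
setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d cells over %d test slice(s) per set\n",
              nrow(object@table), if (nrow(object@table)) object@table$n[1] else 0L))
  print(object@table, digits = 4, row.names = FALSE)
  if (nrow(object@gaps)) {
    cat("Gap statistics:\n")
    print(object@gaps, digits = 4, row.names = FALSE)
  }
})
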
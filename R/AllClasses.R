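## S4 class definitions for sinogap.

.iliProvenances <- c("experimental_clean", "experimental_noisy",
                     "simulated_noisy", "denoised")
.reconProvenances <- c("fbp_of_clean", "fbp_of_noisy", "fbp_of_denoised",
                       "ground_truth_phantom")

#' ScanGeometry: CT acquisition geometry
#'
#' Describes a 2D CT acquisition: beam type, detector layout and angular
#' sampling. Fan-beam geometries additionally carry the source-object (SOD)
#' and source-detector (SDD) distances. Lengths are in millimetres.
#'
#' @slot beamType `"parallel"` or `"fan"`.
#' @slot nDetectorPixels number of (binned) detector pixels.
#' @slot detectorPixelSize detector pixel pitch in mm.
#' @slot nProjections number of projection angles.
#' @slot angularIncrement angular step between projections in degrees.
#' @slot sod,sdd source-object / source-detector distance in mm (fan only).
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(beamType = "character", nDetectorPixels = "integer",
                 detectorPixelSize = "numeric", nProjections = "integer",
                 angularIncrement = "numeric", sod = "numeric", sdd = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@beamType %in% c("parallel", "fan"))
      msg <- c(msg, "beamType must be 'parallel' or 'fan'")
    if (object@nDetectorPixels < 1L || object@nProjections < 1L)
      msg <- c(msg, "detector pixel and projection counts must be positive")
    if (object@detectorPixelSize <= 0 || object@angularIncrement <= 0)
      msg <- c(msg, "detector pixel size and angular increment must be positive")
    span <- object@nProjections * object@angularIncrement
    need <- if (identical(object@beamType, "fan")) 360 else 180
    if (span < need - 1e-9)
      msg <- c(msg, sprintf("angular coverage %.2f deg < required %d deg", span, need))
    if (identical(object@beamType, "fan") &&
        (!is.finite(object@sod) || !is.finite(object@sdd) ||
         object@sod <= 0 || object@sdd <= object@sod))
      msg <- c(msg, "fan beam requires 0 < SOD < SDD")
    if (is.null(msg)) TRUE else msg
  })

#' SourceSpectrum: X-ray source energy spectrum
#'
#' A discrete source spectrum. The monochromatic mode has a single energy
#' bin and is the basis of the standard Radon/Beer-Lambert model; the
#' two-energy surrogate mode adds a second bin with energy-dependent
#' attenuation so that beam hardening (a polychromatic effect the
#' monochromatic noise model cannot express) is present in "experimental
#' surrogate" acquisitions.
#'
#' @slot energies energy per bin (keV, nominal labels).
#' @slot weights nonnegative bin weights summing to one.
#' @slot mode `"monochromatic"` or `"two_energy_surrogate"`.
#' @exportClass SourceSpectrum
setClass("SourceSpectrum",
  representation(energies = "numeric", weights = "numeric", mode = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@mode %in% c("monochromatic", "two_energy_surrogate"))
      msg <- c(msg, "unknown spectrum mode")
    if (identical(object@mode, "monochromatic") && length(object@energies) != 1L)
      msg <- c(msg, "monochromatic spectrum must have exactly one bin")
    if (length(object@energies) != length(object@weights))
      msg <- c(msg, "energies and weights must have equal length")
    if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must be nonnegative and sum to 1")
    if (is.null(msg)) TRUE else msg
  })

#' Phantom: 2D attenuation map with tagged content
#'
#' A square grid of linear attenuation coefficients (per pixel length), one
#' layer per energy bin, plus descriptors of the objects it contains. The
#' content classes mirror the scanned-slice content of the 2DeteCT
#' collection: a low-attenuation matrix plus optional high-attenuation
#' "stone" objects, small or large-and-grouped (the latter drive beam
#' hardening streaks under polychromatic physics).
#'
#' @slot mu numeric array (N, N, nEnergies) of attenuation per pixel length.
#' @slot pixelSize pixel edge length (mm; bookkeeping only).
#' @slot energies nominal energy per layer (keV).
#' @slot objects data.frame of object descriptors
#'   (class, cx, cy, r, mu, hardening).
#' @exportClass Phantom
setClass("Phantom",
  representation(mu = "array", pixelSize = "numeric", energies = "numeric",
                 objects = "data.frame"),
  validity = function(object) {
    d <- dim(object@mu)
    msg <- NULL
    if (length(d) != 3L || d[1] != d[2])
      msg <- c(msg, "mu must be a square (N, N, nEnergies) array")
    if (any(object@mu < 0)) msg <- c(msg, "attenuation must be nonnegative")
    if (length(object@energies) != d[3])
      msg <- c(msg, "one energy label per mu layer required")
    if (nrow(object@objects) > 0) {
      n <- d[1]
      ok <- object@objects$cx - object@objects$r >= 0.5 &
        object@objects$cx + object@objects$r <= n + 0.5 &
        object@objects$cy - object@objects$r >= 0.5 &
        object@objects$cy + object@objects$r <= n + 0.5
      if (!all(ok)) msg <- c(msg, "tagged objects must lie within the grid")
    }
    if (is.null(msg)) TRUE else msg
  })

#' AcquisitionParams: scan settings of one acquisition
#'
#' The five acquisition parameters that control quantum noise (tube voltage
#' V, tube current I, exposure time t, number of projections and number of
#' averaged images), plus the expected photon count per detector pixel with
#' no object in the beam (flux in vacuum). Paired clean/noisy acquisitions
#' of the same slice differ only in tube current, and flux is proportional
#' to current.
#'
#' @slot tubeVoltage kV. @slot tubeCurrent uA. @slot exposureTime ms.
#' @slot nProj number of projections. @slot nAvim number of averaged images.
#' @slot fluxInVacuum expected photons per pixel with no object.
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(tubeVoltage = "numeric", tubeCurrent = "numeric",
                 exposureTime = "numeric", nProj = "numeric", nAvim = "numeric",
                 fluxInVacuum = "numeric"),
  validity = function(object) {
    v <- c(object@tubeVoltage, object@tubeCurrent, object@exposureTime,
           object@nProj, object@nAvim, object@fluxInVacuum)
    if (any(!is.finite(v)) || any(v <= 0)) "all acquisition parameters must be positive" else TRUE
  })

#' PhotonSinogram: raw detector counts with calibration fields
#'
#' Raw counts S (nProjections x nDetectorPixels) together with the paired
#' per-pixel dark field D (source off) and flat field F (source on, no
#' object) used for flat-field correction.
#'
#' @slot counts nonnegative counts matrix (nProjections x nDetectorPixels).
#' @slot dark,flat per-detector-pixel calibration vectors; `flat > dark`.
#' @slot geometry the [ScanGeometry-class] of the acquisition.
#' @slot provenance `"experimental_clean"` or `"experimental_noisy"`.
#' @exportClass PhotonSinogram
setClass("PhotonSinogram",
  representation(counts = "matrix", dark = "numeric", flat = "numeric",
                 geometry = "ScanGeometry", provenance = "character"),
  validity = function(object) {
    msg <- NULL
    g <- object@geometry
    if (!all(dim(object@counts) == c(g@nProjections, g@nDetectorPixels)))
      msg <- c(msg, "counts shape must match geometry (nProjections x nDetectorPixels)")
    if (length(object@dark) != g@nDetectorPixels ||
        length(object@flat) != g@nDetectorPixels)
      msg <- c(msg, "dark/flat must have one value per detector pixel")
    if (any(object@flat <= object@dark))
      msg <- c(msg, "flat field must exceed dark field at every pixel")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (!object@provenance %in% c("experimental_clean", "experimental_noisy"))
      msg <- c(msg, "unknown provenance")
    if (is.null(msg)) TRUE else msg
  })

#' ILISinogram: beam intensity loss image
#'
#' The flat-field-corrected sinogram `(S - D) / (F - D)`, the fraction of
#' beam intensity surviving along each ray. Values are nominally in `[0, 1]`
#' but noise may push individual pixels slightly outside; overshoot is
#' deliberately retained here (it is part of the noise distribution a
#' denoiser must learn) and only handled at the log step. All denoising in
#' this package consumes ILI (pre-log) data, never absorption sinograms.
#'
#' @slot values the ILI matrix (nProjections x nDetectorPixels).
#' @slot geometry the acquisition geometry.
#' @slot provenance one of `"experimental_clean"`, `"experimental_noisy"`,
#'   `"simulated_noisy"`, `"denoised"`.
#' @exportClass ILISinogram
setClass("ILISinogram",
  representation(values = "matrix", geometry = "ScanGeometry",
                 provenance = "character"),
  validity = function(object) {
    msg <- NULL
    g <- object@geometry
    if (!all(dim(object@values) == c(g@nProjections, g@nDetectorPixels)))
      msg <- c(msg, "values shape must match geometry")
    if (!object@provenance %in% .iliProvenances)
      msg <- c(msg, "unknown provenance tag")
    if (is.null(msg)) TRUE else msg
  })

#' AbsorptionSinogram: negative-log sinogram
#'
#' `y = -log(max(ILI, epsilon))` with negative values (from ILI overshoot)
#' clamped to zero: the Beer-Lambert line integrals input to reconstruction.
#'
#' @slot values the absorption matrix, nonnegative and finite.
#' @slot epsilon the clamping floor applied before the logarithm.
#' @slot nClamped number of pixels affected by either clamp.
#' @slot geometry,provenance as in [ILISinogram-class].
#' @exportClass AbsorptionSinogram
setClass("AbsorptionSinogram",
  representation(values = "matrix", epsilon = "numeric", nClamped = "integer",
                 geometry = "ScanGeometry", provenance = "character"),
  validity = function(object) {
    msg <- NULL
    if (any(!is.finite(object@values)) || any(object@values < 0))
      msg <- c(msg, "absorption values must be finite and nonnegative")
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' ReconImage: reconstructed attenuation image
#'
#' @slot values N x N attenuation image (per pixel length); pixels outside
#'   the inscribed reconstruction circle are zero.
#' @slot pixelSize pixel edge length (mm).
#' @slot provenance one of `"fbp_of_clean"`, `"fbp_of_noisy"`,
#'   `"fbp_of_denoised"`, `"ground_truth_phantom"`.
#' @exportClass ReconImage
setClass("ReconImage",
  representation(values = "matrix", pixelSize = "numeric", provenance = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@values) != ncol(object@values))
      msg <- c(msg, "reconstruction must be square")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (!object@provenance %in% .reconProvenances)
      msg <- c(msg, "unknown provenance tag")
    if (is.null(msg)) TRUE else msg
  })

#' NoiseParams: parameters of the simplified detector noise model
#'
#' @slot i0 photons-in-vacuum scale of the Poisson component; lower values
#'   mean noisier data. Default 200 (the empirically calibrated level for
#'   2DeteCT-like data).
#' @slot sigmaElectronic standard deviation of the zero-mean Gaussian
#'   electronic (readout) noise, in photon-count units. Default 0: for
#'   photon-counting regimes well above the starvation floor electronic
#'   noise is usually negligible; it stays configurable.
#' @slot sigmaCrosstalk fraction of each pixel's signal shared with its two
#'   adjacent detector pixels, in `[0, 1)`. Default 0.05.
#' @slot seed RNG seed for the noise draws.
#' @exportClass NoiseParams
setClass("NoiseParams",
  representation(i0 = "numeric", sigmaElectronic = "numeric",
                 sigmaCrosstalk = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@i0 <= 0) msg <- c(msg, "i0 must be positive")
    if (object@sigmaElectronic < 0) msg <- c(msg, "sigmaElectronic must be >= 0")
    if (object@sigmaCrosstalk < 0 || object@sigmaCrosstalk >= 1)
      msg <- c(msg, "sigmaCrosstalk must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' CrosstalkOperator: banded detector mixing matrix
#'
#' Row-stochastic banded matrix Gamma applied along the detector axis;
#' interior rows are `(sigma/2, 1 - sigma, sigma/2)`, boundary rows are
#' renormalized to sum to one. `sigma = 0` yields the identity.
#'
#' @slot size detector pixel count D.
#' @slot sigma total fraction of signal shared with the two neighbours.
#' @slot matrix the D x D sparse mixing matrix.
#' @exportClass CrosstalkOperator
setClass("CrosstalkOperator",
  representation(size = "integer", sigma = "numeric", matrix = "Matrix"),
  validity = function(object) {
    msg <- NULL
    if (any(abs(Matrix::rowSums(object@matrix) - 1) > 1e-12))
      msg <- c(msg, "rows must sum to 1")
    if (any(object@matrix < 0)) msg <- c(msg, "entries must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' FilterSpec: reconstruction filter for FBP
#'
#' @slot kind `"ramp"` (Ram-Lak), `"shepp-logan"` or `"hann"`.
#' @slot cutoff cutoff as a fraction of the Nyquist frequency, in `(0, 1]`.
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(kind = "character", cutoff = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("ramp", "shepp-logan", "hann"))
      msg <- c(msg, "unknown filter kind")
    if (object@cutoff <= 0 || object@cutoff > 1)
      msg <- c(msg, "cutoff must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' NetworkSpec: denoiser architecture specification
#'
#' Describes either a small U-Net (an encoder-decoder with skip connections,
#' `depth` resolution levels and `baseChannels` feature maps at the top
#' level) or a mixed-scale dense network (MSD-Net: `nLayers` width-one
#' densely connected layers whose dilated 3x3 convolutions cycle through
#' dilations `1..dilationCycle` instead of using scaling operations). Both
#' map a one-channel image to a one-channel image of the same size and add
#' the input back (residual denoising).
#'
#' @slot family `"unet"` or `"msdnet"`.
#' @slot depth,baseChannels U-Net resolution levels / top-level channels.
#' @slot nLayers,dilationCycle MSD-Net layer count / dilation cycle length.
#' @slot seed weight-initialization seed.
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(family = "character", depth = "integer", baseChannels = "integer",
                 nLayers = "integer", dilationCycle = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@family %in% c("unet", "msdnet")) msg <- c(msg, "unknown family")
    if (identical(object@family, "unet") &&
        (object@depth < 1L || object@baseChannels < 1L))
      msg <- c(msg, "unet depth and baseChannels must be positive")
    if (identical(object@family, "msdnet") &&
        (object@nLayers < 1L || object@dilationCycle < 1L))
      msg <- c(msg, "msdnet nLayers and dilationCycle must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' DenoisingNetwork: an (untrained or trained) denoiser network
#'
#' @slot spec the [NetworkSpec-class].
#' @slot params nested list of convolution weights and biases.
#' @exportClass DenoisingNetwork
setClass("DenoisingNetwork",
  representation(spec = "NetworkSpec", params = "list"))

#' TrainingConfig: supervised training settings
#'
#' @slot domain `"sinogram"` (noisy ILI -> clean ILI) or `"reconstruction"`
#'   (FBP of noisy data -> clean reconstruction).
#' @slot epochs number of epochs. @slot learningRate Adam step size.
#' @slot batchSize gradient-accumulation batch size. @slot loss `"mse"`.
#' @slot seed RNG seed for shuffling/initialization.
#' @slot splitFractions train/validation/test fractions summing to one.
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(domain = "character", epochs = "integer", learningRate = "numeric",
                 batchSize = "integer", loss = "character", seed = "integer",
                 splitFractions = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@domain %in% c("sinogram", "reconstruction"))
      msg <- c(msg, "domain must be 'sinogram' or 'reconstruction'")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (abs(sum(object@splitFractions) - 1) > 1e-9)
      msg <- c(msg, "split fractions must sum to 1")
    if (!identical(object@loss, "mse")) msg <- c(msg, "only 'mse' loss is available")
    if (is.null(msg)) TRUE else msg
  })

#' TrainedModel: a fitted denoiser with its training provenance
#'
#' The stored weights are those of the epoch with minimal validation loss;
#' the full per-epoch loss history is retained.
#'
#' @slot network the fitted [DenoisingNetwork-class].
#' @slot config the [TrainingConfig-class] used.
#' @slot history data.frame with epoch, trainLoss, valLoss.
#' @slot selectedEpoch epoch whose weights are stored (argmin valLoss).
#' @slot trainingData `"experimental_noisy"` or `"simulated_noisy"`.
#' @slot domain training domain (`"sinogram"` / `"reconstruction"`).
#' @slot scale input/target normalization factor applied around the network.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(network = "DenoisingNetwork", config = "TrainingConfig",
                 history = "data.frame", selectedEpoch = "integer",
                 trainingData = "character", domain = "character",
                 scale = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@history) > 0 &&
        object@selectedEpoch != which.min(object@history$valLoss))
      msg <- c(msg, "selectedEpoch must attain the minimum validation loss")
    if (!object@trainingData %in% c("experimental_noisy", "simulated_noisy"))
      msg <- c(msg, "unknown trainingData provenance")
    if (!object@domain %in% c("sinogram", "reconstruction"))
      msg <- c(msg, "unknown domain")
    if (is.null(msg)) TRUE else msg
  })

#' PairedDataset: paired clean/noisy acquisitions of the same slices
#'
#' Each slice holds one [Phantom-class] and a clean and a noisy
#' [PhotonSinogram-class] of it that differ only in tube current.
#'
#' @slot slices list of `list(phantom, clean, noisy)`.
#' @slot geometry,spectrum shared acquisition geometry and spectrum.
#' @slot surrogateMode `"monochromatic"` or `"experimental_surrogate"`.
#' @slot cleanParams,noisyParams the two [AcquisitionParams-class].
#' @slot seed master seed the dataset is a pure function of.
#' @exportClass PairedDataset
setClass("PairedDataset",
  representation(slices = "list", geometry = "ScanGeometry",
                 spectrum = "SourceSpectrum", surrogateMode = "character",
                 cleanParams = "AcquisitionParams", noisyParams = "AcquisitionParams",
                 seed = "integer"))

#' NoiseLevelTable: empirical noise-level calibration table
#'
#' One row per candidate noise level I0 (simulated rows) plus one
#' experimental-reference row, each with sinogram-domain and
#' reconstruction-domain SSIM/PSNR (mean and sd over slices).
#'
#' @slot table data.frame with columns type, i0, ssimSino, ssimSinoSd,
#'   psnrSino, psnrSinoSd, ssimRecon, ssimReconSd, psnrRecon, psnrReconSd, n.
#' @exportClass NoiseLevelTable
setClass("NoiseLevelTable", representation(table = "data.frame"),
  validity = function(object) {
    tab <- object@table
    need <- c("type", "i0", "ssimSino", "psnrSino", "ssimRecon", "psnrRecon")
    msg <- NULL
    if (!all(need %in% names(tab))) msg <- c(msg, "missing required columns")
    if (sum(tab$type == "experimental") != 1L)
      msg <- c(msg, "exactly one experimental reference row required")
    if (is.null(msg)) TRUE else msg
  })

#' StudyReport: cross-evaluation study matrix with gap statistics
#'
#' The (architecture x training data x test data x evaluation domain) metric
#' matrix aggregated as mean and sd over test slices, plus derived gap
#' statistics (differences between named cells).
#'
#' @slot table tidy data.frame with columns architecture, trainingData,
#'   testData, domain, metric, mean, sd, n.
#' @slot gaps data.frame of named derived differences.
#' @slot meta list of run metadata (calibrated i0, seeds, sizes, ...).
#' @exportClass StudyReport
setClass("StudyReport",
  representation(table = "data.frame", gaps = "data.frame", meta = "list"))
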
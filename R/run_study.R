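#' Configuration of a full sim-to-real denoising study
#'
#' Bundles every knob of [runStudy()] in one object. Two presets are
#' provided: `"desk"` runs in minutes on a single CPU (64 px phantoms,
#' small networks, few slices) while preserving every structural element of
#' the full-scale study; `"benchmark"` mirrors the full-scale slab-scanner
#' setup (956-pixel fan-beam geometry, 100 epochs) and is only practical
#' with substantial compute.
#'
#' @param preset `"desk"` or `"benchmark"`.
#' @param nSlices,imageSize,epochs,fluxNoisy,i0Grid,sigmaCrosstalk,seed
#'   overrides of the preset values.
#' @return a list of study settings (class `"studyConfig"`).
#' @export
studyConfig <- function(preset = c("desk", "benchmark"), nSlices = NULL,
                        imageSize = NULL, epochs = NULL, fluxNoisy = NULL,
                        i0Grid = NULL, sigmaCrosstalk = NULL, seed = 1L) {
  preset <- match.arg(preset)
  cfg <- if (identical(preset, "desk")) {
    list(preset = preset, geometry = deskGeometry(), nSlices = 60L,
         imageSize = 64L, epochs = 20L, fluxNoisy = 200,
         i0Grid = c(100, 150, 200), sigmaCrosstalk = 0.05,
         unet = list(depth = 2L, baseChannels = 4L),
         msdnet = list(nLayers = 8L, dilationCycle = 4L),
         batchSize = 4L, learningRate = 1e-3,
         filter = filterSpec("shepp-logan"))
  } else {
    list(preset = preset, geometry = tdetectGeometry(), nSlices = 4950L,
         imageSize = 956L, epochs = 100L, fluxNoisy = 200,
         i0Grid = c(200, 250, 300, 350), sigmaCrosstalk = 0.05,
         unet = list(depth = 3L, baseChannels = 16L),
         msdnet = list(nLayers = 30L, dilationCycle = 10L),
         batchSize = 4L, learningRate = 1e-3,
         filter = filterSpec("shepp-logan"))
  }
  if (!is.null(nSlices)) cfg$nSlices <- as.integer(nSlices)
  if (!is.null(imageSize)) cfg$imageSize <- as.integer(imageSize)
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  if (!is.null(fluxNoisy)) cfg$fluxNoisy <- fluxNoisy
  if (!is.null(i0Grid)) cfg$i0Grid <- i0Grid
  if (!is.null(sigmaCrosstalk)) cfg$sigmaCrosstalk <- sigmaCrosstalk
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "studyConfig")
}

#' Run the complete sim-to-real denoising study
#'
#' End-to-end driver: (1) generate a paired clean/noisy surrogate dataset
#' plus a monochromatic companion dataset of the same phantoms (no beam
#' hardening, scatter or electronic noise), (2) split it 80/10/10,
#' (3) calibrate the simulated photon count against the experimental noise
#' level on the validation slices, (4) train the model grid -- each
#' architecture (U-Net, MSD-Net) on experimental-surrogate noise and on
#' monochromatic simulated noise, in the sinogram and the reconstruction
#' domain, eight models in total -- and (5) cross-evaluate everything on
#' the test slices.
#'
#' @param config a [studyConfig()].
#' @param verbose print progress lines.
#' @return a list with elements `dataset`, `datasetMono`, `split`,
#'   `calibratedI0` (with the measured [NoiseLevelTable-class] attached),
#'   `models` (named list of [TrainedModel-class]), and `report` (a
#'   [StudyReport-class]).
#' @export
runStudy <- function(config = studyConfig(), verbose = interactive()) {
  stopifnot(inherits(config, "studyConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  say("generating %d paired slices ...", config$nSlices)
  pars <- pairedAcquisitionParams(config$geometry, config$fluxNoisy)
  dataset <- makePairedDataset(
    config$nSlices, geometry = config$geometry,
    surrogateMode = "experimental_surrogate",
    cleanParams = pars$clean, noisyParams = pars$noisy,
    seed = seed, imageSize = config$imageSize)
  ## companion dataset of the same phantoms acquired with the monochromatic
  ## model: no beam hardening, scatter or electronic noise -- the source of
  ## the "simulated" training arm and of the simulated test data
  datasetMono <- makePairedDataset(
    config$nSlices, geometry = config$geometry,
    surrogateMode = "monochromatic",
    cleanParams = pars$clean, noisyParams = pars$noisy,
    seed = seed, detector = noiseParams(sigmaElectronic = 0),
    imageSize = config$imageSize)
  split <- splitDataset(nSlices(dataset), seed = deriveSeed(seed, .roleCode("split")))

  say("calibrating simulated photon count on %d validation slices ...",
      length(split$validation))
  calSubset <- new("PairedDataset", slices = dataset@slices[split$validation],
                   geometry = dataset@geometry, spectrum = dataset@spectrum,
                   surrogateMode = dataset@surrogateMode,
                   cleanParams = dataset@cleanParams,
                   noisyParams = dataset@noisyParams, seed = dataset@seed)
  i0 <- calibrateI0(calSubset, i0Grid = config$i0Grid, metric = "psnr",
                    domain = "reconstruction",
                    sigmaCrosstalk = config$sigmaCrosstalk, seed = seed,
                    imageSize = config$imageSize, filter = config$filter)
  say("calibrated I0 = %g", as.numeric(i0))

  models <- list()
  for (domain in c("sinogram", "reconstruction")) {
    for (td in c("experimental", "simulated")) {
      trainDs <- if (identical(td, "simulated")) datasetMono else dataset
      pairsTrain <- makeTrainingPairs(
        trainDs, split$train, trainingData = td, domain = domain,
        i0 = as.numeric(i0), sigmaCrosstalk = config$sigmaCrosstalk,
        seed = deriveSeed(seed, .roleCode("sim")),
        imageSize = config$imageSize, filter = config$filter)
      pairsVal <- makeTrainingPairs(
        trainDs, split$validation, trainingData = td, domain = domain,
        i0 = as.numeric(i0), sigmaCrosstalk = config$sigmaCrosstalk,
        seed = deriveSeed(seed, .roleCode("sim"), 2L),
        imageSize = config$imageSize, filter = config$filter)
      if (identical(domain, "reconstruction")) {
        ## validation targets must live on the training scale
        f <- pairsTrain$scale / pairsVal$scale
        pairsVal$inputs <- lapply(pairsVal$inputs, `*`, f)
        pairsVal$targets <- lapply(pairsVal$targets, `*`, f)
        pairsVal$scale <- pairsTrain$scale
      }
      for (arch in c("unet", "msdnet")) {
        nm <- paste(arch, td, domain, sep = "_")
        say("training %s ...", nm)
        ## paired design: the two training-data arms of the same
        ## architecture/domain share their weight initialization, so their
        ## comparison isolates the training-data effect
        wseed <- deriveSeed(seed, .roleCode("weights"),
                            match(arch, c("unet", "msdnet")),
                            match(domain, c("sinogram", "reconstruction")))
        spec <- if (identical(arch, "unet")) {
          networkSpec("unet", depth = config$unet$depth,
                      baseChannels = config$unet$baseChannels, seed = wseed)
        } else {
          networkSpec("msdnet", nLayers = config$msdnet$nLayers,
                      dilationCycle = config$msdnet$dilationCycle,
                      seed = wseed)
        }
        tc <- trainingConfig(domain, epochs = config$epochs,
                             learningRate = config$learningRate,
                             batchSize = config$batchSize,
                             seed = deriveSeed(seed, .roleCode("shuffle")))
        models[[nm]] <- trainDenoiser(buildNetwork(spec), pairsTrain, tc,
                                      valPairs = pairsVal)
      }
    }
  }

  say("cross-evaluating on %d test slices ...", length(split$test))
  report <- evaluateStudy(dataset, models, split$test,
                          simDataset = datasetMono, i0 = as.numeric(i0),
                          sigmaCrosstalk = config$sigmaCrosstalk,
                          seed = deriveSeed(seed, .roleCode("test_sim")),
                          imageSize = config$imageSize, filter = config$filter)
  list(dataset = dataset, datasetMono = datasetMono, split = split,
       calibratedI0 = i0, models = models, report = report)
}
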
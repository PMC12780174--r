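#' Construct a training configuration
#'
#' @param domain `"sinogram"` (noisy ILI -> clean ILI) or
#'   `"reconstruction"` (FBP of the noisy acquisition -> clean
#'   reconstruction, the "FBP+" models).
#' @param epochs training epochs (the full-scale preset uses 100; the desk
#'   preset 20).
#' @param learningRate Adam step size (default `1e-3`).
#' @param batchSize gradient-accumulation batch size (default 4).
#' @param loss `"mse"`.
#' @param seed RNG seed for shuffling.
#' @param splitFractions train/validation/test fractions (default
#'   80/10/10).
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(domain = c("sinogram", "reconstruction"),
                           epochs = 20L, learningRate = 1e-3, batchSize = 4L,
                           loss = "mse", seed = 1L,
                           splitFractions = c(0.8, 0.1, 0.1)) {
  new("TrainingConfig", domain = match.arg(domain), epochs = as.integer(epochs),
      learningRate = learningRate, batchSize = as.integer(batchSize),
      loss = loss, seed = as.integer(seed), splitFractions = splitFractions)
}

#' Split slice indices into train/validation/test sets
#'
#' Disjoint, exhaustive and deterministic per seed. Validation and test
#' sizes are `floor(n * fraction)`; the remainder goes to training (so 10
#' slices at 80/10/10 give 8/1/1 and 60 give 48/6/6).
#'
#' @param n number of slices, or a [PairedDataset-class].
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed RNG seed.
#' @return list with integer vectors `train`, `validation`, `test`.
#' @export
splitDataset <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (is(n, "PairedDataset")) n <- nSlices(n)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  nVal <- floor(n * fractions[2])
  nTest <- floor(n * fractions[3])
  nTrain <- n - nVal - nTest
  idx <- withSeed(seed, sample.int(n))
  list(train = sort(idx[seq_len(nTrain)]),
       validation = sort(idx[nTrain + seq_len(nVal)]),
       test = sort(idx[nTrain + nVal + seq_len(nTest)]))
}

#' Reference split sizes of the 2DeteCT denoising benchmark
#'
#' The documented ~80/10/10 slice split of the full-scale experimental
#' collection, stored as a named preset.
#'
#' @format integer vector with elements train, validation, test.
#' @export
tdetectSplitSizes <- c(train = 3930L, validation = 550L, test = 470L)

#' Select the model epoch from a validation-loss history
#'
#' The reported weights are always those of the epoch attaining the minimal
#' validation loss (earliest epoch on ties).
#'
#' @param valLosses numeric vector of per-epoch validation losses.
#' @return the selected epoch index.
#' @export
selectEpoch <- function(valLosses) which.min(valLosses)

#' Build supervised training pairs from a paired dataset
#'
#' Assembles (input, target) image pairs for one training-data type and
#' domain. Targets are always derived from the clean acquisition. Inputs
#' are the experimental noisy acquisition (`"experimental"`) or clean data
#' with simulated noise at level `i0` (`"simulated"`, via
#' [simulateNoisyIli()] with fresh per-slice seeds). In the sinogram domain
#' the pair is (noisy ILI, clean ILI); in the reconstruction domain both
#' sides are passed through [reconstructPipeline()] first and jointly
#' rescaled so targets lie in about `[0, 1]`. All denoising inputs are
#' pre-log ILI data; absorption sinograms are never consumed.
#'
#' @param dataset a [PairedDataset-class].
#' @param indices slice indices to use.
#' @param trainingData `"experimental"` or `"simulated"`.
#' @param domain `"sinogram"` or `"reconstruction"`.
#' @param i0 noise level for simulated noise.
#' @param sigmaCrosstalk cross-talk fraction of the simulated noise.
#' @param seed seed for the simulated-noise draws.
#' @param imageSize reconstruction size (reconstruction domain only).
#' @param filter FBP filter.
#' @return a list of class `"trainingPairs"`.
#' @export
makeTrainingPairs <- function(dataset, indices,
                              trainingData = c("experimental", "simulated"),
                              domain = c("sinogram", "reconstruction"),
                              i0 = 200, sigmaCrosstalk = 0.05, seed = 1L,
                              imageSize = 64L, filter = filterSpec()) {
  stopifnot(is(dataset, "PairedDataset"))
  trainingData <- match.arg(trainingData)
  domain <- match.arg(domain)
  inputs <- vector("list", length(indices))
  targets <- vector("list", length(indices))
  for (k in seq_along(indices)) {
    i <- indices[k]
    sl <- getSlice(dataset, i)
    cleanIli <- flatfieldCorrect(sl$clean)
    noisyIli <- if (identical(trainingData, "experimental")) {
      flatfieldCorrect(sl$noisy)
    } else {
      simulateNoisyIli(cleanIli, noiseParams(
        i0 = i0, sigmaCrosstalk = sigmaCrosstalk,
        seed = deriveSeed(seed, i, .roleCode("sim"))))
    }
    if (identical(domain, "sinogram")) {
      inputs[[k]] <- noisyIli@values
      targets[[k]] <- cleanIli@values
    } else {
      inputs[[k]] <- values(reconstructPipeline(noisyIli, filter = filter,
                                                imageSize = imageSize))
      targets[[k]] <- values(reconstructPipeline(cleanIli, filter = filter,
                                                 imageSize = imageSize))
    }
  }
  scale <- 1
  if (identical(domain, "reconstruction")) {
    m <- max(vapply(targets, function(t) max(abs(t)), numeric(1)), 1e-12)
    scale <- 1 / m
    inputs <- lapply(inputs, `*`, scale)
    targets <- lapply(targets, `*`, scale)
  }
  structure(list(inputs = inputs, targets = targets, domain = domain,
                 trainingData = paste0(
                   if (identical(trainingData, "experimental")) "experimental"
                   else "simulated", "_noisy"),
                 scale = scale, geometry = dataset@geometry,
                 imageSize = imageSize),
            class = "trainingPairs")
}

.mse <- function(a, b) mean((a - b)^2)

#' Train a denoiser network
#'
#' Supervised training with Adam on mean squared error. The returned model
#' carries the weights of the epoch with minimal validation loss and the
#' full per-epoch loss history. Training is deterministic given the config
#' seed and pair order.
#'
#' @param network an untrained [DenoisingNetwork-class].
#' @param pairs training pairs from [makeTrainingPairs()].
#' @param config a [TrainingConfig-class]; its domain must match the pairs.
#' @param valPairs validation pairs; if `NULL`, `pairs` are split by
#'   `config@splitFractions` internally.
#' @return a [TrainedModel-class].
#' @export
trainDenoiser <- function(network, pairs, config, valPairs = NULL) {
  stopifnot(is(network, "DenoisingNetwork"), inherits(pairs, "trainingPairs"),
            is(config, "TrainingConfig"))
  if (!identical(pairs$domain, config@domain))
    stop("training pairs domain '", pairs$domain,
         "' does not match config domain '", config@domain, "'")
  if (is.null(valPairs)) {
    sp <- splitDataset(length(pairs$inputs), config@splitFractions, config@seed)
    if (length(sp$validation) < 1 || length(sp$train) < 1)
      stop("empty training or validation split")
    valPairs <- list(inputs = pairs$inputs[sp$validation],
                     targets = pairs$targets[sp$validation])
    pairs$inputs <- pairs$inputs[sp$train]
    pairs$targets <- pairs$targets[sp$train]
  }
  if (length(pairs$inputs) < 1 || length(valPairs$inputs) < 1)
    stop("empty training or validation split")
  nTrain <- length(pairs$inputs)
  p <- network@params
  m <- zeroTree(p)
  v <- zeroTree(p)
  lr <- config@learningRate
  tAdam <- 0
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric())
  bestVal <- Inf
  bestP <- p
  bestEpoch <- 1L
  net <- network
  for (epoch in seq_len(config@epochs)) {
    ord <- withSeed(deriveSeed(config@seed, epoch, .roleCode("shuffle")),
                    sample.int(nTrain))
    lossSum <- 0
    b <- 0L
    gAcc <- NULL
    for (k in ord) {
      net@params <- p
      fw <- netForward(net, pairs$inputs[[k]], train = TRUE)
      resid <- fw$y - pairs$targets[[k]]
      lossSum <- lossSum + mean(resid^2)
      gy <- 2 * resid / length(resid)
      g <- netBackward(net, fw$cache, gy)
      gAcc <- if (is.null(gAcc)) g else mapTree(`+`, gAcc, g)
      b <- b + 1L
      if (b == config@batchSize || k == ord[length(ord)]) {
        gAcc <- mapTree(function(x) x / b, gAcc)
        tAdam <- tAdam + 1
        m <- mapTree(function(m, g) 0.9 * m + 0.1 * g, m, gAcc)
        v <- mapTree(function(v, g) 0.999 * v + 0.001 * g * g, v, gAcc)
        bc1 <- 1 - 0.9^tAdam
        bc2 <- 1 - 0.999^tAdam
        p <- mapTree(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + 1e-8),
                     p, m, v)
        gAcc <- NULL
        b <- 0L
      }
    }
    net@params <- p
    valLoss <- mean(vapply(seq_along(valPairs$inputs), function(k) {
      .mse(netForward(net, valPairs$inputs[[k]])$y, valPairs$targets[[k]])
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         trainLoss = lossSum / nTrain,
                                         valLoss = valLoss))
    if (valLoss < bestVal) {
      bestVal <- valLoss
      bestP <- p
      bestEpoch <- epoch
    }
  }
  net@params <- bestP
  new("TrainedModel", network = net, config = config, history = history,
      selectedEpoch = as.integer(selectEpoch(history$valLoss)),
      trainingData = pairs$trainingData, domain = pairs$domain,
      scale = pairs$scale)
}

#' Denoise an ILI sinogram with a sinogram-domain model
#'
#' Denoising always consumes pre-log beam-intensity-loss images; absorption
#' sinograms are rejected (the negative log would have amplified and
#' reshaped the noise the model was trained on).
#'
#' @param model a sinogram-domain [TrainedModel-class].
#' @param iliNoisy a noisy [ILISinogram-class].
#' @return a denoised [ILISinogram-class] (provenance `"denoised"`).
#' @export
denoiseSinogram <- function(model, iliNoisy) {
  stopifnot(is(model, "TrainedModel"))
  if (!identical(model@domain, "sinogram"))
    stop("model was trained in the ", model@domain, " domain")
  if (is(iliNoisy, "AbsorptionSinogram"))
    stop("denoising consumes pre-log ILI data, not absorption sinograms")
  stopifnot(is(iliNoisy, "ILISinogram"))
  y <- applyNetwork(model@network, iliNoisy@values)
  new("ILISinogram", values = y, geometry = iliNoisy@geometry,
      provenance = "denoised")
}

#' Denoise directly into the reconstruction domain ("FBP+" models)
#'
#' Runs the fixed pipeline flat-field correction -> negative log -> FBP and
#' then applies a reconstruction-domain network, mapping a noisy
#' acquisition directly to a "clean" reconstruction.
#'
#' @param model a reconstruction-domain [TrainedModel-class].
#' @param x a noisy [PhotonSinogram-class] or [ILISinogram-class].
#' @param imageSize reconstruction size (must match training).
#' @param filter FBP filter.
#' @return a [ReconImage-class] with provenance `"fbp_of_denoised"`.
#' @export
denoiseReconstruction <- function(model, x, imageSize = 64L,
                                  filter = filterSpec()) {
  stopifnot(is(model, "TrainedModel"))
  if (!identical(model@domain, "reconstruction"))
    stop("model was trained in the ", model@domain, " domain")
  ili <- if (is(x, "PhotonSinogram")) flatfieldCorrect(x) else x
  if (is(ili, "AbsorptionSinogram"))
    stop("denoising consumes pre-log ILI data, not absorption sinograms")
  stopifnot(is(ili, "ILISinogram"))
  rec <- reconstructPipeline(ili, filter = filter, imageSize = imageSize)
  out <- applyNetwork(model@network, values(rec) * model@scale) / model@scale
  new("ReconImage", values = out, pixelSize = rec@pixelSize,
      provenance = "fbp_of_denoised")
}
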
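#' Published cross-evaluation benchmark table
#'
#' Loads the reference cross-evaluation results of the full-scale denoising
#' benchmark: two architectures (`unet`, `msdnet`), trained on experimental
#' or simulated noise, each tested on experimental and simulated noise, in
#' three evaluation domains -- `sinogram` (metrics on the denoised ILI),
#' `reconstruction_of_output` (metrics on the FBP of the denoised sinogram)
#' and `reconstruction_direct` (metrics on the output of
#' reconstruction-domain models). Shipped as plain text in `extdata`.
#'
#' @return a `data.frame` with columns `architecture`, `trainingData`,
#'   `testData`, `domain`, `metric`, `mean`, `sd`.
#' @examples
#' head(referenceCrossEvalTable())
#' @export
referenceCrossEvalTable <- function() {
  path <- system.file("extdata", "tdetect_crosseval_reference.csv",
                      package = "sinogap", mustWork = TRUE)
  read.csv(path)
}

## metric pair (ssim, psnr) of one slice's comparison for a given domain
.evalOne <- function(model, sl, cleanIli, noisyIli, cleanRec, mask, filter,
                     imageSize) {
  if (identical(model@domain, "sinogram")) {
    den <- denoiseSinogram(model, noisyIli)
    vC <- values(cleanIli)
    vD <- values(den)
    sino <- c(ssim = ssim(vC, vD), psnr = as.numeric(psnr(vC, vD)))
    recD <- reconstructPipeline(den, filter = filter, imageSize = imageSize)
    rec <- c(ssim = ssim(cleanRec, values(recD), mask = mask),
             psnr = as.numeric(psnr(cleanRec, values(recD), mask = mask)))
    list(sinogram = sino, reconstruction_of_output = rec)
  } else {
    recD <- denoiseReconstruction(model, noisyIli, imageSize = imageSize,
                                  filter = filter)
    rec <- c(ssim = ssim(cleanRec, values(recD), mask = mask),
             psnr = as.numeric(psnr(cleanRec, values(recD), mask = mask)))
    list(reconstruction_direct = rec)
  }
}

#' Cross-evaluate trained denoisers on experimental and simulated noise
#'
#' The core evaluation grid: every trained model is tested on both
#' experimental noisy test slices and on simulated noise applied to the
#' same slices' clean acquisitions. The reference in every comparison is
#' the clean counterpart: the clean ILI in the sinogram domain and the FBP
#' of the clean ILI in the reconstruction domains (restricted to the
#' reconstruction circle). Sinogram-domain models contribute rows in both
#' the `sinogram` and the `reconstruction_of_output` domain;
#' reconstruction-domain models contribute `reconstruction_direct` rows.
#'
#' @param dataset a [PairedDataset-class] providing the experimental test
#'   slices.
#' @param models list of [TrainedModel-class] objects.
#' @param testIndices slice indices of the held-out test set.
#' @param simDataset the dataset whose clean acquisitions generate the
#'   simulated test data (defaults to `dataset`; a study that trains its
#'   simulated arm on a monochromatic companion dataset passes that
#'   dataset here so simulated-test rows are drawn from the same
#'   distribution the models were trained on).
#' @param i0 photon count of the simulated test noise (normally the
#'   calibrated level the simulated training data used).
#' @param sigmaCrosstalk cross-talk fraction of the simulated test noise.
#' @param seed seed for the simulated test-noise draws.
#' @param imageSize reconstruction size.
#' @param filter FBP filter.
#' @return a [StudyReport-class]; its table has one row per
#'   (architecture, trainingData, testData, domain, metric) cell with the
#'   mean, standard deviation and count over test slices, and its gap table
#'   is [gapStatistics()] of that table.
#' @export
evaluateStudy <- function(dataset, models, testIndices, simDataset = dataset,
                          i0 = 200, sigmaCrosstalk = 0.05, seed = 1L,
                          imageSize = 64L,
                          filter = filterSpec("shepp-logan")) {
  stopifnot(is(dataset, "PairedDataset"), is(simDataset, "PairedDataset"),
            nSlices(simDataset) == nSlices(dataset),
            length(models) >= 1, length(testIndices) >= 1)
  mask <- reconMask(imageSize, margin = 1)
  rows <- list()
  perSlice <- list()  # key -> numeric vector of per-slice values
  add <- function(arch, td, test, domain, metric, value) {
    key <- paste(arch, td, test, domain, metric, sep = "|")
    perSlice[[key]] <<- c(perSlice[[key]], value)
  }
  for (i in testIndices) {
    sl <- getSlice(dataset, i)
    slSim <- getSlice(simDataset, i)
    cleanIli <- flatfieldCorrect(sl$clean)
    cleanRec <- values(reconstructPipeline(cleanIli, filter = filter,
                                           imageSize = imageSize))
    cleanIliSim <- flatfieldCorrect(slSim$clean)
    cleanRecSim <- values(reconstructPipeline(cleanIliSim, filter = filter,
                                              imageSize = imageSize))
    ## each test condition is scored against its own clean reference
    cases <- list(
      experimental = list(noisy = flatfieldCorrect(sl$noisy),
                          cleanIli = cleanIli, cleanRec = cleanRec),
      simulated = list(
        noisy = simulateNoisyIli(cleanIliSim, noiseParams(
          i0 = i0, sigmaCrosstalk = sigmaCrosstalk,
          seed = deriveSeed(seed, i, .roleCode("test_sim")))),
        cleanIli = cleanIliSim, cleanRec = cleanRecSim))
    for (model in models) {
      arch <- model@network@spec@family
      for (testData in names(cases)) {
        cs <- cases[[testData]]
        res <- .evalOne(model, sl, cs$cleanIli, cs$noisy, cs$cleanRec,
                        mask, filter, imageSize)
        for (domain in names(res))
          for (metric in names(res[[domain]]))
            add(arch, model@trainingData, testData, domain, metric,
                res[[domain]][[metric]])
      }
    }
  }
  keys <- strsplit(names(perSlice), "|", fixed = TRUE)
  table <- data.frame(
    architecture = vapply(keys, `[`, "", 1L),
    trainingData = vapply(keys, `[`, "", 2L),
    testData = vapply(keys, `[`, "", 3L),
    domain = vapply(keys, `[`, "", 4L),
    metric = vapply(keys, `[`, "", 5L),
    mean = vapply(perSlice, mean, numeric(1)),
    sd = vapply(perSlice, sd, numeric(1)),
    n = vapply(perSlice, length, integer(1)),
    row.names = NULL)
  new("StudyReport", table = table, gaps = gapStatistics(table),
      meta = list(i0 = i0, sigmaCrosstalk = sigmaCrosstalk, seed = seed,
                  testIndices = testIndices, imageSize = imageSize))
}

#' Gap statistics of a cross-evaluation table
#'
#' Derives the two headline quantities of the sim-to-real analysis from a
#' cross-evaluation table:
#'
#' * `sim_to_real_gap`: for models trained on simulated noise, the mean
#'   metric when tested on simulated noise minus the mean when tested on
#'   experimental noise, per architecture, domain and metric. Large
#'   positive values mean the model exploits structure of the simulated
#'   noise that the experimental noise does not have.
#' * `domain_improvement`: the `reconstruction_direct` mean minus the
#'   `reconstruction_of_output` mean for the same architecture, training
#'   data, test data and metric -- the benefit of training in the domain
#'   the metric is computed in.
#'
#' @param table a [StudyReport-class], or a `data.frame` in the layout of
#'   [referenceCrossEvalTable()].
#' @return a `data.frame` with columns `statistic`, `architecture`,
#'   `trainingData`, `testData`, `domain`, `metric`, `value`.
#' @examples
#' gaps <- gapStatistics(referenceCrossEvalTable())
#' subset(gaps, statistic == "sim_to_real_gap" & metric == "ssim")
#' @export
gapStatistics <- function(table) {
  if (is(table, "StudyReport")) table <- table@table
  stopifnot(is.data.frame(table))
  pick <- function(...) {
    cond <- list(...)
    sel <- rep(TRUE, nrow(table))
    for (nm in names(cond)) sel <- sel & table[[nm]] == cond[[nm]]
    r <- table[sel, , drop = FALSE]
    if (nrow(r) == 1L) r$mean else NA_real_
  }
  out <- list()
  simTrained <- unique(table[table$trainingData == "simulated_noisy",
                             c("architecture", "domain", "metric")])
  for (r in seq_len(nrow(simTrained))) {
    a <- simTrained$architecture[r]; d <- simTrained$domain[r]
    m <- simTrained$metric[r]
    vs <- pick(architecture = a, trainingData = "simulated_noisy",
               testData = "simulated", domain = d, metric = m)
    ve <- pick(architecture = a, trainingData = "simulated_noisy",
               testData = "experimental", domain = d, metric = m)
    if (is.finite(vs) && is.finite(ve))
      out[[length(out) + 1L]] <- data.frame(
        statistic = "sim_to_real_gap", architecture = a,
        trainingData = "simulated_noisy", testData = "simulated_vs_experimental",
        domain = d, metric = m, value = vs - ve)
  }
  direct <- unique(table[table$domain == "reconstruction_direct",
                         c("architecture", "trainingData", "testData",
                           "metric")])
  for (r in seq_len(nrow(direct))) {
    a <- direct$architecture[r]; td <- direct$trainingData[r]
    te <- direct$testData[r]; m <- direct$metric[r]
    vd <- pick(architecture = a, trainingData = td, testData = te,
               domain = "reconstruction_direct", metric = m)
    vo <- pick(architecture = a, trainingData = td, testData = te,
               domain = "reconstruction_of_output", metric = m)
    if (is.finite(vd) && is.finite(vo))
      out[[length(out) + 1L]] <- data.frame(
        statistic = "domain_improvement", architecture = a,
        trainingData = td, testData = te,
        domain = "reconstruction_direct_minus_of_output", metric = m,
        value = vd - vo)
  }
  if (length(out) == 0L)
    return(data.frame(statistic = character(), architecture = character(),
                      trainingData = character(), testData = character(),
                      domain = character(), metric = character(),
                      value = numeric()))
  do.call(rbind, out)
}
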
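## Shared fixtures for the sinogap test suite. Everything here is small
## enough that the non-acceptance suite stays in the seconds range.

tinyGeometry <- function() deskGeometry(nDetectorPixels = 48L, nProjections = 60L)

tinyDataset <- function(nSlices = 3, seed = 7, fluxNoisy = 200,
                        geometry = tinyGeometry(), imageSize = 32L,
                        surrogateMode = "experimental_surrogate") {
  pars <- pairedAcquisitionParams(geometry, fluxNoisy)
  makePairedDataset(nSlices, geometry = geometry,
                    surrogateMode = surrogateMode,
                    cleanParams = pars$clean, noisyParams = pars$noisy,
                    seed = seed, imageSize = imageSize)
}

## single centred disc, optionally without energy dependence
discPhantom <- function(n = 64, r = 0.3 * n, mu = 0.02, hardening = 1) {
  obj <- data.frame(class = "matrix", cx = (n + 1) / 2, cy = (n + 1) / 2,
                    r = r, mu = mu, hardening = hardening)
  generatePhantom(phantomContent(objects = obj), n, seed = 1)
}

## constant clean ILI sinogram on a given geometry
constantIli <- function(value, geometry = tinyGeometry(),
                        provenance = "experimental_clean") {
  new("ILISinogram",
      values = matrix(value, geometry@nProjections, geometry@nDetectorPixels),
      geometry = geometry, provenance = provenance)
}

## enumerate paths to numeric leaves of a nested parameter list
leafPaths <- function(tree, prefix = list()) {
  if (is.list(tree)) {
    out <- list()
    for (i in seq_along(tree))
      out <- c(out, leafPaths(tree[[i]], c(prefix, i)))
    out
  } else list(prefix)
}

getLeaf <- function(tree, path) {
  for (i in path) tree <- tree[[i]]
  tree
}

setLeafEntry <- function(tree, path, idx, value) {
  if (length(path) == 1L) {
    tree[[path[[1L]]]][idx] <- value
    return(tree)
  }
  tree[[path[[1L]]]] <- setLeafEntry(tree[[path[[1L]]]], path[-1L], idx, value)
  tree
}

## numeric-vs-analytic gradient check of the MSE loss for one network spec
checkNetworkGradients <- function(spec, n = 8L, nChecks = 12L, eps = 1e-5) {
  net <- buildNetwork(spec)
  set.seed(99)
  x <- matrix(rnorm(n * n, sd = 0.5), n, n)
  tgt <- matrix(rnorm(n * n, sd = 0.5), n, n)
  fw <- sinogap:::netForward(net, x, train = TRUE)
  gy <- 2 * (fw$y - tgt) / length(tgt)
  g <- sinogap:::netBackward(net, fw$cache, gy)
  lossAt <- function(p) {
    net@params <- p
    mean((sinogap:::netForward(net, x)$y - tgt)^2)
  }
  paths <- leafPaths(net@params)
  worst <- 0
  k <- 0L
  for (pth in paths) {
    leaf <- getLeaf(net@params, pth)
    gleaf <- getLeaf(g, pth)
    if (length(leaf) == 1L && identical(gleaf, 0)) next  # dilation marker
    idx <- ((k * 7L) %% length(leaf)) + 1L
    p1 <- setLeafEntry(net@params, pth, idx, leaf[idx] + eps)
    p2 <- setLeafEntry(net@params, pth, idx, leaf[idx] - eps)
    gNum <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
    gAna <- gleaf[idx]
    denom <- max(abs(gNum), abs(gAna), 1e-8)
    worst <- max(worst, abs(gNum - gAna) / denom)
    k <- k + 1L
    if (k >= nChecks) break
  }
  worst
}
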
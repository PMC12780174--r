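#' Describe the content of synthetic phantoms
#'
#' Content specification for [generatePhantom()]. The object classes mirror
#' mixed-content scanned slices: a large low-attenuation `matrix` disc,
#' small high-attenuation `stone_small` discs, and `stone_large_grouped`
#' clusters of at least two large stones with centres within three radii of
#' each other (the configuration that produces beam-hardening streaks under
#' polychromatic physics).
#'
#' Each object carries a nominal attenuation `mu` (per pixel length) and a
#' `hardening` ratio: the ratio of its low-energy to high-energy attenuation
#' coefficient. The two energy layers are chosen so that their mean equals
#' the nominal `mu`; a ratio of 1 means no energy dependence.
#'
#' @param includeMatrix place the background matrix disc (default `TRUE`).
#' @param nStonesSmall integer range `c(min, max)` of small stones.
#' @param pStoneGroup probability of adding one grouped-stone cluster.
#' @param matrixMu,stoneMu nominal attenuation per pixel length.
#' @param matrixHardening,stoneHardening low/high-energy attenuation ratios
#'   (defaults 1.2 and 2: stones harden the beam twice as strongly at the
#'   low energy).
#' @param matrixRadiusFrac matrix disc radius as a fraction of the grid.
#' @param objects optional data.frame (class, cx, cy, r, mu, hardening) of
#'   explicit objects in pixel coordinates, bypassing random placement.
#' @return a list of class `"phantomContent"`.
#' @export
phantomContent <- function(includeMatrix = TRUE, nStonesSmall = c(1, 3),
                           pStoneGroup = 0.5, matrixMu = 0.03, stoneMu = 0.12,
                           matrixHardening = 1.2, stoneHardening = 2,
                           matrixRadiusFrac = 0.42, objects = NULL) {
  structure(list(includeMatrix = includeMatrix, nStonesSmall = nStonesSmall,
                 pStoneGroup = pStoneGroup, matrixMu = matrixMu,
                 stoneMu = stoneMu, matrixHardening = matrixHardening,
                 stoneHardening = stoneHardening,
                 matrixRadiusFrac = matrixRadiusFrac, objects = objects),
            class = "phantomContent")
}

## split nominal mu into low/high-energy values with ratio `hard`
.muSplit <- function(mu, hard) {
  c(low = 2 * hard / (1 + hard) * mu, high = 2 / (1 + hard) * mu)
}

#' Generate a synthetic phantom
#'
#' Deterministically (per seed) places the objects described by a
#' [phantomContent()] spec on a square grid and rasterizes them into two
#' energy layers (low, high). Objects are drawn in order matrix, then
#' stones, each overwriting the attenuation beneath it.
#'
#' @param content a [phantomContent()] spec.
#' @param imageSize grid edge length in pixels (at least 32).
#' @param seed RNG seed; the phantom is a pure function of (content, seed).
#' @param pixelSize pixel edge length in mm (bookkeeping).
#' @return a [Phantom-class].
#' @examples
#' ph <- generatePhantom(phantomContent(), imageSize = 64, seed = 1)
#' ph
#' @export
generatePhantom <- function(content = phantomContent(), imageSize, seed,
                            pixelSize = 1) {
  stopifnot(inherits(content, "phantomContent"))
  if (imageSize < 32) stop("imageSize must be at least 32")
  n <- as.integer(imageSize)
  objects <- withSeed(seed, .placeObjects(content, n))
  lowE <- matrix(0, n, n)
  highE <- matrix(0, n, n)
  if (nrow(objects) > 0) {
    xg <- matrix(seq_len(n), n, n)
    yg <- t(xg)
    for (k in seq_len(nrow(objects))) {
      o <- objects[k, ]
      if (o$cx - o$r < 0.5 || o$cx + o$r > n + 0.5 ||
          o$cy - o$r < 0.5 || o$cy + o$r > n + 0.5)
        stop("object '", o$class, "' does not fit the grid")
      mask <- (xg - o$cx)^2 + (yg - o$cy)^2 <= o$r^2
      mu2 <- .muSplit(o$mu, o$hardening)
      lowE[mask] <- mu2[["low"]]
      highE[mask] <- mu2[["high"]]
    }
  }
  mu <- array(c(lowE, highE), dim = c(n, n, 2))
  new("Phantom", mu = mu, pixelSize = pixelSize, energies = c(40, 80),
      objects = objects)
}

.emptyObjects <- function() {
  data.frame(class = character(), cx = numeric(), cy = numeric(),
             r = numeric(), mu = numeric(), hardening = numeric())
}

.placeObjects <- function(content, n) {
  if (!is.null(content$objects)) {
    obj <- content$objects
    need <- c("class", "cx", "cy", "r", "mu", "hardening")
    if (!all(need %in% names(obj)))
      stop("explicit objects need columns ", paste(need, collapse = ", "))
    return(obj)
  }
  obj <- .emptyObjects()
  c0 <- (n + 1) / 2
  rMat <- content$matrixRadiusFrac * n
  if (content$includeMatrix) {
    obj <- rbind(obj, data.frame(
      class = "matrix", cx = c0 + runif(1, -0.02, 0.02) * n,
      cy = c0 + runif(1, -0.02, 0.02) * n, r = rMat * runif(1, 0.95, 1),
      mu = content$matrixMu * runif(1, 0.9, 1.1),
      hardening = content$matrixHardening))
  }
  inMatrix <- function(r) {
    ## random centre such that a disc of radius r stays inside the matrix
    rho <- sqrt(runif(1)) * (rMat * 0.92 - r)
    ang <- runif(1, 0, 2 * pi)
    c(c0 + rho * cos(ang), c0 + rho * sin(ang))
  }
  nSmall <- if (length(content$nStonesSmall) > 1)
    sample(content$nStonesSmall[1]:content$nStonesSmall[2], 1)
  else content$nStonesSmall
  for (k in seq_len(nSmall)) {
    r <- runif(1, 0.03, 0.06) * n
    ctr <- inMatrix(r)
    obj <- rbind(obj, data.frame(class = "stone_small", cx = ctr[1], cy = ctr[2],
                                 r = r, mu = content$stoneMu * runif(1, 0.9, 1.1),
                                 hardening = content$stoneHardening))
  }
  if (runif(1) < content$pStoneGroup) {
    r <- runif(1, 0.07, 0.10) * n
    nGrp <- sample(2:3, 1)
    ctr <- inMatrix(r + 2.6 * r)  # leave room for the companions
    for (k in seq_len(nGrp)) {
      ang <- runif(1, 0, 2 * pi)
      d <- if (k == 1) 0 else runif(1, 1.6, 2.4) * r
      obj <- rbind(obj, data.frame(
        class = "stone_large_grouped", cx = ctr[1] + d * cos(ang),
        cy = ctr[2] + d * sin(ang), r = r * runif(1, 0.85, 1),
        mu = content$stoneMu * runif(1, 0.9, 1.1),
        hardening = content$stoneHardening))
    }
  }
  obj
}

#' Attenuation map of a phantom
#'
#' Returns the 2D attenuation map for a given energy bin, or the
#' equal-weight mean over bins (the effective monochromatic map, which the
#' polychromatic projection reduces to in the thin-object limit) when
#' `bin = NULL`.
#'
#' @param phantom a [Phantom-class].
#' @param bin energy bin index, or `NULL` for the mean map.
#' @return a numeric matrix.
#' @export
attenuation <- function(phantom, bin = NULL) {
  stopifnot(is(phantom, "Phantom"))
  if (is.null(bin)) {
    nE <- dim(phantom@mu)[3]
    Reduce(`+`, lapply(seq_len(nE), function(k) phantom@mu[, , k])) / nE
  } else phantom@mu[, , bin]
}
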
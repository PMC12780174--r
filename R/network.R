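#' Construct a denoiser architecture specification
#'
#' @param family `"unet"` or `"msdnet"`.
#' @param depth U-Net resolution levels (encoder/decoder stages).
#' @param baseChannels U-Net feature maps at the top level (doubled per
#'   level going down).
#' @param nLayers MSD-Net width-one dense layers.
#' @param dilationCycle MSD-Net dilation cycle length: layer `j` uses
#'   dilation `((j - 1) mod dilationCycle) + 1`.
#' @param seed weight-initialization seed.
#' @return a [NetworkSpec-class].
#' @export
networkSpec <- function(family = c("unet", "msdnet"), depth = 2L,
                        baseChannels = 4L, nLayers = 8L, dilationCycle = 4L,
                        seed = 1L) {
  family <- match.arg(family)
  new("NetworkSpec", family = family, depth = as.integer(depth),
      baseChannels = as.integer(baseChannels), nLayers = as.integer(nLayers),
      dilationCycle = as.integer(dilationCycle), seed = as.integer(seed))
}

#' Dilation schedule of an MSD network
#'
#' @param nLayers,dilationCycle layer count and cycle length.
#' @return integer vector of per-layer dilations.
#' @examples
#' msdDilations(20, 10)  # 1..10, 1..10
#' @export
msdDilations <- function(nLayers, dilationCycle) {
  as.integer(((seq_len(nLayers) - 1L) %% dilationCycle) + 1L)
}

## He-style initialization for one conv layer
.initConv <- function(cout, cin, k, gain = 1) {
  w <- array(rnorm(cout * cin * k * k, 0, gain * sqrt(2 / (cin * k * k))),
             dim = c(cout, cin, k, k))
  list(w = w, b = numeric(cout))
}

#' Build an untrained denoiser network
#'
#' Instantiates the weights of a [networkSpec()] deterministically from its
#' seed. Both families map a one-channel image to a one-channel image of
#' the same size and add the input back (residual denoising); the U-Net
#' uses 3x3 convolutions with 2x2 average pooling / nearest upsampling and
#' skip connections, the MSD-Net uses densely connected width-one layers of
#' dilated 3x3 convolutions (no scaling operations) and therefore has far
#' fewer feature maps and trainable parameters.
#'
#' @param spec a [NetworkSpec-class].
#' @return a [DenoisingNetwork-class].
#' @export
buildNetwork <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  params <- withSeed(spec@seed, {
    if (identical(spec@family, "unet")) {
      L <- spec@depth
      ch <- spec@baseChannels * 2^(seq_len(L) - 1L)
      enc <- lapply(seq_len(L), function(i) {
        cin <- if (i == 1L) 1L else ch[i - 1L]
        list(conv1 = .initConv(ch[i], cin, 3L), conv2 = .initConv(ch[i], ch[i], 3L))
      })
      dec <- if (L > 1L) lapply(seq_len(L - 1L), function(i) {
        list(conv1 = .initConv(ch[i], ch[i + 1L] + ch[i], 3L),
             conv2 = .initConv(ch[i], ch[i], 3L))
      }) else list()
      list(enc = enc, dec = dec, head = .initConv(1L, ch[1L], 1L, gain = 0.1))
    } else {
      dil <- msdDilations(spec@nLayers, spec@dilationCycle)
      layers <- lapply(seq_len(spec@nLayers), function(j) {
        c(.initConv(1L, j, 3L), list(dilation = dil[j]))
      })
      list(layers = layers, head = .initConv(1L, spec@nLayers + 1L, 1L, gain = 0.1))
    }
  })
  new("DenoisingNetwork", spec = spec, params = params)
}

.asTensor <- function(m) array(m, c(1L, dim(m)))
.asMatrix <- function(t) matrix(t, dim(t)[2], dim(t)[3])

.relu <- function(x) x * (x > 0)

.concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

## ---- U-Net forward/backward (recursive over levels) ----

.unetForward <- function(params, x, level = 1L) {
  L <- length(params$enc)
  e <- params$enc[[level]]
  h1 <- .relu(cpp_conv2d_forward(x, e$conv1$w, e$conv1$b, 1L))
  a <- .relu(cpp_conv2d_forward(h1, e$conv2$w, e$conv2$b, 1L))
  if (level == L)
    return(list(out = a, cache = list(x = x, h1 = h1, a = a)))
  p <- cpp_avgpool2_forward(a)
  lower <- .unetForward(params, p, level + 1L)
  u <- cpp_upsample2_forward(lower$out)
  cc <- .concatC(u, a)
  d <- params$dec[[level]]
  g1 <- .relu(cpp_conv2d_forward(cc, d$conv1$w, d$conv1$b, 1L))
  o <- .relu(cpp_conv2d_forward(g1, d$conv2$w, d$conv2$b, 1L))
  list(out = o, cache = list(x = x, h1 = h1, a = a, lower = lower$cache,
                             cc = cc, g1 = g1, o = o))
}

.unetBackward <- function(params, cache, gout, level = 1L) {
  L <- length(params$enc)
  e <- params$enc[[level]]
  grads <- list()
  if (level < L) {
    d <- params$dec[[level]]
    g <- gout * (cache$o > 0)
    b2 <- cpp_conv2d_backward(cache$g1, d$conv2$w, g, 1L)
    g <- b2$gx * (cache$g1 > 0)
    b1 <- cpp_conv2d_backward(cache$cc, d$conv1$w, g, 1L)
    grads$dec <- list(conv1 = list(w = b1$gw, b = b1$gb),
                      conv2 = list(w = b2$gw, b = b2$gb))
    nu <- dim(cache$cc)[1] - dim(cache$a)[1]
    gu <- b1$gx[seq_len(nu), , , drop = FALSE]
    dim(gu) <- c(nu, dim(cache$cc)[2], dim(cache$cc)[3])
    ga <- b1$gx[nu + seq_len(dim(cache$a)[1]), , , drop = FALSE]
    dim(ga) <- dim(cache$a)
    glow <- cpp_upsample2_backward(gu)
    lower <- .unetBackward(params, cache$lower, glow, level + 1L)
    grads$lower <- lower$grads
    gp <- cpp_avgpool2_backward(lower$gx, dim(cache$a)[2], dim(cache$a)[3])
    ga <- ga + gp
  } else {
    ga <- gout
  }
  g <- ga * (cache$a > 0)
  b2 <- cpp_conv2d_backward(cache$h1, e$conv2$w, g, 1L)
  g <- b2$gx * (cache$h1 > 0)
  b1 <- cpp_conv2d_backward(cache$x, e$conv1$w, g, 1L)
  grads$enc <- list(conv1 = list(w = b1$gw, b = b1$gb),
                    conv2 = list(w = b2$gw, b = b2$gb))
  list(grads = grads, gx = b1$gx)
}

## reshape recursive U-Net grads into the params tree layout
.unetCollect <- function(g, L) {
  enc <- vector("list", L)
  dec <- if (L > 1L) vector("list", L - 1L) else list()
  node <- g
  for (level in seq_len(L)) {
    enc[[level]] <- node$enc
    if (level < L) {
      dec[[level]] <- node$dec
      node <- node$lower
    }
  }
  list(enc = enc, dec = dec)
}

## ---- MSD-Net forward/backward ----

.msdForward <- function(params, x) {
  n <- length(params$layers)
  d <- dim(x)
  feats <- array(0, c(n + 1L, d[2], d[3]))
  feats[1L, , ] <- x
  for (j in seq_len(n)) {
    ly <- params$layers[[j]]
    inp <- feats[seq_len(j), , , drop = FALSE]
    dim(inp) <- c(j, d[2], d[3])
    z <- .relu(cpp_conv2d_forward(inp, ly$w, ly$b, ly$dilation))
    feats[j + 1L, , ] <- z
  }
  list(feats = feats)
}

.msdBackward <- function(params, cache, ghead) {
  ## ghead: gradient w.r.t. the full feature stack coming from the head
  n <- length(params$layers)
  feats <- cache$feats
  d <- dim(feats)
  gf <- ghead
  layerGrads <- vector("list", n)
  for (j in rev(seq_len(n))) {
    ly <- params$layers[[j]]
    z <- feats[j + 1L, , , drop = FALSE]
    dim(z) <- c(1L, d[2], d[3])
    g <- gf[j + 1L, , , drop = FALSE]
    dim(g) <- c(1L, d[2], d[3])
    g <- g * (z > 0)
    inp <- feats[seq_len(j), , , drop = FALSE]
    dim(inp) <- c(j, d[2], d[3])
    b <- cpp_conv2d_backward(inp, ly$w, g, ly$dilation)
    layerGrads[[j]] <- list(w = b$gw, b = b$gb, dilation = 0)
    gf[seq_len(j), , ] <- gf[seq_len(j), , , drop = FALSE] + b$gx
  }
  gx <- gf[1L, , , drop = FALSE]
  dim(gx) <- c(1L, d[2], d[3])
  list(layers = layerGrads, gx = gx)
}

## ---- shared entry points ----

## Forward pass. Returns list(y = output matrix, cache) when train = TRUE.
netForward <- function(network, input, train = FALSE) {
  p <- network@params
  x <- .asTensor(input)
  if (identical(network@spec@family, "unet")) {
    fw <- .unetForward(p, x)
    yhead <- cpp_conv2d_forward(fw$out, p$head$w, p$head$b, 1L)
    y <- .asMatrix(yhead) + input
    if (!train) return(list(y = y))
    list(y = y, cache = list(fw = fw, x = x))
  } else {
    fw <- .msdForward(p, x)
    yhead <- cpp_conv2d_forward(fw$feats, p$head$w, p$head$b, 1L)
    y <- .asMatrix(yhead) + input
    if (!train) return(list(y = y))
    list(y = y, cache = list(fw = fw, x = x))
  }
}

## Backward pass for MSE-style gradient gy (matrix d loss / d output).
## Returns gradients in the same tree layout as network@params.
netBackward <- function(network, cache, gy) {
  p <- network@params
  g <- .asTensor(gy)
  if (identical(network@spec@family, "unet")) {
    bh <- cpp_conv2d_backward(cache$fw$out, p$head$w, g, 1L)
    rec <- .unetBackward(p, cache$fw$cache, bh$gx)
    out <- .unetCollect(rec$grads, length(p$enc))
    out$head <- list(w = bh$gw, b = bh$gb)
    out
  } else {
    bh <- cpp_conv2d_backward(cache$fw$feats, p$head$w, g, 1L)
    rec <- .msdBackward(p, cache$fw, bh$gx)
    list(layers = rec$layers, head = list(w = bh$gw, b = bh$gb))
  }
}

#' Apply a denoiser network to a single image or sinogram matrix
#'
#' @param network a [DenoisingNetwork-class].
#' @param input numeric matrix (for U-Nets, both sides must be divisible by
#'   `2^(depth - 1)`).
#' @return the denoised matrix (same shape).
#' @export
applyNetwork <- function(network, input) {
  stopifnot(is(network, "DenoisingNetwork"), is.matrix(input))
  if (identical(network@spec@family, "unet")) {
    f <- 2^(network@spec@depth - 1L)
    if (any(dim(input) %% f != 0))
      stop("input sides must be divisible by ", f, " for this U-Net")
  }
  netForward(network, input)$y
}

## ---- parameter-tree utilities ----

mapTree <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1))
      out[[i]] <- do.call(mapTree, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

zeroTree <- function(p) mapTree(function(x) x * 0, p)
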
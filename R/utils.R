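## Internal helpers: seeded RNG streams and small numeric utilities.

#' Derive a reproducible child seed from a master seed
#'
#' Hashes a master seed together with any number of integer indices (slice
#' number, role code, replicate, ...) into a new seed in `[1, 2^31 - 2]`.
#' Used to give every stochastic stage of a dataset its own independent,
#' deterministic RNG stream, so that e.g. the clean and noisy acquisition of
#' the same slice use independent draws (physical re-acquisition) while the
#' whole dataset remains a pure function of the master seed.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the stream.
#' @return a single integer seed.
#' @export
deriveSeed <- function(master, ...) {
  h <- as.integer(master)
  for (k in as.integer(c(101L, ...))) {
    h <- bitwXor(h, k)
    ## xorshift32 mixing
    h <- bitwXor(h, bitwShiftL(h, 13L))
    h <- bitwXor(h, bitwShiftR(h, 17L))
    h <- bitwXor(h, bitwShiftL(h, 5L))
  }
  v <- bitwAnd(h, 2147483647L)
  max(v, 1L)
}

## Evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
## state is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## role codes for deriveSeed streams
.roleCode <- function(role) {
  codes <- c(phantom = 1L, clean = 2L, noisy = 3L, flat = 4L, sim = 5L,
             split = 6L, weights = 7L, shuffle = 8L, test_sim = 9L)
  if (!role %in% names(codes)) stop("unknown RNG role: ", role)
  codes[[role]]
}
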
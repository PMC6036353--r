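# Reproducible, independent uniform streams derived from one master seed.
#
# The collimator consumes randomness from two logically separate streams
# (azimuthal rotation angles and fractional-MU draws) so that turning one
# consumer on or off cannot perturb the other's sequence. R has a single
# global generator, so each stream keeps its own .Random.seed snapshot and
# swaps it in around every draw.

#' Derive a child seed from a base seed and an index
#'
#' Stable integer mixing (multiplicative hash modulo the Mersenne prime
#' 2^31 - 1) used wherever the package needs several independent seeds from
#' one master seed: parallel IMRT splits, per-stage RNG streams. Distinct
#' indices always yield distinct seeds for a fixed base.
#'
#' @param base_seed integer master seed.
#' @param index non-negative integer stream/split index.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(base_seed, index) {
  p <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.double(base_seed)) %% p) + 40503 * (as.double(index) + 1)
  # 2654435761 is the Knuth multiplicative constant; exact in doubles here
  x <- (x %% p) * 69621 %% p
  x <- (x * 40014 + 12345) %% p
  as.integer(x %% (p - 2) + 1)
}

rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(env) <- "fajt_rng_stream"
  env
}

with_stream <- function(stream, fn) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

stream_runif <- function(stream, n, min = 0, max = 1) {
  with_stream(stream, function() runif(n, min, max))
}

stream_rnorm <- function(stream, n, mean = 0, sd = 1) {
  with_stream(stream, function() rnorm(n, mean, sd))
}

stream_sample_int <- function(stream, n, size, replace = FALSE, prob = NULL) {
  with_stream(stream, function() sample.int(n, size, replace = replace, prob = prob))
}
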
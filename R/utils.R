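# Internal numeric helpers shared across modules.

#' Derive a child RNG seed from a master seed and a stream key
#'
#' Every stochastic routine in the package draws from a named stream whose
#' seed is computed from the master seed and integer key components with a
#' fixed linear-congruential fold. Inserting new samples into a generator
#' spec therefore never perturbs the draws of existing (subject, sample)
#' streams.
#'
#' @param seed Master seed (integer).
#' @param ... Integer key components identifying the stream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(...)
  stopifnot(length(keys) >= 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (k in keys) {
    # LCG fold; constants from Numerical Recipes, arithmetic kept in double
    # range (all operands < 2^31 so products < 2^62 are exact doubles).
    h <- (h * 69069 + as.numeric(k) %% m + 1234567) %% m
    h <- (h * 1103515245 + 12345) %% m
  }
  as.integer(h)
}

# Numerically stable row-wise softmax of a matrix.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# argmax with lowest index winning exact ties (prediction tie-break rule)
argmax_first <- function(x) which.max(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
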
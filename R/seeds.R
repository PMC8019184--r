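#' Derive a child seed from a master seed and an index path
#'
#' Counter-based splitting: the master seed and each index are folded into a
#' 31-bit state with a multiplicative-congruential step. Deterministic,
#' independent of R's RNG state, and always in \[1, 2^31 - 2\], so derived
#' seeds are safe 32-bit integers. Used by every experiment runner to give
#' each (scenario, level, replicate) its own reproducible stream; the
#' derived seed is stored in the replicate record.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the child stream (e.g. level,
#'   design index, replicate number).
#' @return A single integer seed.
#' @export
split_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (idx in c(...)) {
    # 69069 * m < 2^53: exact in double arithmetic
    s <- (s * 69069 + as.numeric(idx) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}
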
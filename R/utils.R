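#' Derive a child RNG seed from a top-level seed and an index
#'
#' All randomness in multi-record experiments flows from one top-level seed
#' through per-record derived seeds, so that growing an ensemble does not
#' perturb earlier records.  A fixed LCG-style mix keeps the result a valid
#' 32-bit integer seed.
#'
#' @param seed top-level integer seed.
#' @param k child index (`>= 0`).
#' @return integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
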
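# Deterministic substream seeding. Every stochastic stage draws from its own
# substream keyed by (global seed, stage, sample, step, unit id), so results
# are reproducible and independent of the order in which meshes, steps or
# samples are executed.

.STAGE <- list(
  synth_pop = 11L, synth_hosp = 12L, synth_net = 13L,
  project = 21L, incidence = 22L, allocate = 23L
)

# Character keys (mesh ids) hash via their code points, so substreams are
# stable under subsetting or reordering of the mesh table.
key_ints <- function(k) {
  if (is.character(k)) utf8ToInt(k) else as.numeric(k)
}

#' Derive a substream seed from a base seed and a sequence of keys
#'
#' Mixes integer or character keys into a base seed with a Lehmer-style
#' multiplicative congruential step (modulus 2^31 - 1), giving a
#' deterministic, well-dispersed seed below 2^31 for `set.seed()`.
#' Used internally so each (stage, sample, step, mesh) combination has its
#' own reproducible random substream.
#'
#' @param seed base integer seed.
#' @param ... integer or character keys identifying the substream.
#' @return a single integer seed.
#' @examples
#' derive_seed(1, 21, 3, "m001_002")
#' @export
derive_seed <- function(seed, ...) {
  keys <- list(...)
  x <- abs(as.numeric(seed)) %% 2147483647
  for (k in keys) {
    for (kk in key_ints(k)) {
      x <- (x * 48271 + kk + 1) %% 2147483647
    }
  }
  as.integer(x)
}
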
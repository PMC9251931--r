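# Deterministic seed derivation.
#
# Every stochastic step in the simulator draws from a stream seeded by a hash
# of (root seed, stream labels). Detection uniforms are keyed by transcript
# only (not by sample), which couples samples generated from the same root
# seed through common random numbers: a transcript's junction/exon support is
# qpois(u, lambda), monotone in its read count, so merging read pools or
# subsampling reads can only move detection in the direction the counts move.
# Read allocation and noise are keyed by sample as well, so replicates differ.
#
# The hash is a Lehmer-style linear congruential fold modulo 2^31 - 1 (a
# prime), kept in exact double arithmetic (products stay below 2^53).

hash_chunks <- function(x) {
  if (is.character(x)) {
    x <- vapply(x, function(s) {
      v <- utf8ToInt(s)
      h <- 7
      for (ch in v) h <- (h * 131 + ch) %% 2147483647
      h
    }, numeric(1), USE.NAMES = FALSE)
  }
  as.numeric(x)
}

#' Derive a child seed from a root seed and stream labels
#'
#' @param seed integer root seed.
#' @param ... integers or strings identifying the stream (e.g. a sample id and
#'   a transcript index).
#' @return an integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @keywords internal
derive_seed <- function(seed, ...) {
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (part in list(...)) {
    for (v in hash_chunks(part)) {
      h <- (h * 48271) %% 2147483647
      h <- (h + (v %% 2147483647) + 1) %% 2147483647
    }
  }
  h <- (h * 48271) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
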
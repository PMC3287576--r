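# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. All package randomness flows through this so a
# single master seed gives bit-identical reruns.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Deterministic child seeds below 2^31, spread by a fixed multiplier.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647)
}
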
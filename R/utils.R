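# Seeded evaluation that leaves the caller's RNG stream untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seeds: one master seed, distinct small offsets per
# stochastic stage, kept within the 32-bit integer range.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}
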
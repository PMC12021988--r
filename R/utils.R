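# internal helpers

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed, kept within 32-bit
# integer range so they are valid set.seed() arguments.
deriveSeeds <- function(seed, n) {
  as.integer((as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
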
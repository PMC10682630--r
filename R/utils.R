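# internal helpers

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# small integer seed derived from a base seed and an offset, kept inside the
# 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1009 * as.double(offset)) %% .Machine$integer.max)
}
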
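# Deterministic seeded substreams. Each (seed, label) pair maps to a fixed
# 32-bit seed so independent components draw from independent, reproducible
# streams regardless of call order, and without touching the caller's
# global RNG state.

rng_substream <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(as.numeric(codes) * seq_along(codes) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

with_rng <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
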
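## Seed plumbing: every stochastic routine takes an explicit seed, runs
## under a saved/restored RNG state, and derives per-run seeds from the
## master seed, so no hidden global state leaks between calls.

withSeed <- function(seed, fn) {
  seed <- as.integer(as.double(seed) %% 2147483647)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## Deterministic 32-bit-safe stream split: master seed + stream index ->
## derived seed. Doubles are exact here (values < 2^53).
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919 + 1) %%
               2147483629)
}
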
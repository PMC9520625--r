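## Small internal helpers shared across modules.

## Deterministic derivation of per-stage seeds from one master seed, kept
## inside the 32-bit signed range R requires for set.seed().
deriveSeed <- function(master, stream) {
  v <- (as.numeric(master) %% 2147483647) * 69069 +
    1013 * as.numeric(stream)                  # < 2^53, exact in double
  as.integer(v %% 2147483647)
}

## Run expr under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so library code never disturbs user RNG streams.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
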
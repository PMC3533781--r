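# evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round half away from zero to `digits` decimals (round() rounds half to
# even, which does not reproduce printed tables)
round_half_away <- function(x, digits = 2L) {
  f <- 10^digits
  # 1e-9 guard keeps values that are exactly .5 in decimal (but stored just
  # below it in binary, e.g. 2.675) on the away-from-zero side
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}
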
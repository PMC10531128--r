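# round half away from zero (commercial rounding): report-time VND rounding
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(abs(x) * m + 0.5) / m * sign(x)
}

# run a block with a private RNG stream, leaving .Random.seed untouched
with_private_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}
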
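## run expr with a local RNG state; the caller's .Random.seed is untouched
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

## 3-point parabolic interpolation of a discrete maximum; returns the x offset
## in grid units relative to x[i]
parabolicOffset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (denom == 0) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, off))
}
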
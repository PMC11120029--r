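## small shared generators used across test files

quickInstrument <- function(nPoints = 150, noiseSd = 0.01) {
  instrumentModel(nPoints = nPoints, noiseSd = noiseSd)
}

quickTraceSet <- function(scheme, seed = 1, noiseSd = 0.01, nPoints = 150,
                          design = fig4Design(), response = clampResponseModel()) {
  simulateTraceSet(scheme, response, quickInstrument(nPoints, noiseSd),
                   design, seed = seed)
}

## numeric equilibrium solver for the binding quadratic (independent oracle)
numericFractionDuplex <- function(A, B, Kd) {
  if (A == 0 || B == 0) return(0)
  f <- function(D) (A - D) * (B - D) - Kd * D
  stats::uniroot(f, lower = 0, upper = min(A, B), tol = 1e-16)$root / A
}
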
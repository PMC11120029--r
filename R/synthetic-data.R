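#' Construct a stopped-flow instrument model
#'
#' Defaults mirror a typical stopped-flow fluorimeter setup for millisecond
#' binding kinetics: a 1.4 ms mixing dead time and 400 log-spaced sampling
#' points from the dead time up to 1 s.
#'
#' @param deadTime instrument dead time in seconds (default 0.0014).
#' @param tMax last sampling time in seconds (default 1).
#' @param nPoints number of log-spaced samples (default 400).
#' @param times explicit sampling times overriding `tMax`/`nPoints`.
#' @param noiseSd Gaussian noise sd as a fraction of the full-scale signal
#'   (default 0.01, i.e. 1%). The full scale of a trace set is its recorded
#'   dynamic range (max - min of the noiseless signal over the whole set),
#'   matching how a stopped-flow acquisition range is adjusted to the
#'   observed change.
#' @return an [InstrumentModel-class].
#' @export
instrumentModel <- function(deadTime = 0.0014, tMax = 1, nPoints = 400,
                            times = NULL, noiseSd = 0.01) {
  if (is.null(times)) {
    if (deadTime <= 0) stop("log-spaced sampling requires deadTime > 0; supply 'times'")
    times <- logspace(deadTime, tMax, nPoints)
  }
  new("InstrumentModel", deadTime = deadTime, times = times, noiseSd = noiseSd)
}

#' Construct a fluorescence response model
#'
#' @param background offset in a.u.
#' @param coefficients named numeric: response of each species in a.u. per
#'   molar. Species absent from the map contribute no signal.
#' @return a [ResponseModel-class].
#' @export
responseModel <- function(background = 0, coefficients = numeric(0)) {
  new("ResponseModel", background = background, coefficients = coefficients)
}

#' Default clamp-fluorescence response
#'
#' Free clamp-containing duplex is bright; enzyme-bound states are slightly
#' dimmer (the clamp micro-environment changes on binding), so association
#' appears as a modest signal decrease. The enzyme itself is dark at the
#' clamp excitation/emission wavelengths.
#'
#' @return a [ResponseModel-class] with coefficients for S, ES and ES*.
#' @export
clampResponseModel <- function() {
  responseModel(
    background = 0.05,
    coefficients = c(S = 1.0e6, ES = 0.90e6, "ES*" = 0.75e6)
  )
}

## signal = background + sum_s coeff_s * [s](t) for a trajectory data.frame
predictSignal <- function(response, trajectory) {
  sig <- rep(response@background, nrow(trajectory))
  co <- response@coefficients
  use <- intersect(names(co), names(trajectory))
  for (s in use) sig <- sig + co[[s]] * trajectory[[s]]
  sig
}

#' Simulate a stopped-flow concentration series
#'
#' Each design point is integrated from mixing (t = 0) under `scheme`, the
#' observable is evaluated through the linear response model at the
#' instrument's sampling times (all at or after the dead time), and seeded
#' Gaussian noise with sd `noiseSd * fullScale` is added, where the full
#' scale is the maximum noiseless signal over the whole set.
#'
#' @param scheme a valid [KineticScheme-class]; the trace-set convention maps
#'   total enzyme to species "E" and total duplex to species "S".
#' @param response a [ResponseModel-class].
#' @param instrument an [InstrumentModel-class].
#' @param design data.frame with columns `enzyme` and `duplex` (molar), one
#'   row per trace; see [fig4Design()] for the default concentration series.
#' @param seed integer seed; identical seeds give identical output.
#' @param condition label stored with the set.
#' @return a [TraceSet-class] whose `groundTruth` records the generator
#'   scheme, response, instrument, and seed.
#' @export
simulateTraceSet <- function(scheme, response, instrument, design,
                             seed = NULL, condition = "synthetic") {
  validObject(scheme); validObject(response); validObject(instrument)
  design <- as.data.frame(design)
  if (!nrow(design)) stop("design must contain at least one (enzyme, duplex) row")
  if (!all(c("enzyme", "duplex") %in% names(design))) {
    stop("design must have columns 'enzyme' and 'duplex'")
  }
  if (any(design$enzyme <= 0) || any(design$duplex <= 0)) {
    stop("design concentrations must be > 0")
  }
  tt <- instrument@times
  clean <- lapply(seq_len(nrow(design)), function(i) {
    traj <- integrateScheme(
      scheme, c(E = design$enzyme[i], S = design$duplex[i]), tt
    )
    predictSignal(response, traj)
  })
  ## full scale = the acquisition range, which a stopped-flow operator sets
  ## to span the kinetic signal change of a shot; taken as the largest
  ## within-trace change of the set, falling back to the absolute level for
  ## kinetics-free (flat) signals
  span <- max(vapply(clean, function(sig) diff(range(sig)), numeric(1)))
  fullScale <- if (span > 0) span else max(abs(unlist(clean)), 1)
  sd <- instrument@noiseSd * fullScale
  traces <- withSeed(seed, lapply(clean, function(sig) {
    data.frame(time = tt,
               signal = sig + if (sd > 0) stats::rnorm(length(sig), 0, sd) else 0)
  }))
  new("TraceSet",
      traces = traces, design = design[, c("enzyme", "duplex")],
      condition = condition,
      groundTruth = list(
        rateConstants = scheme@rateConstants, scheme = scheme,
        response = response, instrument = instrument, seed = seed,
        fullScale = fullScale
      ))
}

#' Default stopped-flow concentration design
#'
#' Fixed 1 uM enzyme mixed with a duplex series of 0.4, 0.8, 1.2 and
#' 1.6 uM. The complementary design (duplex fixed at 1 uM, enzyme varied)
#' is available via `fixedDuplexDesign()`.
#'
#' @return data.frame with columns `enzyme`, `duplex` (molar).
#' @export
fig4Design <- function() {
  data.frame(enzyme = 1e-6, duplex = c(0.4, 0.8, 1.2, 1.6) * 1e-6)
}

#' @rdname fig4Design
#' @param enzyme enzyme concentrations (molar) for the varied-enzyme design.
#' @export
fixedDuplexDesign <- function(enzyme = c(0.5, 1, 1.5, 2) * 1e-6) {
  data.frame(enzyme = enzyme, duplex = 1e-6)
}

setMethod("show", "TraceSet", function(object) {
  cat("TraceSet (", object@condition, "): ", length(object@traces),
      " trace(s), ", nrow(object@traces[[1L]]), " points each\n", sep = "")
  cat("  enzyme [M]:", paste(signif(object@design$enzyme, 3), collapse = ", "), "\n")
  cat("  duplex [M]:", paste(signif(object@design$duplex, 3), collapse = ", "), "\n")
})

#' Two-state duplex fraction along a melting curve
#'
#' For a non-self-complementary duplex A + B <-> AB at equal strand totals
#' `strandConc`, the association constant follows the van't Hoff form
#' anchored so that half the strands are paired at `tm`:
#' `K(T) = (2 / strandConc) * exp((-dH / R) * (1/T - 1/Tm))` (temperatures in
#' kelvin). The paired fraction is the exact root of the binding quadratic,
#' evaluated in a cancellation-free form:
#' `theta = 2 u / (u + 1 + sqrt(2 u + 1))` with `u = 2 K strandConc`.
#'
#' @param temperature °C (vectorized).
#' @param tm melting temperature, °C (where theta = 1/2).
#' @param dH van't Hoff enthalpy of association, J/mol (negative).
#' @param strandConc molar concentration of each strand.
#' @return duplex fraction of either strand, in (0, 1).
#' @export
meltFraction <- function(temperature, tm, dH, strandConc) {
  if (dH >= 0) stop("dH must be < 0 (association is exothermic)")
  if (strandConc <= 0) stop("strandConc must be > 0")
  R <- 8.31446261815324
  TK <- temperature + 273.15
  TmK <- tm + 273.15
  K <- (2 / strandConc) * exp((-dH / R) * (1 / TK - 1 / TmK))
  u <- 2 * K * strandConc
  u / (u + 1 + sqrt(2 * u + 1))
}

#' Default melting baselines
#'
#' Linear duplex (ds) and single-strand (ss) baselines per analysis
#' wavelength, plus a flat instrumental 330 nm channel that carries no
#' melting transition. Values are in absorbance units; slopes in a.u./°C.
#'
#' @return nested list keyed by wavelength.
#' @export
defaultMeltingBaselines <- function() {
  list(
    "260" = list(ds = c(intercept = 0.80, slope = 2e-4),
                 ss = c(intercept = 1.00, slope = 4e-4)),
    "270" = list(ds = c(intercept = 0.76, slope = 2e-4),
                 ss = c(intercept = 0.95, slope = 4e-4)),
    "330" = list(baseline = c(intercept = 0.02, slope = 0))
  )
}

#' Simulate a multi-wavelength UV melting curve
#'
#' Generates two-state sigmoidal denaturation curves at 260 and 270 nm
#' (hyperchromic: duplex absorbs less than single strands) with linear
#' baselines, and a transition-free 330 nm control channel, over a heating
#' ramp from 5 to 95 °C in 0.5 °C increments by default.
#'
#' @param tm melting temperature, °C.
#' @param dH van't Hoff association enthalpy, J/mol (negative; default
#'   -400 kJ/mol, typical of a 13-mer duplex).
#' @param strandConc molar concentration of each strand (default 2e-6).
#' @param grid temperature grid, °C.
#' @param baselines per-wavelength baselines, see [defaultMeltingBaselines()].
#' @param noiseSd Gaussian noise sd as a fraction of the maximum absorbance
#'   (default 0.002, i.e. 0.2%).
#' @param seed integer seed.
#' @param label duplex label.
#' @return a [MeltingCurve-class] with ground truth recorded.
#' @export
simulateMeltingCurve <- function(tm, dH = -400e3, strandConc = 2e-6,
                                 grid = seq(5, 95, by = 0.5),
                                 baselines = defaultMeltingBaselines(),
                                 noiseSd = 0.002, seed = NULL, label = "") {
  theta <- meltFraction(grid, tm, dH, strandConc)
  clean <- list()
  for (wl in names(baselines)) {
    bl <- baselines[[wl]]
    if (!is.null(bl$baseline)) {
      clean[[wl]] <- bl$baseline[["intercept"]] + bl$baseline[["slope"]] * grid
    } else {
      ds <- bl$ds[["intercept"]] + bl$ds[["slope"]] * grid
      ss <- bl$ss[["intercept"]] + bl$ss[["slope"]] * grid
      clean[[wl]] <- ds * theta + ss * (1 - theta)
    }
  }
  fullScale <- max(abs(unlist(clean)))
  sd <- noiseSd * fullScale
  absorbance <- withSeed(seed, lapply(clean, function(a) {
    a + if (sd > 0) stats::rnorm(length(a), 0, sd) else 0
  }))
  new("MeltingCurve",
      temperatures = grid, absorbance = absorbance, label = label,
      strandConc = strandConc, processing = list(),
      groundTruth = list(tm = tm, dH = dH, strandConc = strandConc,
                         noiseSd = noiseSd, seed = seed))
}

setMethod("show", "MeltingCurve", function(object) {
  cat("MeltingCurve (", object@label, "): ", length(object@temperatures),
      " points, ", min(object@temperatures), "-", max(object@temperatures),
      " degC at wavelengths ", paste(names(object@absorbance), collapse = "/"),
      " nm\n", sep = "")
})

#' Simulate a hybridization-quenching titration
#'
#' Relative clamp fluorescence versus added partner-strand concentration:
#' `1 - quenchEff * fractionDuplex(...)` for an oxoG-containing partner, flat
#' at 1 for a normal-G partner (no quenching on pairing with G).
#'
#' @param clampConc molar concentration of the clamp-containing strand
#'   (default 1e-5, a 10 uM assay).
#' @param addedSeries molar concentrations of the added partner strand.
#' @param Kd molar dissociation constant of the duplex.
#' @param quenchEff fraction of clamp fluorescence lost on pairing with oxoG.
#' @param partnerIsOxoG if FALSE the partner carries normal G and the signal
#'   stays at 1 apart from noise.
#' @param noiseSd Gaussian noise sd on the relative signal (default 0.01).
#' @param seed integer seed.
#' @return data.frame with columns `partner_total`, `rel_fluorescence`;
#'   generator metadata attached as attribute `"groundTruth"`.
#' @export
simulateTitration <- function(clampConc = 1e-5, addedSeries, Kd, quenchEff,
                              partnerIsOxoG = TRUE, noiseSd = 0.01,
                              seed = NULL) {
  if (clampConc < 0 || any(addedSeries < 0)) stop("concentrations must be >= 0")
  model <- new("QuenchModel", Kd = Kd, quenchEff = quenchEff, f0 = 1,
               se = numeric(0), flags = character(0))
  clean <- predictRelativeFluorescence(model, clampConc, addedSeries,
                                       partnerIsOxoG = partnerIsOxoG)
  rel <- withSeed(seed, clean +
                    if (noiseSd > 0) stats::rnorm(length(clean), 0, noiseSd) else 0)
  out <- data.frame(partner_total = addedSeries, rel_fluorescence = rel)
  attr(out, "groundTruth") <- list(clampConc = clampConc, Kd = Kd,
                                   quenchEff = quenchEff,
                                   partnerIsOxoG = partnerIsOxoG,
                                   noiseSd = noiseSd, seed = seed)
  out
}

#' Simulate a gel-densitometry cleavage time course
#'
#' Applies the consecutive-reaction closed forms of [predictReadouts()] and
#' adds seeded Gaussian densitometry noise (clipped into [0, 1]). The
#' untreated aliquot reports the nicked fraction only; the alkali-treated
#' aliquot reports AP + nicked, because alkali converts AP sites to strand
#' breaks.
#'
#' @param kg,kl,activeFraction,stimulationFactor see [cleavageParams()].
#' @param times sampling times in seconds.
#' @param alkali logical: simulate the alkali-treated readout?
#' @param noiseSd densitometry noise sd on the fraction scale (default 0.03).
#' @param seed integer seed.
#' @param condition duplex label.
#' @return a [CleavageTimeCourse-class] with ground truth recorded.
#' @export
simulateCleavageTimecourse <- function(kg, kl, activeFraction, times,
                                       alkali = TRUE, stimulationFactor = 1,
                                       noiseSd = 0.03, seed = NULL,
                                       condition = "synthetic") {
  params <- cleavageParams(kg, kl, activeFraction, stimulationFactor)
  ro <- predictReadouts(params, times)
  clean <- if (alkali) ro$alkali@readout else ro$untreated@readout
  noisy <- withSeed(seed, clean +
                      if (noiseSd > 0) stats::rnorm(length(clean), 0, noiseSd) else 0)
  noisy <- pmin(1, pmax(0, noisy))
  new("CleavageTimeCourse",
      times = times, readout = noisy, alkaliTreated = alkali,
      condition = condition,
      groundTruth = list(kg = kg, kl = kl, activeFraction = activeFraction,
                         stimulationFactor = stimulationFactor,
                         noiseSd = noiseSd, seed = seed))
}
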
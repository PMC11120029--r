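#' @import methods
NULL

#' Mass-action kinetic scheme
#'
#' A `KineticScheme` holds an ordered species list, a set of (optionally
#' reversible) mass-action steps with up to two reactants and two products,
#' and a named vector of rate constant values. Bimolecular constants are in
#' M^-1 s^-1, unimolecular constants in s^-1. Schemes are compiled to an ODE
#' right-hand side by [compileRHS()] and integrated by [integrateScheme()].
#'
#' @slot species character vector of unique species names, in display order.
#' @slot steps list of steps as returned by [kineticStep()].
#' @slot rateConstants named numeric vector; every rate name referenced by a
#'   step must be present, and all values must be non-negative.
#'
#' @seealso [kineticScheme()], [twoStepBindingScheme()], [derivedConstants()]
#' @export
setClass("KineticScheme",
  representation(
    species = "character",
    steps = "list",
    rateConstants = "numeric"
  )
)

setValidity("KineticScheme", function(object) {
  msgs <- character()
  sp <- object@species
  if (length(sp) == 0L) msgs <- c(msgs, "scheme has no species")
  if (anyDuplicated(sp)) msgs <- c(msgs, "species names must be unique")
  rc <- object@rateConstants
  if (is.null(names(rc)) || any(!nzchar(names(rc)))) {
    msgs <- c(msgs, "rate constants must be named")
  }
  if (any(!is.finite(rc)) || any(rc < 0)) {
    msgs <- c(msgs, "all rate constants must be finite and >= 0")
  }
  for (i in seq_along(object@steps)) {
    st <- object@steps[[i]]
    if (!all(c("reactants", "products", "kf") %in% names(st))) {
      msgs <- c(msgs, sprintf("step %d is malformed", i))
      next
    }
    if (length(st$reactants) > 2L || length(st$products) > 2L) {
      msgs <- c(msgs, sprintf(
        "step %d: mass action is supported up to bimolecular (<= 2 reactants and <= 2 products)", i
      ))
    }
    unknown <- setdiff(c(st$reactants, st$products), sp)
    if (length(unknown)) {
      msgs <- c(msgs, sprintf("step %d references unknown species: %s",
                              i, paste(unknown, collapse = ", ")))
    }
    ks <- c(st$kf, if (!is.na(st$kr)) st$kr)
    missing_k <- setdiff(ks, names(rc))
    if (length(missing_k)) {
      msgs <- c(msgs, sprintf("step %d references undefined rate constants: %s",
                              i, paste(missing_k, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Stopped-flow instrument model
#'
#' Describes the acquisition characteristics of a stopped-flow fluorimeter:
#' the mixing dead time (no observation is possible before it), the sampling
#' grid, and the noise level as a fraction of the full-scale signal.
#'
#' @slot deadTime seconds; first emitted sample is at or after this time.
#'   Default 1.4 ms.
#' @slot times acquisition times in seconds (log-spaced by default).
#' @slot noiseSd Gaussian noise standard deviation expressed as a fraction of
#'   the full-scale (maximum noiseless) signal of a trace set.
#'
#' @seealso [instrumentModel()], [simulateTraceSet()]
#' @export
setClass("InstrumentModel",
  representation(deadTime = "numeric", times = "numeric", noiseSd = "numeric")
)

setValidity("InstrumentModel", function(object) {
  msgs <- character()
  if (length(object@deadTime) != 1L || object@deadTime < 0) {
    msgs <- c(msgs, "deadTime must be a single value >= 0")
  }
  if (length(object@times) < 2L || is.unsorted(object@times, strictly = TRUE)) {
    msgs <- c(msgs, "times must be strictly increasing with >= 2 points")
  }
  if (length(object@times) && min(object@times) < object@deadTime) {
    msgs <- c(msgs, "first sample time must be >= deadTime")
  }
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Linear fluorescence response model
#'
#' The observed signal is `background + sum(coefficients[s] * [s])` over the
#' species of a scheme, in arbitrary fluorescence units; coefficients are in
#' a.u. per molar. Species without a coefficient contribute nothing.
#'
#' @slot background scalar offset, a.u.
#' @slot coefficients named numeric, a.u. per molar of each species.
#'
#' @seealso [responseModel()], [simulateTraceSet()]
#' @export
setClass("ResponseModel",
  representation(background = "numeric", coefficients = "numeric")
)

setValidity("ResponseModel", function(object) {
  msgs <- character()
  if (length(object@background) != 1L || !is.finite(object@background)) {
    msgs <- c(msgs, "background must be a single finite value")
  }
  if (length(object@coefficients) &&
      (is.null(names(object@coefficients)) || any(!is.finite(object@coefficients)))) {
    msgs <- c(msgs, "coefficients must be a named finite numeric vector")
  }
  if (length(msgs)) msgs else TRUE
})

#' A concentration series of stopped-flow traces
#'
#' All traces in a set share one sampling grid, one response model and one
#' underlying mechanism; they differ in total enzyme and duplex
#' concentrations. When produced by [simulateTraceSet()], the `groundTruth`
#' slot records the generating scheme, response, instrument and seed so that
#' parameter-recovery tests are self-contained.
#'
#' @slot traces list of data.frames with columns `time` (s) and `signal` (a.u.).
#' @slot design data.frame with columns `enzyme` and `duplex` (molar totals).
#' @slot condition label of the duplex condition (e.g. "oxoG/C").
#' @slot groundTruth list of generator metadata (empty for imported data).
#'
#' @seealso [simulateTraceSet()], [globalFit()]
#' @export
setClass("TraceSet",
  representation(
    traces = "list",
    design = "data.frame",
    condition = "character",
    groundTruth = "list"
  )
)

setValidity("TraceSet", function(object) {
  msgs <- character()
  if (length(object@traces) != nrow(object@design)) {
    msgs <- c(msgs, "one design row is required per trace")
  }
  if (!all(c("enzyme", "duplex") %in% names(object@design))) {
    msgs <- c(msgs, "design must have columns 'enzyme' and 'duplex'")
  } else if (any(object@design$enzyme <= 0) || any(object@design$duplex <= 0)) {
    msgs <- c(msgs, "all concentrations must be > 0")
  }
  for (tr in object@traces) {
    if (!is.data.frame(tr) || !all(c("time", "signal") %in% names(tr))) {
      msgs <- c(msgs, "each trace must be a data.frame with 'time' and 'signal'")
      break
    }
  }
  if (length(object@traces) > 1L) {
    t1 <- object@traces[[1L]]$time
    same <- vapply(object@traces, function(tr) {
      length(tr$time) == length(t1) && all(tr$time == t1)
    }, logical(1))
    if (!all(same)) msgs <- c(msgs, "all traces in a set must share one sampling grid")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a global kinetic fit
#'
#' @slot estimates named numeric of fitted rate constants.
#' @slot se asymptotic standard errors (same names; NA when the Jacobian is
#'   singular).
#' @slot linearCoefficients profiled linear parameters: one effective
#'   background per trace and one shared response increment per bound species.
#' @slot ssr residual sum of squares.
#' @slot nobs number of fitted points; @slot npar total free parameters
#'   (nonlinear + profiled linear).
#' @slot derived list with stepwise equilibrium constants `K1`, `K2`, overall
#'   association constant `Ka` (M^-1) and `KaSE`.
#' @slot residuals list of per-trace residual vectors.
#' @slot status convergence status string; @slot niter iterations used.
#' @slot scheme the fitted [KineticScheme-class] with estimated constants.
#' @slot window upper time bound (s) of the data actually fitted.
#'
#' @seealso [globalFit()], [selectMechanism()], [compareConditions()]
#' @export
setClass("FitResult",
  representation(
    estimates = "numeric",
    se = "numeric",
    linearCoefficients = "numeric",
    ssr = "numeric",
    nobs = "integer",
    npar = "integer",
    derived = "list",
    residuals = "list",
    status = "character",
    niter = "integer",
    scheme = "KineticScheme",
    window = "numeric"
  )
)

#' Report of stepwise mechanism selection
#'
#' @slot history data.frame with one row per (window, candidate) fit:
#'   columns `window`, `candidate`, `npar`, `ssr`, `aic`, `fstat`, `pvalue`,
#'   `decision`.
#' @slot chosen index of the selected candidate (smallest not rejected).
#' @slot fits list of the final [FitResult-class] per candidate examined at
#'   the full window.
#' @slot flags character vector of diagnostics (e.g. unidentifiability).
#'
#' @seealso [selectMechanism()]
#' @export
setClass("SelectionReport",
  representation(
    history = "data.frame",
    chosen = "integer",
    fits = "list",
    flags = "character"
  )
)

#' Multi-wavelength DNA melting curve
#'
#' Absorbance versus temperature recorded at several wavelengths during
#' heating. The 330 nm channel is expected to carry no melting transition and
#' is used by [baselineCorrect()] as an instrumental baseline reference.
#'
#' @slot temperatures ascending °C grid within [5, 95].
#' @slot absorbance named list (by wavelength, e.g. "260") of absorbance
#'   vectors, all the same length as the grid.
#' @slot label duplex label.
#' @slot strandConc molar concentration of each strand.
#' @slot processing list recording applied processing steps.
#' @slot groundTruth generator metadata (empty for imported data).
#'
#' @seealso [simulateMeltingCurve()], [differentialMelting()]
#' @export
setClass("MeltingCurve",
  representation(
    temperatures = "numeric",
    absorbance = "list",
    label = "character",
    strandConc = "numeric",
    processing = "list",
    groundTruth = "list"
  )
)

setValidity("MeltingCurve", function(object) {
  msgs <- character()
  tt <- object@temperatures
  if (is.unsorted(tt, strictly = TRUE)) {
    msgs <- c(msgs, "temperatures must be strictly increasing")
  }
  if (length(tt) && (min(tt) < 5 - 1e-9 || max(tt) > 95 + 1e-9)) {
    msgs <- c(msgs, "temperatures must lie within [5, 95] degC")
  }
  if (!length(object@absorbance) || is.null(names(object@absorbance))) {
    msgs <- c(msgs, "absorbance must be a named list keyed by wavelength")
  } else {
    len_ok <- vapply(object@absorbance, function(a) length(a) == length(tt), logical(1))
    if (!all(len_ok)) msgs <- c(msgs, "absorbance grids must match the temperature grid")
  }
  if (length(object@strandConc) == 1L && object@strandConc <= 0) {
    msgs <- c(msgs, "strandConc must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Melting temperature estimate
#'
#' @slot perWavelength named numeric of Tm estimates (°C) per analysis
#'   wavelength; NA where no transition was detected.
#' @slot consensus unweighted mean of the defined per-wavelength estimates.
#' @slot derivatives list of data.frames (`temperature`, `dAdT`) per
#'   wavelength.
#' @slot settings smoothing settings used.
#'
#' @seealso [differentialMelting()], [deltaTm()]
#' @export
setClass("TmEstimate",
  representation(
    perWavelength = "numeric",
    consensus = "numeric",
    derivatives = "list",
    settings = "list"
  )
)

#' Hybridization-quenching model
#'
#' Static two-state quenching: the clamp strand is bright when free and loses
#' the fraction `quenchEff` of its fluorescence when paired with an
#' oxoG-containing partner; pairing with a normal-G partner does not quench.
#'
#' @slot Kd molar dissociation constant of the duplex.
#' @slot quenchEff fraction of clamp fluorescence lost on pairing, in [0, 1].
#' @slot f0 unquenched fluorescence (a.u.).
#' @slot se standard errors from [fitQuenchTitration()] (may be empty).
#' @slot flags diagnostics (e.g. saturation / identifiability warnings).
#'
#' @seealso [predictRelativeFluorescence()], [fitQuenchTitration()]
#' @export
setClass("QuenchModel",
  representation(
    Kd = "numeric",
    quenchEff = "numeric",
    f0 = "numeric",
    se = "numeric",
    flags = "character"
  )
)

setValidity("QuenchModel", function(object) {
  msgs <- character()
  if (object@Kd <= 0) msgs <- c(msgs, "Kd must be > 0")
  if (object@quenchEff < 0 || object@quenchEff > 1) {
    msgs <- c(msgs, "quenchEff must be in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Single-turnover cleavage parameters
#'
#' Consecutive first-order model for a bifunctional glycosylase acting on a
#' pre-bound substrate: base excision (rate `kg`) leaves an AP site, which is
#' then incised by the AP-lyase activity (rate `kl`). Only the fraction
#' `activeFraction` of substrate is processed at all; `stimulationFactor`
#' multiplies `kl` to represent lyase stimulation by added base analogs.
#'
#' @slot kg N-glycosylase rate, s^-1.
#' @slot kl AP-lyase rate, s^-1.
#' @slot activeFraction fraction of substrate processed at t -> Inf, in [0, 1].
#' @slot stimulationFactor multiplier (>= 1) applied to `kl`.
#'
#' @seealso [predictFractions()], [predictReadouts()], [fitCleavage()]
#' @export
setClass("CleavageParams",
  representation(
    kg = "numeric",
    kl = "numeric",
    activeFraction = "numeric",
    stimulationFactor = "numeric"
  )
)

setValidity("CleavageParams", function(object) {
  msgs <- character()
  if (object@kg < 0 || object@kl < 0) msgs <- c(msgs, "rates must be >= 0")
  if (object@activeFraction < 0 || object@activeFraction > 1) {
    msgs <- c(msgs, "activeFraction must be in [0, 1]")
  }
  if (object@stimulationFactor < 1) msgs <- c(msgs, "stimulationFactor must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Gel-densitometry cleavage time course
#'
#' @slot times seconds, non-negative and increasing.
#' @slot readout fraction cleaved in [0, 1]: nicked only for untreated
#'   aliquots, AP + nicked for alkali-treated aliquots.
#' @slot alkaliTreated logical flag.
#' @slot condition duplex label.
#' @slot groundTruth generator metadata (empty for imported data).
#'
#' @seealso [simulateCleavageTimecourse()], [fitCleavage()]
#' @export
setClass("CleavageTimeCourse",
  representation(
    times = "numeric",
    readout = "numeric",
    alkaliTreated = "logical",
    condition = "character",
    groundTruth = "list"
  )
)

setValidity("CleavageTimeCourse", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@readout)) {
    msgs <- c(msgs, "times and readout must have equal length")
  }
  if (length(object@times) && (any(object@times < 0) ||
      is.unsorted(object@times, strictly = TRUE))) {
    msgs <- c(msgs, "times must be non-negative and strictly increasing")
  }
  if (any(object@readout < -1e-9) || any(object@readout > 1 + 1e-9)) {
    msgs <- c(msgs, "readout fractions must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a joint cleavage fit
#'
#' @slot params fitted [CleavageParams-class].
#' @slot se standard errors for `kg`, `kl`, `activeFraction`.
#' @slot flags identifiability diagnostics.
#' @slot ssr residual sum of squares; @slot nobs points fitted.
#'
#' @seealso [fitCleavage()]
#' @export
setClass("CleavageFit",
  representation(
    params = "CleavageParams",
    se = "numeric",
    flags = "character",
    ssr = "numeric",
    nobs = "integer"
  )
)
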
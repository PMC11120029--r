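#' Synthetic reference parameter sets for the study conditions
#'
#' The elementary rate constants below are synthetic: the study this package
#' models reports only summary constants in its text (the overall binding
#' constants Ka, the melting temperatures, the ~20% equimolar quench, the
#' 2 h cleavage plateaus), not the elementary rates themselves. Each fixture
#' is therefore a parameter set chosen once so that the quantity it implies
#' matches the reported summary value, and is used to drive the synthetic
#' generators in tests and demos.
#'
#' `conditionFixtures()` returns two-step binding rate constants per duplex
#' condition; the implied overall association constants are
#' Ka = K1 (1 + K2): 5e6 M^-1 for oxoG/C, 0.45e6 for G/C, and 0.25e6 for
#' oxoG/oxoG-clamp (an order of magnitude or more below the specific
#' substrate).
#'
#' @return `conditionFixtures()`: named list per condition with elements
#'   `k1`, `k_1`, `k2`, `k_2` and the implied `Ka`.
#' @export
conditionFixtures <- function() {
  fx <- list(
    "oxoG/C" = c(k1 = 2e7, k_1 = 20, k2 = 20, k_2 = 5),
    "G/C" = c(k1 = 9e6, k_1 = 50, k2 = 15, k_2 = 10),
    "oxoG/oxoG-clamp" = c(k1 = 5e6, k_1 = 50, k2 = 15, k_2 = 10)
  )
  lapply(fx, function(k) {
    sch <- twoStepBindingScheme(k[["k1"]], k[["k_1"]], k[["k2"]], k[["k_2"]])
    c(as.list(k), Ka = derivedConstants(sch)$Ka)
  })
}

#' @rdname conditionFixtures
#' @param dH,strandConc passed to [anchorForDerivativeMax()] when computing
#'   generator anchors.
#' @return `meltingFixtures()`: data.frame of duplex labels, reference
#'   melting temperatures (°C; the operational derivative-maximum values:
#'   48/35 for the oxoG pair opposite C / oxoG-clamp, 49/33 for the G pair,
#'   24/21 for the AP-site pair) and the corresponding van't Hoff
#'   half-pairing `anchor` to hand to [simulateMeltingCurve()] so the
#'   simulated differential melting curve peaks at the reference value.
#' @export
meltingFixtures <- function(dH = -400e3, strandConc = 2e-6) {
  out <- data.frame(
    duplex = c("oxoG/C", "oxoG/oxoG-clamp", "G/C", "G/oxoG-clamp",
               "AP/C", "AP/oxoG-clamp"),
    tm = c(48, 35, 49, 33, 24, 21)
  )
  out$anchor <- vapply(out$tm, anchorForDerivativeMax, numeric(1),
                       dH = dH, strandConc = strandConc)
  out
}

#' @rdname conditionFixtures
#' @return `quenchFixture()`: a [QuenchModel-class] with Kd = 0.1 uM and the
#'   quench efficiency calibrated so that the equimolar point of a 10 uM
#'   titration shows a 20% fluorescence decrease.
#' @export
quenchFixture <- function() {
  Kd <- 1e-7
  clamp <- 1e-5
  quenchEff <- 0.20 / fractionDuplex(clamp, clamp, Kd)
  quenchModel(Kd = Kd, quenchEff = quenchEff)
}

#' @rdname conditionFixtures
#' @return `cleavageFixtures()`: named list per condition of
#'   [CleavageParams-class]; the oxoG/C rates are chosen so the alkali
#'   readout plateaus within 2 h at ~55% and the untreated readout reaches
#'   ~46%, and the clamp-opposed conditions have kg = 0 (no product
#'   formation).
#' @export
cleavageFixtures <- function() {
  list(
    "oxoG/C" = cleavageParams(kg = 1e-3, kl = 3e-4, activeFraction = 0.55),
    "oxoG/oxoG-clamp" = cleavageParams(kg = 0, kl = 0, activeFraction = 0),
    "AP/oxoG-clamp" = cleavageParams(kg = 0, kl = 0, activeFraction = 0)
  )
}
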
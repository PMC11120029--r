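#' Equilibrium duplex fraction of the clamp strand
#'
#' Exact root of the two-component binding quadratic for
#' A + B <-> AB with totals `clampTotal` (A) and `partnerTotal` (B) and
#' dissociation constant `Kd`:
#' `D = 2AB / ((A + B + Kd) + sqrt((A - B)^2 + 2 Kd (A + B) + Kd^2))`.
#' The discriminant is expanded in the cancellation-free form above so the
#' result stays accurate when `Kd` is far below the totals.
#'
#' @param clampTotal molar total of the clamp-containing strand (scalar).
#' @param partnerTotal molar total of the added partner strand (vectorized).
#' @param Kd molar dissociation constant (> 0).
#' @return fraction of the clamp strand in duplex, in [0, 1].
#' @examples
#' fractionDuplex(1e-5, 1e-5, 1e-5)  # A = B = Kd: (3 - sqrt(5)) / 2
#' @export
fractionDuplex <- function(clampTotal, partnerTotal, Kd) {
  if (Kd <= 0) stop("Kd must be > 0")
  if (clampTotal < 0 || any(partnerTotal < 0)) stop("totals must be >= 0")
  if (clampTotal == 0) return(rep(0, length(partnerTotal)))
  A <- clampTotal
  B <- partnerTotal
  disc <- (A - B)^2 + 2 * Kd * (A + B) + Kd^2
  D <- 2 * A * B / ((A + B + Kd) + sqrt(disc))
  D / A
}

#' Construct a quenching model
#'
#' @param Kd molar dissociation constant of the clamp duplex.
#' @param quenchEff fraction of clamp fluorescence lost on pairing with an
#'   oxoG-containing partner, in [0, 1].
#' @param f0 unquenched fluorescence in a.u. (the relative-signal scale uses
#'   f0 = 1).
#' @return a [QuenchModel-class].
#' @export
quenchModel <- function(Kd, quenchEff, f0 = 1) {
  new("QuenchModel", Kd = Kd, quenchEff = quenchEff, f0 = f0,
      se = numeric(0), flags = character(0))
}

setMethod("show", "QuenchModel", function(object) {
  cat("QuenchModel: Kd =", signif(object@Kd, 4), "M, quenchEff =",
      signif(object@quenchEff, 4), "\n")
  if (length(object@se)) {
    cat("  SE:", paste(sprintf("%s = %.3g", names(object@se), object@se),
                       collapse = ", "), "\n")
  }
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' Predict relative clamp fluorescence
#'
#' Static two-state quenching: the bound clamp is partially dark, the free
#' clamp fully bright, so the relative signal is
#' `1 - quenchEff * fractionDuplex(...)`. A partner carrying normal G does
#' not quench the clamp, so `partnerIsOxoG = FALSE` forces the quench
#' efficiency to zero and the predicted signal to 1.
#'
#' @param model a [QuenchModel-class].
#' @param clampTotal molar total of the clamp strand.
#' @param partnerTotal molar total of added partner strand (vectorized).
#' @param partnerIsOxoG does the partner carry 8-oxoguanine?
#' @return relative fluorescence in [1 - quenchEff, 1].
#' @export
predictRelativeFluorescence <- function(model, clampTotal, partnerTotal,
                                        partnerIsOxoG = TRUE) {
  validObject(model)
  if (!partnerIsOxoG) return(rep(1, length(partnerTotal)))
  1 - model@quenchEff * fractionDuplex(clampTotal, partnerTotal, model@Kd)
}

#' Fit a quenching titration
#'
#' Least-squares fit of the static-quenching isotherm to a titration series.
#' `Kd` is fitted on the log scale (it is positive and can span decades) and
#' `quenchEff` within [0, 1]. When every titration point is saturating
#' (fitted duplex fraction > 0.95 throughout), `Kd` and `quenchEff` are
#' weakly separable; a flag is set and the `Kd` estimate should be read as
#' an upper bound only.
#'
#' @param series data.frame with columns `partner_total` and
#'   `rel_fluorescence` (>= 4 points spanning sub- to super-equimolar
#'   recommended).
#' @param clampTotal molar total of the clamp strand.
#' @param fixKd,fixQuenchEff optionally fix either parameter.
#' @param start optional named list of starting values (`Kd`, `quenchEff`).
#' @return a fitted [QuenchModel-class] with standard errors and flags.
#' @export
fitQuenchTitration <- function(series, clampTotal, fixKd = NULL,
                               fixQuenchEff = NULL, start = NULL) {
  stopifnot(all(c("partner_total", "rel_fluorescence") %in% names(series)))
  if (nrow(series) < 4L) {
    warning("fewer than 4 titration points; estimates may be unreliable")
  }
  B <- series$partner_total
  y <- series$rel_fluorescence
  if (max(B) < clampTotal || min(B[B > 0], na.rm = TRUE) > clampTotal) {
    warning("titration does not span sub- to super-equimolar partner concentrations")
  }
  s0 <- list(
    Kd = if (!is.null(start$Kd)) start$Kd else clampTotal / 10,
    quenchEff = if (!is.null(start$quenchEff)) start$quenchEff
                else min(0.95, max(0.05, 1 - min(y)))
  )
  freeKd <- is.null(fixKd)
  freeQ <- is.null(fixQuenchEff)
  par0 <- c(if (freeKd) log(s0$Kd), if (freeQ) s0$quenchEff)
  unpack <- function(p) {
    i <- 1L
    Kd <- if (freeKd) { v <- exp(p[i]); i <- i + 1L; v } else fixKd
    q <- if (freeQ) p[i] else fixQuenchEff
    list(Kd = Kd, quenchEff = q)
  }
  resFun <- function(p) {
    pp <- unpack(p)
    y - (1 - pp$quenchEff * fractionDuplex(clampTotal, B, pp$Kd))
  }
  lower <- c(if (freeKd) log(1e-15), if (freeQ) 0)
  upper <- c(if (freeKd) log(1), if (freeQ) 1)
  fit <- minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resFun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  pp <- unpack(fit$par)
  flags <- character(0)
  frac <- fractionDuplex(clampTotal, B[B > 0], pp$Kd)
  if (length(frac) && all(frac > 0.95)) {
    flags <- c(flags, "saturated")
    warning("all titration points are saturating; Kd and quenchEff are ",
            "weakly separable and Kd is identified only as an upper bound")
  }
  nfree <- length(par0)
  se <- stats::setNames(rep(NA_real_, nfree),
                        c(if (freeKd) "Kd", if (freeQ) "quenchEff"))
  dof <- length(y) - nfree
  if (dof > 0) {
    s2 <- sum(fit$fvec^2) / dof
    cv <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
    if (!is.null(cv)) {
      sdiag <- sqrt(pmax(0, diag(cv)))
      i <- 1L
      if (freeKd) { se[["Kd"]] <- pp$Kd * sdiag[i]; i <- i + 1L }  # delta method, log scale
      if (freeQ) se[["quenchEff"]] <- sdiag[i]
    }
  }
  out <- quenchModel(pp$Kd, min(1, max(0, pp$quenchEff)))
  out@se <- se
  out@flags <- flags
  out
}
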
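#' Define one mass-action step
#'
#' @param reactants character vector of 1-2 reactant species (repeat a name
#'   for a homodimerization step).
#' @param products character vector of 1-2 product species.
#' @param kf name of the forward rate constant.
#' @param kr name of the reverse rate constant, or `NA` for an irreversible
#'   step.
#' @return a step descriptor for [kineticScheme()].
#' @export
kineticStep <- function(reactants, products, kf, kr = NA_character_) {
  stopifnot(is.character(reactants), is.character(products),
            is.character(kf), length(kf) == 1L)
  list(reactants = reactants, products = products,
       kf = kf, kr = as.character(kr))
}

#' Construct a kinetic scheme
#'
#' @param species ordered character vector of species names.
#' @param steps list of steps from [kineticStep()].
#' @param rateConstants named numeric vector of rate constant values;
#'   bimolecular constants in M^-1 s^-1, unimolecular in s^-1, all >= 0.
#' @return a validated [KineticScheme-class].
#' @examples
#' sch <- kineticScheme(
#'   species = c("E", "S", "ES"),
#'   steps = list(kineticStep(c("E", "S"), "ES", "k1", "k_1")),
#'   rateConstants = c(k1 = 1e6, k_1 = 10)
#' )
#' @export
kineticScheme <- function(species, steps, rateConstants) {
  new("KineticScheme", species = species, steps = steps,
      rateConstants = rateConstants)
}

#' @describeIn kineticScheme reversible one-step binding E + S <-> ES.
#' @param k1,k_1,k2,k_2,k3,k_3 rate constant values (>= 0).
#' @export
oneStepBindingScheme <- function(k1, k_1) {
  kineticScheme(
    species = c("E", "S", "ES"),
    steps = list(kineticStep(c("E", "S"), "ES", "k1", "k_1")),
    rateConstants = c(k1 = k1, k_1 = k_1)
  )
}

#' @describeIn kineticScheme two reversible stages
#'   E + S <-> ES <-> ES* (bimolecular encounter followed by a unimolecular
#'   rearrangement of the complex).
#' @export
twoStepBindingScheme <- function(k1, k_1, k2, k_2) {
  kineticScheme(
    species = c("E", "S", "ES", "ES*"),
    steps = list(
      kineticStep(c("E", "S"), "ES", "k1", "k_1"),
      kineticStep("ES", "ES*", "k2", "k_2")
    ),
    rateConstants = c(k1 = k1, k_1 = k_1, k2 = k2, k_2 = k_2)
  )
}

#' @describeIn kineticScheme three reversible stages
#'   E + S <-> ES <-> ES* <-> ES**, used as selection headroom.
#' @export
threeStepBindingScheme <- function(k1, k_1, k2, k_2, k3, k_3) {
  kineticScheme(
    species = c("E", "S", "ES", "ES*", "ES**"),
    steps = list(
      kineticStep(c("E", "S"), "ES", "k1", "k_1"),
      kineticStep("ES", "ES*", "k2", "k_2"),
      kineticStep("ES*", "ES**", "k3", "k_3")
    ),
    rateConstants = c(k1 = k1, k_1 = k_1, k2 = k2, k_2 = k_2,
                      k3 = k3, k_3 = k_3)
  )
}

#' Species of a scheme
#' @param scheme a [KineticScheme-class].
#' @return character vector of species names.
#' @export
speciesNames <- function(scheme) scheme@species

#' Rate constants of a scheme
#' @param scheme a [KineticScheme-class].
#' @return named numeric vector.
#' @export
rateConstants <- function(scheme) scheme@rateConstants

#' Replace rate constant values
#' @param scheme a [KineticScheme-class].
#' @param value named numeric vector; names must match the existing constants.
#' @return the updated, re-validated scheme.
#' @export
`rateConstants<-` <- function(scheme, value) {
  if (is.null(names(value))) stop("replacement rate constants must be named")
  rc <- scheme@rateConstants
  unknown <- setdiff(names(value), names(rc))
  if (length(unknown)) {
    stop("unknown rate constants: ", paste(unknown, collapse = ", "))
  }
  rc[names(value)] <- value
  scheme@rateConstants <- rc
  validObject(scheme)
  scheme
}

setMethod("show", "KineticScheme", function(object) {
  cat("KineticScheme with", length(object@species), "species and",
      length(object@steps), "step(s)\n")
  for (st in object@steps) {
    arrow <- if (is.na(st$kr)) "->" else "<->"
    klab <- if (is.na(st$kr)) st$kf else paste(st$kf, st$kr, sep = ", ")
    cat(" ", paste(st$reactants, collapse = " + "), arrow,
        paste(st$products, collapse = " + "), ";", klab, "\n")
  }
  cat("  rates:", paste(sprintf("%s = %.4g", names(object@rateConstants),
                                object@rateConstants), collapse = ", "), "\n")
})

## internal: per-flux index structure and net stoichiometry matrix
.schemeStructure <- function(scheme) {
  sp <- scheme@species
  nsp <- length(sp)
  nst <- length(scheme@steps)
  N <- matrix(0, nsp, nst, dimnames = list(sp, NULL))
  react <- vector("list", nst)
  prod <- vector("list", nst)
  kf <- character(nst)
  kr <- character(nst)
  for (j in seq_len(nst)) {
    st <- scheme@steps[[j]]
    ri <- match(st$reactants, sp)
    pi <- match(st$products, sp)
    for (i in ri) N[i, j] <- N[i, j] - 1
    for (i in pi) N[i, j] <- N[i, j] + 1
    react[[j]] <- ri
    prod[[j]] <- pi
    kf[j] <- st$kf
    kr[j] <- st$kr
  }
  list(N = N, react = react, prod = prod, kf = kf, kr = kr)
}

#' Compile a scheme to an ODE right-hand side
#'
#' Produces a deterministic, side-effect-free derivative function in the form
#' expected by [deSolve::ode()] (`function(t, y, parms)` returning
#' `list(dy)`), with an analytic mass-action Jacobian attached as the
#' `"jacobian"` attribute and the net stoichiometry matrix as
#' `"stoichiometry"`.
#'
#' @param scheme a valid [KineticScheme-class].
#' @return the derivative function (see Details).
#' @examples
#' sch <- twoStepBindingScheme(5e6, 50, 15, 10)
#' rhs <- compileRHS(sch)
#' y <- c(E = 1e-6, S = 1e-6, ES = 0, "ES*" = 0)
#' rhs(0, y, NULL)[[1]]
#' @export
compileRHS <- function(scheme) {
  validObject(scheme)
  str <- .schemeStructure(scheme)
  k <- scheme@rateConstants
  nflux <- length(str$kf)
  kfv <- unname(k[str$kf])
  krv <- vapply(str$kr, function(nm) if (is.na(nm)) 0 else unname(k[[nm]]),
                numeric(1), USE.NAMES = FALSE)
  react <- str$react
  prod <- str$prod
  N <- str$N
  nsp <- nrow(N)

  rhs <- function(t, y, parms) {
    v <- numeric(nflux)
    for (j in seq_len(nflux)) {
      fwd <- kfv[j]
      for (i in react[[j]]) fwd <- fwd * y[[i]]
      rev <- krv[j]
      if (rev != 0) for (i in prod[[j]]) rev <- rev * y[[i]]
      v[j] <- fwd - rev
    }
    list(as.vector(N %*% v))
  }

  ## d(prod over idx of y)/dy_i, handling repeated indices (y_A^2 -> 2 y_A)
  dprod <- function(idx, y, kval) {
    g <- numeric(nsp)
    if (kval == 0) return(g)
    for (pos in seq_along(idx)) {
      term <- kval
      others <- idx[-pos]
      for (i in others) term <- term * y[[i]]
      g[idx[pos]] <- g[idx[pos]] + term
    }
    g
  }

  jac <- function(t, y, parms) {
    dv <- matrix(0, nflux, nsp)
    for (j in seq_len(nflux)) {
      dv[j, ] <- dprod(react[[j]], y, kfv[j]) - dprod(prod[[j]], y, krv[j])
    }
    N %*% dv
  }

  attr(rhs, "jacobian") <- jac
  attr(rhs, "stoichiometry") <- N
  rhs
}

#' Conservation laws of a scheme
#'
#' Returns a basis of the left null space of the net stoichiometry matrix:
#' every column `v` satisfies `t(v) %*% dy/dt == 0`, so `sum(v * y)` is
#' constant along any trajectory (e.g. total enzyme, total DNA).
#'
#' @param scheme a [KineticScheme-class].
#' @return numeric matrix (species x laws), possibly with zero columns when
#'   no conservation law exists.
#' @export
conservationLaws <- function(scheme) {
  N <- attr(compileRHS(scheme), "stoichiometry")
  sv <- svd(N, nu = nrow(N))
  rank <- sum(sv$d > max(dim(N)) * max(sv$d, 0) * 1e-12)
  if (rank >= nrow(N)) {
    return(matrix(numeric(0), nrow(N), 0, dimnames = list(rownames(N), NULL)))
  }
  basis <- sv$u[, (rank + 1L):nrow(N), drop = FALSE]
  rownames(basis) <- rownames(N)
  basis
}

#' Integrate a kinetic scheme
#'
#' Integrates the compiled mass-action ODE system with a stiff-capable solver
#' (lsoda) using the analytic Jacobian; rate constants in a scheme may span
#' many orders of magnitude. Concentrations marginally below zero (>= -1e-12
#' M, integrator round-off) are clipped to zero; larger negatives raise an
#' error.
#'
#' @param scheme a valid [KineticScheme-class].
#' @param init named numeric of initial molar concentrations; species not
#'   named start at zero.
#' @param times strictly increasing output times in seconds (a leading t = 0
#'   is added internally when absent and dropped from the output only if it
#'   was absent from `times`).
#' @param rtol,atol relative / absolute integration tolerances (defaults
#'   1e-8 and 1e-12 M).
#' @return data.frame with column `time` and one column per species.
#' @examples
#' sch <- twoStepBindingScheme(5e6, 50, 15, 10)
#' traj <- integrateScheme(sch, c(E = 2e-6, S = 1e-6), c(0.001, 0.01, 0.1, 1))
#' @export
integrateScheme <- function(scheme, init, times, rtol = 1e-8, atol = 1e-12) {
  validObject(scheme)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(times < 0)) stop("times must be >= 0")
  sp <- scheme@species
  y0 <- stats::setNames(numeric(length(sp)), sp)
  if (length(init)) {
    unknown <- setdiff(names(init), sp)
    if (length(unknown)) {
      stop("init names unknown species: ", paste(unknown, collapse = ", "))
    }
    y0[names(init)] <- init
  }
  if (any(y0 < 0)) stop("initial concentrations must be >= 0")
  prepend0 <- times[1L] > 0
  tt <- if (prepend0) c(0, times) else times
  rhs <- compileRHS(scheme)
  out <- tryCatch(
    deSolve::ode(y = y0, times = tt, func = rhs,
                 jacfunc = attr(rhs, "jacobian"), jactype = "fullusr",
                 parms = NULL, method = "lsoda", rtol = rtol, atol = atol),
    warning = function(w) {
      stop("ODE integration failed for scheme with rates [",
           paste(sprintf("%s=%.3g", names(scheme@rateConstants),
                         scheme@rateConstants), collapse = ", "),
           "]: ", conditionMessage(w))
    }
  )
  out <- as.data.frame(out)
  if (prepend0) out <- out[-1L, , drop = FALSE]
  conc <- as.matrix(out[, sp, drop = FALSE])
  if (any(conc < -1e-12)) {
    bad <- which(conc < -1e-12, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "integration produced a negative concentration (%.3g) for species '%s'",
      conc[bad[1L], bad[2L]], sp[bad[2L]]))
  }
  conc[conc < 0] <- 0
  out[, sp] <- conc
  rownames(out) <- NULL
  out
}

#' Equilibrium constants derived from a binding chain
#'
#' For a scheme of the chain form `E + S <-> ES <-> ES* <-> ...` computes the
#' stepwise equilibrium constants `Ki = kf_i / kr_i` and the overall
#' association constant lumping all bound species over free species,
#' `Ka = K1 * (1 + K2 + K2*K3 + ...)`; for the two-step scheme this is
#' `Ka = K1 * (1 + K2)`.
#'
#' @param scheme a [KineticScheme-class] whose steps form a binding chain
#'   (one bimolecular association followed by unimolecular isomerizations).
#' @return list with elements `K1` (M^-1), `K2` (dimensionless; NA for a
#'   one-step scheme), `Ka` (M^-1) and `stepConstants` (all Ki).
#' @examples
#' derivedConstants(twoStepBindingScheme(5e6, 50, 15, 10))  # Ka = 2.5e5
#' @export
derivedConstants <- function(scheme) {
  validObject(scheme)
  steps <- scheme@steps
  if (!length(steps)) stop("scheme has no steps")
  if (length(steps[[1L]]$reactants) != 2L || length(steps[[1L]]$products) != 1L) {
    stop("derivedConstants expects a binding chain starting with a bimolecular association")
  }
  if (length(steps) > 1L) {
    for (j in 2:length(steps)) {
      if (length(steps[[j]]$reactants) != 1L || length(steps[[j]]$products) != 1L) {
        stop("derivedConstants expects unimolecular isomerization steps after the first")
      }
    }
  }
  k <- scheme@rateConstants
  Ki <- vapply(steps, function(st) {
    if (is.na(st$kr) || k[[st$kr]] == 0) {
      stop("equilibrium undefined: reverse rate of step '", st$kf,
           "' is zero or absent")
    }
    k[[st$kf]] / k[[st$kr]]
  }, numeric(1))
  ## cumulative product over bound states: [ES_i]/([E][S]) = K1*K2*...*Ki
  cumK <- cumprod(Ki)
  Ka <- sum(cumK)
  list(
    K1 = Ki[[1L]],
    K2 = if (length(Ki) >= 2L) Ki[[2L]] else NA_real_,
    Ka = Ka,
    stepConstants = unname(Ki)
  )
}
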
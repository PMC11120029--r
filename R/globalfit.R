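#' Fit a single exponential to one trace
#'
#' Least-squares fit of `A * exp(-kobs * t) + B`, used as the seed of the
#' stepwise selection procedure and for kobs-versus-concentration
#' diagnostics of the initial, single-exponential part of a binding curve.
#'
#' @param time,signal numeric vectors, or pass a data.frame with columns
#'   `time` and `signal` as the first argument.
#' @param window optional upper time bound (s); at least 10 points must
#'   remain.
#' @return list with `amplitude`, `kobs`, `offset`, `ssr` and a `flag`
#'   (`"ok"`, `"unidentifiable"` for a constant trace, or
#'   `"nonpositiveRate"` when the optimum drifts to kobs <= 0).
#' @export
fitSingleExponential <- function(time, signal = NULL, window = NULL) {
  if (is.data.frame(time)) {
    signal <- time$signal
    time <- time$time
  }
  if (!is.null(window)) {
    keep <- time <= window
    time <- time[keep]
    signal <- signal[keep]
  }
  if (length(time) < 10L) stop("window must contain at least 10 points")
  B0 <- mean(utils::tail(signal, max(5L, length(signal) %/% 10L)))
  A0 <- signal[1L] - B0
  noise <- stats::sd(diff(signal)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if (abs(A0) <= 3 * noise / sqrt(length(signal)) && stats::sd(signal) <= 1.5 * noise) {
    return(list(amplitude = 0, kobs = NA_real_, offset = mean(signal),
                ssr = sum((signal - mean(signal))^2), flag = "unidentifiable"))
  }
  ## crude rate from the time where the decay has relaxed to ~37%
  target <- B0 + A0 * exp(-1)
  k0 <- 1 / max(time[which.min(abs(signal - target))], min(time[time > 0]))
  resFun <- function(p) signal - (p[1L] * exp(-exp(p[2L]) * time) + p[3L])
  best <- NULL
  for (k0try in unique(c(k0, k0 * 10, k0 / 10))) {
    fit <- minpack.lm::nls.lm(
      par = c(A0, log(k0try), B0), fn = resFun,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14, ptol = 1e-14)
    )
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  kobs <- exp(best$par[2L])
  flag <- if (kobs <= 0) "nonpositiveRate" else "ok"
  list(amplitude = best$par[1L], kobs = kobs, offset = best$par[3L],
       ssr = sum(best$fvec^2), flag = flag)
}

## bimolecular rate names of a scheme (those of 2-reactant / 2-product sides)
.bimolecularRates <- function(scheme) {
  out <- character(0)
  for (st in scheme@steps) {
    if (length(st$reactants) == 2L) out <- c(out, st$kf)
    if (!is.na(st$kr) && length(st$products) == 2L) out <- c(out, st$kr)
  }
  unique(out)
}

## variable projection over the linear response parameters: either one
## shared background plus shared per-species responses (default, a single
## optical session), or one free background per trace plus shared response
## increments for the bound species
.projectLinear <- function(concList, signals, perTrace = FALSE) {
  m <- length(concList)
  nb <- ncol(concList[[1L]])
  ns <- vapply(concList, nrow, integer(1))
  ncolX <- if (perTrace) m + nb else 1L + nb
  X <- matrix(0, sum(ns), ncolX)
  y <- unlist(signals, use.names = FALSE)
  at <- 0L
  for (i in seq_len(m)) {
    rows <- at + seq_len(ns[i])
    if (perTrace) {
      X[rows, i] <- 1
      X[rows, m + seq_len(nb)] <- concList[[i]]
    } else {
      X[rows, 1L] <- 1
      X[rows, 1L + seq_len(nb)] <- concList[[i]]
    }
    at <- at + ns[i]
  }
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  beta[is.na(beta)] <- 0
  fitted <- X %*% beta
  list(beta = beta, resid = y - as.vector(fitted), rank = qrX$rank,
       ncol = ncolX)
}

#' Global fit of a trace set under a candidate mechanism
#'
#' Minimizes the summed squared residuals over all traces simultaneously.
#' Rate constants are shared across traces and optimized on the log scale by
#' trust-region least squares with seeded multi-start; the linear response
#' parameters (one effective background per trace and one shared response
#' increment per enzyme-bound species) are profiled out exactly at every
#' step by linear least squares. The model is integrated from mixing
#' (t = 0) but residuals are evaluated only at the sampled times (all at or
#' after the instrument dead time), so the pre-dead-time evolution is
#' absorbed rather than re-zeroed.
#'
#' By default one background and one response per DNA-containing species
#' are shared across all traces of a set (a concentration series is
#' recorded in a single optical session, so the dependence of the absolute
#' signal level on total duplex is informative and is kept). With
#' `backgroundPerTrace = TRUE` each trace instead gets a free background;
#' total-duplex conservation then makes the free-duplex response
#' unidentifiable, so only response increments of the bound species are
#' fitted and the concentration dependence of the level is absorbed — Ka
#' rests on the kinetic shapes alone and is correspondingly less well
#' determined.
#'
#' @param traceset a [TraceSet-class] (>= 2 traces at distinct
#'   concentrations for a two-step mechanism).
#' @param scheme candidate [KineticScheme-class]; its rate constant values
#'   are ignored except as one multi-start seed.
#' @param window optional upper time bound (s) of data to fit (stepwise
#'   selection truncates here).
#' @param nStarts number of seeded starting points (default 5); the best
#'   final SSR is kept.
#' @param seed integer seed for start generation.
#' @param speciesMap names of the scheme species receiving the per-trace
#'   enzyme and duplex totals.
#' @param backgroundPerTrace free background per trace instead of one
#'   shared background (see Details).
#' @return a [FitResult-class]. Non-convergence is reported in the `status`
#'   slot with best-so-far parameters, never silently; a numerically
#'   singular Jacobian triggers a warning naming the flattest parameter
#'   combination and NA standard errors.
#' @export
globalFit <- function(traceset, scheme, window = NULL, nStarts = 5, seed = 1,
                      speciesMap = c(enzyme = "E", duplex = "S"),
                      backgroundPerTrace = FALSE) {
  stopifnot(is(traceset, "TraceSet"))
  validObject(scheme)
  nfreeSteps <- length(scheme@steps)
  if (length(traceset@traces) < 2L && nfreeSteps >= 2L) {
    stop("at least 2 traces at distinct concentrations are required for a two-step mechanism")
  }
  boundSpecies <- setdiff(scheme@species, unname(speciesMap))
  if (!length(boundSpecies)) stop("scheme has no bound species to observe")
  ## responsive species: everything carrying the duplex (the enzyme is dark)
  respSpecies <- if (backgroundPerTrace) boundSpecies
                 else c(unname(speciesMap[["duplex"]]), boundSpecies)
  times0 <- traceset@traces[[1L]]$time
  keep <- if (is.null(window)) rep(TRUE, length(times0)) else times0 <= window
  if (sum(keep) < 5L) stop("window retains fewer than 5 points")
  tt <- times0[keep]
  signals <- lapply(traceset@traces, function(tr) tr$signal[keep])
  design <- traceset@design
  kNames <- names(scheme@rateConstants)
  nfree <- length(kNames)
  bimol <- .bimolecularRates(scheme)

  residFor <- function(logk) {
    sch <- scheme
    sch@rateConstants[kNames] <- exp(logk)
    concList <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      init <- stats::setNames(c(design$enzyme[i], design$duplex[i]),
                              unname(speciesMap))
      traj <- tryCatch(integrateScheme(sch, init, tt),
                       error = function(e) NULL)
      if (is.null(traj)) return(NULL)
      concList[[i]] <- as.matrix(traj[, respSpecies, drop = FALSE])
    }
    .projectLinear(concList, signals, perTrace = backgroundPerTrace)
  }
  fn <- function(logk) {
    proj <- residFor(logk)
    if (is.null(proj)) return(rep(1e3, sum(lengths(signals))))
    proj$resid
  }

  ## multi-start: scheme values, a kobs heuristic, then seeded log-uniform draws
  starts <- list()
  if (all(scheme@rateConstants > 0)) starts[[1L]] <- log(scheme@rateConstants)
  heur <- tryCatch({
    iBig <- which.max(design$enzyme + design$duplex)
    se <- fitSingleExponential(traceset@traces[[iBig]], window = window)
    if (is.finite(se$kobs) && se$kobs > 0) {
      h <- stats::setNames(numeric(nfree), kNames)
      tot <- design$enzyme[iBig] + design$duplex[iBig]
      for (nm in kNames) {
        h[nm] <- if (nm %in% bimol) se$kobs / tot else max(se$kobs / 2, 1)
      }
      log(h)
    } else NULL
  }, error = function(e) NULL)
  if (!is.null(heur)) starts[[length(starts) + 1L]] <- heur
  nRandom <- max(0L, nStarts - length(starts))
  if (nRandom > 0) {
    draws <- withSeed(seed, matrix(stats::runif(nRandom * nfree), nRandom, nfree))
    for (r in seq_len(nRandom)) {
      s <- stats::setNames(numeric(nfree), kNames)
      for (j in seq_len(nfree)) {
        rng <- if (kNames[j] %in% bimol) log(c(1e5, 1e8)) else log(c(0.1, 1e3))
        s[j] <- rng[1L] + draws[r, j] * (rng[2L] - rng[1L])
      }
      starts[[length(starts) + 1L]] <- s
    }
  }

  ## wide positivity-preserving box in log space; keeps hill-climbing out of
  ## the degenerate fast-equilibrium region where rates diverge jointly
  lowerB <- vapply(kNames, function(nm)
    if (nm %in% bimol) log(1e3) else log(1e-5), numeric(1))
  upperB <- vapply(kNames, function(nm)
    if (nm %in% bimol) log(1e11) else log(1e6), numeric(1))

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13, ptol = 1e-13)
  for (st in starts) {
    st <- pmin(pmax(st, lowerB), upperB)
    fit <- tryCatch(minpack.lm::nls.lm(par = st, fn = fn, lower = lowerB,
                                       upper = upperB, control = ctrl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) stop("global fit failed from every starting point")

  logk <- best$par
  est <- stats::setNames(exp(logk), kNames)
  proj <- residFor(logk)
  nlin <- proj$ncol
  nobs <- sum(lengths(signals))
  npar <- as.integer(nfree + nlin)
  ssr <- sum(proj$resid^2)
  status <- if (best$info %in% 1:4) "converged" else
    sprintf("non-convergence (nls.lm info %d); best-so-far parameters reported", best$info)

  ## asymptotic SEs from the profiled Jacobian at the optimum
  se <- stats::setNames(rep(NA_real_, nfree), kNames)
  covLog <- NULL
  dof <- nobs - npar
  H <- best$hessian
  ev <- eigen(H, symmetric = TRUE, only.values = FALSE)
  if (min(ev$values) <= max(ev$values) * 1e-12) {
    flat <- ev$vectors[, which.min(ev$values)]
    worst <- kNames[order(abs(flat), decreasing = TRUE)][1:min(2L, nfree)]
    warning("singular Jacobian: the combination of ",
            paste(worst, collapse = " and "),
            " is not identifiable from this design")
  } else if (dof > 0) {
    s2 <- ssr / dof
    covLog <- solve(H) * s2
    se[] <- est * sqrt(pmax(0, diag(covLog)))  # delta method from log scale
  }

  fittedScheme <- scheme
  fittedScheme@rateConstants[kNames] <- est
  derived <- tryCatch(derivedConstants(fittedScheme), error = function(e) {
    list(K1 = NA_real_, K2 = NA_real_, Ka = NA_real_, stepConstants = NA_real_)
  })
  if (!is.null(covLog) && is.finite(derived$Ka)) {
    ## delta method for Ka on the log-rate scale
    g <- vapply(seq_len(nfree), function(j) {
      lk <- logk
      h <- 1e-6
      lk[j] <- lk[j] + h
      schUp <- scheme
      schUp@rateConstants[kNames] <- exp(lk)
      (derivedConstants(schUp)$Ka - derived$Ka) / h
    }, numeric(1))
    derived$KaSE <- sqrt(max(0, as.numeric(t(g) %*% covLog %*% g)))
  } else {
    derived$KaSE <- NA_real_
  }

  m <- length(signals)
  linNames <- if (backgroundPerTrace) {
    c(sprintf("background.%d", seq_len(m)),
      sprintf("dResponse.%s", respSpecies))
  } else {
    c("background", sprintf("response.%s", respSpecies))
  }
  residList <- split(proj$resid, rep(seq_len(m), each = length(tt)))
  new("FitResult",
      estimates = est, se = se,
      linearCoefficients = stats::setNames(proj$beta, linNames),
      ssr = ssr, nobs = as.integer(nobs), npar = npar,
      derived = derived, residuals = unname(residList),
      status = status, niter = as.integer(best$niter),
      scheme = fittedScheme,
      window = if (is.null(window)) max(tt) else window)
}

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", object@status, "in", object@niter, "iterations\n")
  est <- object@estimates
  se <- object@se
  for (nm in names(est)) {
    cat(sprintf("  %-5s = %.4g (SE %.3g)\n", nm, est[[nm]], se[[nm]]))
  }
  d <- object@derived
  cat(sprintf("  K1 = %.4g /M, K2 = %.4g, Ka = %.4g /M (SE %.3g)\n",
              d$K1, d$K2, d$Ka, d$KaSE))
  cat(sprintf("  SSR = %.4g over %d points (%d parameters), window <= %.3g s\n",
              object@ssr, object@nobs, object@npar, object@window))
})

## extra-sum-of-squares F test of nested least-squares fits
.extraSSFTest <- function(fitSmall, fitBig) {
  df1 <- fitBig@npar - fitSmall@npar
  df2 <- fitBig@nobs - fitBig@npar
  if (df1 <= 0 || df2 <= 0 || fitBig@ssr <= 0) {
    return(list(fstat = NA_real_, pvalue = NA_real_))
  }
  f <- ((fitSmall@ssr - fitBig@ssr) / df1) / (fitBig@ssr / df2)
  list(fstat = f, pvalue = stats::pf(f, df1, df2, lower.tail = FALSE))
}

.aic <- function(fit) fit@nobs * log(fit@ssr / fit@nobs) + 2 * (fit@npar + 1)

#' Default candidate mechanisms for selection
#'
#' One and two reversible binding stages, ordered by step count. Rate values
#' are placeholders used only as one multi-start seed.
#'
#' @return list of [KineticScheme-class] candidates.
#' @export
defaultCandidates <- function() {
  list(
    oneStepBindingScheme(1e6, 10),
    twoStepBindingScheme(1e6, 10, 10, 10)
  )
}

#' Stepwise selection of the minimal kinetic mechanism
#'
#' Implements stepwise model expansion over a growing time window: fitting
#' starts on the initial part of the curves (which a single-exponential
#' stage describes), and the fitted time range is expanded step by step; at
#' each window the current candidate is compared with the next larger one by
#' the extra-sum-of-squares F test, and a step is added to the mechanism
#' only when the smaller model is rejected (p < `alpha`). The procedure
#' terminates when the full window is fit without a further rejection; the
#' chosen mechanism is the smallest candidate not rejected.
#'
#' @param traceset a [TraceSet-class].
#' @param candidates list of candidate schemes ordered by step count
#'   (default [defaultCandidates()]).
#' @param windows increasing upper time bounds (s); the last one should span
#'   the full traces.
#' @param alpha rejection level of the F test (default 0.01).
#' @param nStarts,seed multi-start settings passed to [globalFit()].
#' @return a [SelectionReport-class]. AIC is reported alongside the F
#'   statistics in the `history` slot. If the residuals of the final chosen
#'   fit stay far above the noise floor, the flag
#'   `"noSatisfactoryScheme"` is set.
#' @export
selectMechanism <- function(traceset, candidates = defaultCandidates(),
                            windows = c(0.05, 1), alpha = 0.01,
                            nStarts = 3, seed = 1) {
  stopifnot(length(candidates) >= 1L, !is.unsorted(windows, strictly = TRUE))
  flags <- character(0)

  ## zero-amplitude screen: compare per-trace variability to the noise floor
  noise <- mean(vapply(traceset@traces, function(tr) {
    stats::sd(diff(tr$signal)) / sqrt(2)
  }, numeric(1)))
  amp <- max(vapply(traceset@traces, function(tr) {
    sm <- stats::filter(tr$signal, rep(1 / 15, 15), sides = 2)
    diff(range(sm, na.rm = TRUE))
  }, numeric(1)))
  if (!is.finite(amp) || amp < 3 * noise) flags <- c(flags, "zeroAmplitude")

  cur <- 1L
  hist <- list()
  fits <- list()
  for (w in windows) {
    fitCur <- globalFit(traceset, candidates[[cur]], window = w,
                        nStarts = nStarts, seed = seed)
    fits[[cur]] <- fitCur
    hist[[length(hist) + 1L]] <- data.frame(
      window = w, candidate = cur, npar = fitCur@npar, ssr = fitCur@ssr,
      aic = .aic(fitCur), fstat = NA_real_, pvalue = NA_real_,
      decision = "fit")
    while (cur < length(candidates)) {
      fitNext <- globalFit(traceset, candidates[[cur + 1L]], window = w,
                           nStarts = nStarts, seed = seed)
      fits[[cur + 1L]] <- fitNext
      ft <- .extraSSFTest(fitCur, fitNext)
      reject <- is.finite(ft$pvalue) && ft$pvalue < alpha &&
        fitNext@ssr < fitCur@ssr
      hist[[length(hist) + 1L]] <- data.frame(
        window = w, candidate = cur + 1L, npar = fitNext@npar,
        ssr = fitNext@ssr, aic = .aic(fitNext),
        fstat = ft$fstat, pvalue = ft$pvalue,
        decision = if (reject) "smaller model rejected" else "smaller model retained")
      if (reject) {
        cur <- cur + 1L
        fitCur <- fitNext
      } else break
    }
  }

  ## absolute lack-of-fit screen on the final chosen fit
  rms <- sqrt(fitCur@ssr / fitCur@nobs)
  if (is.finite(noise) && noise > 0 && rms > 3 * noise) {
    flags <- c(flags, "noSatisfactoryScheme")
  }
  if (any(!is.finite(fitCur@se))) flags <- c(flags, "unidentifiedParameters")

  new("SelectionReport",
      history = do.call(rbind, hist),
      chosen = cur,
      fits = fits,
      flags = flags)
}

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport: chosen candidate", object@chosen, "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  print(object@history, row.names = FALSE)
})

#' Tabulate and compare fitted conditions
#'
#' Collects the stepwise and overall binding constants of several fitted
#' conditions and forms all pairwise ratios of the overall association
#' constants (row / column).
#'
#' @param fitResults named list of [FitResult-class] objects, one per duplex
#'   condition.
#' @return list with `constants` (data.frame: condition, K1, K2, Ka, KaSE)
#'   and `kaRatios` (square matrix; NULL for a single condition).
#' @export
compareConditions <- function(fitResults) {
  stopifnot(length(fitResults) >= 1L, !is.null(names(fitResults)))
  tab <- do.call(rbind, lapply(names(fitResults), function(nm) {
    d <- fitResults[[nm]]@derived
    data.frame(condition = nm, K1 = d$K1, K2 = d$K2, Ka = d$Ka,
               KaSE = if (!is.null(d$KaSE)) d$KaSE else NA_real_)
  }))
  ratios <- NULL
  if (nrow(tab) >= 2L) {
    ratios <- outer(tab$Ka, tab$Ka, "/")
    dimnames(ratios) <- list(tab$condition, tab$condition)
  }
  list(constants = tab, kaRatios = ratios)
}
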
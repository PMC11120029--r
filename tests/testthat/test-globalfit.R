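test_that("single-exponential fitting recovers exact and kinetic inputs", {
  ## exact self-fit
  tt <- seq(0, 1, length.out = 120)
  fit <- fitSingleExponential(tt, 1 * exp(-10 * tt) + 0.2)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$kobs, 10, tolerance = 1e-6)
  expect_equal(fit$offset, 0.2, tolerance = 1e-6)
  expect_identical(fit$flag, "ok")

  ## pseudo-first-order one-step trace: kobs = k1 E0 + k_1
  sch <- oneStepBindingScheme(1e6, 10)
  ts <- simulateTraceSet(sch, responseModel(0.1, c(S = 1e6, ES = 0.5e6)),
                         instrumentModel(nPoints = 300, noiseSd = 0),
                         data.frame(enzyme = 2e-6, duplex = 4e-8))
  fit2 <- fitSingleExponential(ts@traces[[1L]])
  expect_lt(abs(fit2$kobs / 12 - 1), 0.01)

  ## constant trace is flagged, not an error
  fit3 <- fitSingleExponential(tt, rep(0.5, length(tt)))
  expect_identical(fit3$flag, "unidentifiable")
  expect_equal(fit3$amplitude, 0)

  expect_error(fitSingleExponential(tt[1:5], tt[1:5]), "10 points")
})

test_that("noiseless global fit recovers the generating constants to 0.1%", {
  truth <- c(k1 = 5e6, k_1 = 50, k2 = 15, k_2 = 10)
  sch <- twoStepBindingScheme(truth[["k1"]], truth[["k_1"]],
                              truth[["k2"]], truth[["k_2"]])
  ts <- quickTraceSet(sch, noiseSd = 0, nPoints = 200)
  fit <- globalFit(ts, twoStepBindingScheme(1e6, 10, 10, 10),
                   nStarts = 3, seed = 1)
  expect_identical(fit@status, "converged")
  for (nm in names(truth)) {
    expect_lt(abs(fit@estimates[[nm]] / truth[[nm]] - 1), 1e-3)
  }
  expect_lt(abs(fit@derived$Ka / 2.5e5 - 1), 1e-3)
  ## SSR at the noiseless optimum is numerically zero on the signal scale
  expect_lt(fit@ssr, 1e-12)
  ## derived constants agree exactly with the mechanism algebra
  expect_identical(fit@derived$Ka, derivedConstants(fit@scheme)$Ka)
})

test_that("rescaling the response rescales SSR by c^2 and leaves rates unchanged", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  ts <- quickTraceSet(sch, seed = 8, noiseSd = 0.01, nPoints = 120)
  cfac <- 3.7
  ts2 <- ts
  ts2@traces <- lapply(ts@traces, function(tr) {
    tr$signal <- tr$signal * cfac
    tr
  })
  f1 <- suppressWarnings(globalFit(ts, twoStepBindingScheme(1e6, 10, 10, 10),
                                   nStarts = 2, seed = 1))
  f2 <- suppressWarnings(globalFit(ts2, twoStepBindingScheme(1e6, 10, 10, 10),
                                   nStarts = 2, seed = 1))
  expect_equal(f2@ssr / f1@ssr, cfac^2, tolerance = 1e-6)
  expect_equal(f2@estimates, f1@estimates, tolerance = 1e-4)
})

test_that("kinetics-free data leave only the variance about the background", {
  sch <- twoStepBindingScheme(0, 0, 0, 0)   # no kinetics at all
  ts <- simulateTraceSet(sch, responseModel(0.5), quickInstrument(100, 0.01),
                         fig4Design(), seed = 3)
  fit <- suppressWarnings(globalFit(ts, twoStepBindingScheme(1e6, 10, 10, 10),
                                    nStarts = 1, seed = 1))
  y <- unlist(lapply(ts@traces, `[[`, "signal"))
  totalVar <- sum((y - mean(y))^2)
  expect_lt(fit@ssr, totalVar * 1.0001)
  expect_gt(fit@ssr, totalVar * 0.95)
})

test_that("Ka is recovered within 15% across seeds at 1% noise, with calibrated SEs", {
  truth <- conditionFixtures()[["G/C"]]
  sch <- twoStepBindingScheme(truth$k1, truth$k_1, truth$k2, truth$k_2)
  seeds <- 1:10
  res <- vapply(seeds, function(s) {
    ts <- quickTraceSet(sch, seed = s, noiseSd = 0.01, nPoints = 150)
    fit <- suppressWarnings(globalFit(ts, twoStepBindingScheme(1e6, 10, 10, 10),
                                      nStarts = 2, seed = s))
    c(fit@derived$Ka, fit@derived$KaSE)
  }, numeric(2))
  relErr <- res[1L, ] / truth$Ka - 1
  expect_gte(sum(abs(relErr) <= 0.15), 9L)
  ## estimator is nearly unbiased at this noise level
  expect_lt(abs(mean(relErr)), 0.05)
  ## +-2 SE intervals cover the truth for most seeds
  covered <- abs(res[1L, ] - truth$Ka) <= 2 * res[2L, ]
  expect_gte(sum(covered), 8L)
})

test_that("condition comparison tabulates constants and Ka ratios", {
  mkFit <- function(K1, K2) {
    sch <- twoStepBindingScheme(K1 * 10, 10, K2 * 10, 10)
    new("FitResult",
        estimates = rateConstants(sch), se = rateConstants(sch) * NA,
        linearCoefficients = numeric(0), ssr = 0, nobs = 10L, npar = 4L,
        derived = c(derivedConstants(sch), KaSE = NA_real_),
        residuals = list(), status = "converged", niter = 1L,
        scheme = sch, window = 1)
  }
  fits <- list("oxoG/C" = mkFit(1e6, 4),              # Ka = 5e6
               "oxoG/oxoG-clamp" = mkFit(1e5, 1.5))   # Ka = 2.5e5
  cmp <- compareConditions(fits)
  expect_equal(cmp$constants$Ka, c(5e6, 2.5e5))
  expect_equal(cmp$kaRatios["oxoG/C", "oxoG/oxoG-clamp"], 20)
  expect_equal(diag(cmp$kaRatios), c(1, 1), ignore_attr = TRUE)

  single <- compareConditions(fits[1L])
  expect_null(single$kaRatios)

  same <- compareConditions(list(a = fits[[1L]], b = fits[[1L]]))
  expect_true(all(same$kaRatios == 1))
})
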
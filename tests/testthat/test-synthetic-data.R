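test_that("identical seeds give identical synthetic output, different seeds differ", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  a <- quickTraceSet(sch, seed = 5)
  b <- quickTraceSet(sch, seed = 5)
  c <- quickTraceSet(sch, seed = 6)
  expect_identical(a@traces, b@traces)
  expect_false(identical(a@traces, c@traces))

  m1 <- simulateMeltingCurve(45, noiseSd = 0.002, seed = 9)
  m2 <- simulateMeltingCurve(45, noiseSd = 0.002, seed = 9)
  expect_identical(m1@absorbance, m2@absorbance)

  t1 <- simulateTitration(addedSeries = c(0, 1e-5), Kd = 1e-7,
                          quenchEff = 0.2, seed = 3)
  t2 <- simulateTitration(addedSeries = c(0, 1e-5), Kd = 1e-7,
                          quenchEff = 0.2, seed = 3)
  expect_identical(t1, t2)

  c1 <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, times = 1:10 * 60,
                                   seed = 4)
  c2 <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, times = 1:10 * 60,
                                   seed = 4)
  expect_identical(c1@readout, c2@readout)
})

test_that("generator seeding does not disturb the caller's RNG stream", {
  set.seed(123)
  ref <- stats::runif(3)
  set.seed(123)
  invisible(simulateMeltingCurve(45, noiseSd = 0.002, seed = 77))
  expect_identical(stats::runif(3), ref)
})

test_that("the default instrument honors the 1.4 ms dead time", {
  inst <- instrumentModel()
  expect_equal(inst@deadTime, 0.0014)
  expect_equal(min(inst@times), 0.0014)
  expect_length(inst@times, 400L)
  expect_error(instrumentModel(times = c(0.001, 0.01), deadTime = 0.0014),
               "deadTime")
})

test_that("trace simulation validates the design and records ground truth", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  expect_error(quickTraceSet(sch, design = data.frame(enzyme = 0, duplex = 1e-6)),
               "> 0")
  expect_error(
    simulateTraceSet(sch, clampResponseModel(), quickInstrument(),
                     data.frame(enzyme = numeric(0), duplex = numeric(0))),
    "at least one"
  )
  ts <- quickTraceSet(sch, seed = 1)
  expect_equal(ts@groundTruth$rateConstants, rateConstants(sch))
  expect_equal(ts@groundTruth$seed, 1)
})

test_that("zero response coefficients yield a flat trace at background", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  inst <- instrumentModel(nPoints = 50, noiseSd = 0)
  ts <- simulateTraceSet(sch, responseModel(background = 0.7), inst,
                         fig4Design())
  for (tr in ts@traces) expect_true(all(tr$signal == 0.7))
})

test_that("a noiseless pseudo-first-order trace is a single exponential", {
  sch <- oneStepBindingScheme(1e6, 10)
  inst <- instrumentModel(nPoints = 200, noiseSd = 0)
  ts <- simulateTraceSet(sch, responseModel(0.1, c(S = 1e6, ES = 0.5e6)),
                         inst, data.frame(enzyme = 2e-6, duplex = 4e-8))
  tr <- ts@traces[[1L]]
  kobs <- 1e6 * 2e-6 + 10
  fit <- stats::lm(tr$signal ~ exp(-kobs * tr$time))
  expect_gt(summary(fit)$r.squared, 0.9999)
})

test_that("generated noise matches the requested level within 10%", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  des <- fig4Design()
  clean <- simulateTraceSet(sch, clampResponseModel(),
                            instrumentModel(nPoints = 300, noiseSd = 0), des)
  noisy <- simulateTraceSet(sch, clampResponseModel(),
                            instrumentModel(nPoints = 300, noiseSd = 0.01),
                            des, seed = 2)
  resid <- unlist(lapply(seq_along(des$duplex), function(i) {
    noisy@traces[[i]]$signal - clean@traces[[i]]$signal
  }))
  expect_gte(length(resid), 1000L)
  target <- 0.01 * noisy@groundTruth$fullScale
  expect_lt(abs(stats::sd(resid) / target - 1), 0.10)
})

test_that("two-state melting anchors half-pairing at tm and is monotone", {
  ## flat baselines: absorbance at tm is the midpoint 0.9
  bl <- list("260" = list(ds = c(intercept = 0.8, slope = 0),
                          ss = c(intercept = 1.0, slope = 0)),
             "330" = list(baseline = c(intercept = 0, slope = 0)))
  cv <- simulateMeltingCurve(48, strandConc = 2e-6, baselines = bl,
                             noiseSd = 0, grid = seq(5, 95, by = 0.5))
  iTm <- which(cv@temperatures == 48)
  expect_equal(cv@absorbance[["260"]][iTm], 0.9, tolerance = 1e-9)

  theta <- meltFraction(cv@temperatures, 48, -350e3, 2e-6)
  expect_true(all(diff(theta) < 0))
  expect_gt(theta[1L], 0.999)                       # fully paired at 5 degC
  expect_equal(meltFraction(48, 48, -350e3, 2e-6), 0.5, tolerance = 1e-12)

  ## K(Tm) = 2 / strandConc reproduces theta = 1/2 in the quadratic
  Cs <- 2e-6; K <- 2 / Cs
  u <- 2 * K * Cs
  expect_equal(u / (u + 1 + sqrt(2 * u + 1)), 0.5)

  ## the 330 nm channel carries baseline only
  expect_true(all(cv@absorbance[["330"]] == 0))
  expect_error(simulateMeltingCurve(48, dH = 100), "dH")
})

test_that("titration generator reproduces the quenching limits", {
  ## no partner -> full signal
  s0 <- simulateTitration(addedSeries = 0, Kd = 1e-7, quenchEff = 0.2,
                          noiseSd = 0)
  expect_equal(s0$rel_fluorescence, 1)
  ## tight binding, equimolar -> 1 - quenchEff
  s1 <- simulateTitration(clampConc = 1e-5, addedSeries = 1e-5, Kd = 1e-15,
                          quenchEff = 0.2, noiseSd = 0)
  expect_equal(s1$rel_fluorescence, 0.8, tolerance = 1e-4)
  ## excess partner plateaus: going 10x to 20x changes the signal < 0.5%
  s2 <- simulateTitration(clampConc = 1e-5, addedSeries = c(1e-4, 2e-4),
                          Kd = 1e-7, quenchEff = 0.2, noiseSd = 0)
  expect_lt(abs(diff(s2$rel_fluorescence)), 0.005)
  expect_error(simulateTitration(addedSeries = -1, Kd = 1e-7, quenchEff = 0.2),
               ">= 0")
})

test_that("cleavage generator obeys the null, saturation and ordering limits", {
  tt <- seq(60, 7200, length.out = 20)
  null <- simulateCleavageTimecourse(0, 0, 0, tt, noiseSd = 0)
  expect_true(all(null@readout == 0))

  alk <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, c(tt, 1e6),
                                    alkali = TRUE, noiseSd = 0)
  unt <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, c(tt, 1e6),
                                    alkali = FALSE, noiseSd = 0)
  expect_true(all(alk@readout >= unt@readout))
  expect_equal(utils::tail(alk@readout, 1), 0.55, tolerance = 1e-6)
  expect_equal(utils::tail(unt@readout, 1), 0.55, tolerance = 1e-6)
})
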
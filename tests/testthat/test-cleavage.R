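test_that("closed-form fractions obey the null result, conservation and limits", {
  ## kg = 0: no products ever (the clamp-opposed null result)
  null <- predictFractions(cleavageParams(0, 1e-3, 0.55), c(0, 60, 7200))
  expect_true(all(null$ap == 0))
  expect_true(all(null$nicked == 0))
  expect_true(all(null$intact == 1))

  ## intact + AP + nicked = 1 exactly for random parameters
  set.seed(17)
  for (i in 1:20) {
    p <- cleavageParams(10^runif(1, -5, -2), 10^runif(1, -5, -2),
                        runif(1))
    fr <- predictFractions(p, 10^runif(5, 0, 5))
    expect_equal(fr$intact + fr$ap + fr$nicked, rep(1, 5), tolerance = 1e-12)
  }

  ## t = 0 and t -> Inf limits of the readouts
  p <- cleavageParams(1e-3, 3e-4, 0.55)
  ro0 <- predictReadouts(p, 1e-9)
  expect_lt(ro0$alkali@readout, 1e-9)
  roInf <- predictReadouts(p, 1e7)
  expect_equal(roInf$alkali@readout, 0.55, tolerance = 1e-9)
  expect_equal(roInf$untreated@readout, 0.55, tolerance = 1e-9)
  expect_error(predictFractions(p, -1), ">= 0")
})

test_that("the kl = kg removable singularity is continuous", {
  tt <- c(10, 100, 1000, 5000)
  kg <- 1e-3
  exact <- predictFractions(cleavageParams(kg, kg, 0.6), tt)$ap
  ## evaluations straddling the singularity converge linearly onto the
  ## limit form (the model is differentiable in kl, so a relative rate
  ## perturbation of eps moves AP by O(eps), not less)
  up <- predictFractions(cleavageParams(kg, kg * (1 + 1e-8), 0.6), tt)$ap
  dn <- predictFractions(cleavageParams(kg, kg * (1 - 1e-8), 0.6), tt)$ap
  expect_equal(exact, up, tolerance = 1e-8)
  expect_equal(exact, dn, tolerance = 1e-8)
  coarse <- predictFractions(cleavageParams(kg, kg * (1 + 1e-6), 0.6), tt)$ap
  expect_equal(exact, coarse, tolerance = 1e-6)
})

test_that("closed forms reproduce ODE integration of S -> AP -> N to 1e-9", {
  set.seed(23)
  for (i in 1:8) {
    kg <- 10^runif(1, -4, -2)
    kl <- if (i <= 2) kg * (1 + 1e-7) else 10^runif(1, -4, -2)  # incl. kl ~ kg
    a <- runif(1, 0.3, 1)
    sch <- kineticScheme(
      c("S", "AP", "N"),
      list(kineticStep("S", "AP", "kg"), kineticStep("AP", "N", "kl")),
      c(kg = kg, kl = kl)
    )
    tt <- ClampKinetics:::logspace(1, 2e4, 30)
    traj <- integrateScheme(sch, c(S = a), tt, rtol = 1e-12, atol = 1e-16)
    fr <- predictFractions(cleavageParams(kg, kl, a), tt)
    expect_equal(fr$ap, traj$AP, tolerance = 1e-9)
    expect_equal(fr$nicked, traj$N, tolerance = 1e-9)
    expect_equal(fr$intact - (1 - a), traj$S, tolerance = 1e-9)
  }
})

test_that("the alkali readout dominates the untreated readout pointwise", {
  p <- cleavageParams(1e-3, 3e-4, 0.55)
  tt <- seq(0, 7200, length.out = 50)
  ro <- predictReadouts(p, tt)
  expect_true(all(ro$alkali@readout >= ro$untreated@readout))
})

test_that("lyase stimulation advances the untreated half-plateau by ~ the factor", {
  ## the exact half-plateau ratio is (ln2/kl + 1/kg) / (ln2/(f*kl) + 1/kg),
  ## which approaches the stimulation factor f from below for kl << kg
  tHalf <- function(p) {
    stats::uniroot(function(t) {
      predictReadouts(p, t)$untreated@readout - p@activeFraction / 2
    }, c(1, 1e7))$root
  }
  r <- tHalf(cleavageParams(1e-3, 1e-5, 0.55, 1)) /
       tHalf(cleavageParams(1e-3, 1e-5, 0.55, 10))
  expect_gt(r, 8)
  expect_lt(r, 10)
})

test_that("joint fitting recovers parameters exactly on noiseless readouts", {
  truth <- cleavageParams(1e-3, 3e-4, 0.55)
  tt <- seq(120, 7200, length.out = 12)
  alk <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, tt, alkali = TRUE,
                                    noiseSd = 0)
  unt <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, tt, alkali = FALSE,
                                    noiseSd = 0)
  fit <- fitCleavage(alk, unt)
  expect_lt(abs(fit@params@kg / truth@kg - 1), 1e-3)
  expect_lt(abs(fit@params@kl / truth@kl - 1), 1e-3)
  expect_lt(abs(fit@params@activeFraction / truth@activeFraction - 1), 1e-3)
})

test_that("kg is recovered within 20% under 3% densitometry noise", {
  tt <- seq(120, 7200, length.out = 12)
  relErr <- vapply(1:10, function(s) {
    alk <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, tt, alkali = TRUE,
                                      noiseSd = 0.03, seed = s)
    unt <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, tt, alkali = FALSE,
                                      noiseSd = 0.03, seed = 1000 + s)
    fit <- fitCleavage(alk, unt)
    abs(fit@params@kg / 1e-3 - 1)
  }, numeric(1))
  expect_gte(sum(relErr <= 0.20), 9L)
  expect_lt(stats::median(relErr), 0.10)
})

test_that("clamp-condition data (kg = 0) fit back to no cleavage", {
  tt <- seq(120, 7200, length.out = 12)
  ## noiseless all-zero pair: explicit null with flags
  alk0 <- simulateCleavageTimecourse(0, 0, 0, tt, alkali = TRUE, noiseSd = 0)
  unt0 <- simulateCleavageTimecourse(0, 0, 0, tt, alkali = FALSE, noiseSd = 0)
  fit0 <- fitCleavage(alk0, unt0)
  expect_equal(fit0@params@kg, 0)
  expect_true("aUnidentifiable" %in% fit0@flags)

  ## noisy null: the fitted model predicts negligible product at 2 h
  for (s in 1:3) {
    alk <- simulateCleavageTimecourse(0, 0, 0, tt, alkali = TRUE,
                                      noiseSd = 0.01, seed = s)
    unt <- simulateCleavageTimecourse(0, 0, 0, tt, alkali = FALSE,
                                      noiseSd = 0.01, seed = 100 + s)
    fit <- fitCleavage(alk, unt)
    pred <- predictReadouts(fit@params, 7200)
    expect_lt(pred$alkali@readout, 0.05)
  }
})

test_that("cleavage time courses round-trip through densitometry CSV", {
  tt <- seq(600, 7200, length.out = 8)
  alk <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, tt, alkali = TRUE,
                                    noiseSd = 0.02, seed = 2, condition = "oxoG/C")
  unt <- simulateCleavageTimecourse(1e-3, 3e-4, 0.55, tt, alkali = FALSE,
                                    noiseSd = 0.02, seed = 3, condition = "oxoG/C")
  f <- withr::local_tempfile(fileext = ".csv")
  writeCleavageCSV(list(alk, unt), f)
  back <- readCleavageCSV(f)
  expect_length(back, 2L)
  ra <- back[[which(vapply(back, slot, logical(1), "alkaliTreated"))]]
  expect_equal(ra@readout, alk@readout, tolerance = 1e-12)
})
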
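test_that("scheme construction validates species, steps and rates", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  expect_s4_class(sch, "KineticScheme")
  expect_identical(speciesNames(sch), c("E", "S", "ES", "ES*"))
  expect_length(sch@steps, 2L)

  expect_error(twoStepBindingScheme(-1, 50, 15, 10), "rate constants")
  expect_error(kineticScheme(c("A", "A"), list(), c(k = 1)), "unique")
  expect_error(
    kineticScheme("A", list(kineticStep("A", "B", "k")), c(k = 1)),
    "unknown species"
  )
  expect_error(
    kineticScheme(c("A", "B"), list(kineticStep(c("A", "A", "A"), "B", "k")),
                  c(k = 1)),
    "bimolecular"
  )
  expect_error(
    kineticScheme(c("A", "B"), list(kineticStep("A", "B", "kf", "kr")),
                  c(kf = 1)),
    "undefined rate"
  )
})

test_that("rate constant replacement is validated", {
  sch <- oneStepBindingScheme(1e6, 10)
  rateConstants(sch) <- c(k1 = 2e6)
  expect_equal(rateConstants(sch)[["k1"]], 2e6)
  expect_error(rateConstants(sch) <- c(bogus = 1), "unknown rate")
  expect_error(rateConstants(sch) <- c(k1 = -5), "rate constants")
})

test_that("compiled right-hand side obeys mass action and conservation", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  rhs <- compileRHS(sch)

  ## no free species -> no bimolecular flux into ES
  y0 <- c(E = 0, S = 0, ES = 1e-6, "ES*" = 0)
  d0 <- rhs(0, y0, NULL)[[1L]]
  expect_equal(d0[[1L]], 50 * 1e-6)  # only dissociation feeds E

  ## one-step irreversible: d[ES]/dt = k1 [E][S]
  irr <- kineticScheme(c("E", "S", "ES"),
                       list(kineticStep(c("E", "S"), "ES", "k1")),
                       c(k1 = 1e6))
  d <- compileRHS(irr)(0, c(E = 1e-6, S = 1e-6, ES = 0), NULL)[[1L]]
  expect_equal(d[[3L]], 1e-6)
  expect_equal(d[[1L]], -1e-6)

  ## conservation: every left-null vector annihilates dy/dt at random states
  laws <- conservationLaws(sch)
  expect_gte(ncol(laws), 2L)
  set.seed(42)
  for (i in 1:20) {
    y <- stats::setNames(stats::runif(4, 0, 2e-6), speciesNames(sch))
    dy <- rhs(0, y, NULL)[[1L]]
    expect_lt(max(abs(crossprod(laws, dy))), 1e-18)
  }
})

test_that("analytic Jacobian matches finite differences", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  rhs <- compileRHS(sch)
  jac <- attr(rhs, "jacobian")
  y <- c(E = 8e-7, S = 1.2e-6, ES = 3e-7, "ES*" = 1e-7)
  J <- jac(0, y, NULL)
  h <- 1e-12
  for (j in 1:4) {
    yp <- y; yp[j] <- yp[j] + h
    num <- (rhs(0, yp, NULL)[[1L]] - rhs(0, y, NULL)[[1L]]) / h
    expect_equal(unname(J[, j]), num, tolerance = 1e-5)
  }
})

test_that("all-zero rates leave every concentration constant", {
  sch <- twoStepBindingScheme(0, 0, 0, 0)
  traj <- integrateScheme(sch, c(E = 1e-6, S = 2e-6), c(0.001, 0.1, 1, 10))
  expect_true(all(traj$E == 1e-6))
  expect_true(all(traj$S == 2e-6))
  expect_true(all(traj$ES == 0))
})

test_that("trajectories conserve enzyme and DNA totals to 1e-9 relative", {
  set.seed(11)
  for (i in 1:5) {
    sch <- twoStepBindingScheme(10^runif(1, 5, 7), 10^runif(1, 0, 2),
                                10^runif(1, -1, 2), 10^runif(1, -1, 2))
    E0 <- runif(1, 0.5, 2) * 1e-6
    S0 <- runif(1, 0.5, 2) * 1e-6
    traj <- integrateScheme(sch, c(E = E0, S = S0),
                            ClampKinetics:::logspace(1e-4, 10, 100))
    Etot <- traj$E + traj$ES + traj$`ES*`
    Stot <- traj$S + traj$ES + traj$`ES*`
    expect_lt(max(abs(Etot - E0)) / E0, 1e-9)
    expect_lt(max(abs(Stot - S0)) / S0, 1e-9)
  }
})

test_that("pseudo-first-order relaxation follows A(1 - exp(-kobs t)), kobs = k1 E0 + k_1", {
  k1 <- 1e6; km1 <- 10
  E0 <- 2e-6; S0 <- 4e-8            # 50-fold enzyme excess
  kobs <- k1 * E0 + km1             # 12 /s
  sch <- oneStepBindingScheme(k1, km1)
  tt <- seq(0.001, 1, length.out = 400)
  traj <- integrateScheme(sch, c(E = E0, S = S0), tt)
  ESinf <- S0 * (k1 * E0) / (k1 * E0 + km1)
  pred <- ESinf * (1 - exp(-kobs * tt))
  expect_lt(max(abs(traj$ES - pred)) / ESinf, 0.01)
})

test_that("long-time integration reproduces the equilibrium constants to 0.1%", {
  set.seed(7)
  for (i in 1:6) {
    sch <- twoStepBindingScheme(10^runif(1, 5, 7), 10^runif(1, 0, 2),
                                10^runif(1, -1, 2), 10^runif(1, -1, 2))
    d <- derivedConstants(sch)
    eq <- integrateScheme(sch, c(E = 1e-6, S = 1.5e-6), c(1e3, 1e5),
                          rtol = 1e-11, atol = 1e-16)[2L, ]
    K1 <- eq$ES / (eq$E * eq$S)
    K2 <- eq$`ES*` / eq$ES
    expect_lt(abs(K1 / d$K1 - 1), 1e-3)
    expect_lt(abs(K2 / d$K2 - 1), 1e-3)
    expect_lt(abs(K1 * (1 + K2) / d$Ka - 1), 1e-3)
  }
})

test_that("derived constants follow the two-step equilibrium algebra", {
  d <- derivedConstants(twoStepBindingScheme(5e6, 50, 15, 10))
  expect_equal(d$K1, 1e5)
  expect_equal(d$K2, 1.5)
  expect_equal(d$Ka, 2.5e5)

  ## k2 = 0 collapses to the single-step constant
  d0 <- derivedConstants(twoStepBindingScheme(5e6, 50, 0, 10))
  expect_equal(d0$Ka, d0$K1)

  ## Ka is linear in k1
  d2 <- derivedConstants(twoStepBindingScheme(1e7, 50, 15, 10))
  expect_equal(d2$Ka, 2 * d$Ka)

  ## one-step scheme
  d1 <- derivedConstants(oneStepBindingScheme(1e6, 10))
  expect_equal(d1$Ka, 1e5)
  expect_true(is.na(d1$K2))

  expect_error(derivedConstants(twoStepBindingScheme(5e6, 0, 15, 10)),
               "equilibrium undefined")
})

test_that("relabeling a reversible step preserves the equilibrium (detailed balance)", {
  a <- kineticScheme(c("E", "S", "ES", "ES*"),
                     list(kineticStep(c("E", "S"), "ES", "k1", "k_1"),
                          kineticStep("ES", "ES*", "k2", "k_2")),
                     c(k1 = 5e6, k_1 = 50, k2 = 15, k_2 = 10))
  b <- kineticScheme(c("E", "S", "ES", "ES*"),
                     list(kineticStep(c("E", "S"), "ES", "k1", "k_1"),
                          kineticStep("ES*", "ES", "k_2", "k2")),
                     c(k1 = 5e6, k_1 = 50, k2 = 15, k_2 = 10))
  eqA <- integrateScheme(a, c(E = 1e-6, S = 1e-6), c(1e4))
  eqB <- integrateScheme(b, c(E = 1e-6, S = 1e-6), c(1e4))
  for (sp in c("E", "S", "ES", "ES*")) {
    expect_equal(eqA[[sp]], eqB[[sp]], tolerance = 1e-8)
  }
})

test_that("integration rejects invalid inputs and reports failures with context", {
  sch <- oneStepBindingScheme(1e6, 10)
  expect_error(integrateScheme(sch, c(E = 1e-6), c(1, 0.5)), "increasing")
  expect_error(integrateScheme(sch, c(E = 1e-6), c(0.1, 1), rtol = 0), "tolerances")
  expect_error(integrateScheme(sch, c(X = 1e-6), c(0.1, 1)), "unknown species")
  expect_error(integrateScheme(sch, c(E = -1e-6), c(0.1, 1)), ">= 0")
})

test_that("schemes round-trip through the plain-text serialization", {
  sch <- twoStepBindingScheme(5e6, 50, 15, 10)
  f <- withr::local_tempfile(fileext = ".txt")
  writeScheme(sch, f)
  back <- readScheme(f)
  expect_identical(speciesNames(back), speciesNames(sch))
  expect_equal(rateConstants(back), rateConstants(sch))
  expect_length(back@steps, 2L)
  expect_identical(back@steps[[1L]]$reactants, c("E", "S"))
  expect_identical(back@steps[[2L]]$kr, "k_2")

  ## irreversible step round-trips too
  irr <- kineticScheme(c("A", "B"), list(kineticStep("A", "B", "k")), c(k = 2))
  writeScheme(irr, f)
  expect_true(is.na(readScheme(f)@steps[[1L]]$kr))

  expect_error(readScheme(textConnection("A -> B ; k")), "rates")
})
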
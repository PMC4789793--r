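# Closed-form recovery models and derived quantities.

test_that("free-diffusion curve has the correct endpoints and shape", {
  geom <- bleachGeometry(w = 7.5, bleachDepth = 1)
  expect_equal(freeRecoveryCurve(0, D = 2, geom), 0)
  # complete recovery at asymptotic times
  tInf <- 1e6 * 7.5^2 / 2
  expect_lt(abs(freeRecoveryCurve(tInf, D = 2, geom) - 1), 1e-3)
  # partial bleach starts at 1 - depth
  g2 <- bleachGeometry(w = 7.5, bleachDepth = 0.6)
  expect_equal(freeRecoveryCurve(0, D = 2, g2), 0.4)
  # monotone non-decreasing and bounded by the plateau
  t <- seq(0, 200, length.out = 400)
  iN <- freeRecoveryCurve(t, D = 0.5, geom)
  expect_true(all(diff(iN) >= -1e-12))
  expect_true(all(iN <= 1 + 1e-12))
  expect_error(freeRecoveryCurve(t, D = -1, geom), class = "frapkdInvalidParameter")
  expect_error(bleachGeometry(w = -7.5), "positive")
})

test_that("free-diffusion curve matches the reaction-diffusion oracle to 1% sup-norm", {
  for (D in c(0.05, 1, 3.75, 8)) {
    for (w in c(5, 7.5, 10)) {
      geom <- bleachGeometry(w = w)
      tau <- cTwoThirds() * w^2 / D
      times <- seq(0, 2.5 * tau, length.out = 50)
      kin <- bindingKinetics(K = 0, kOff = 1, sigmaFree = 0, dFree = D)
      # generous domain so reflecting boundaries do not depress the tail
      tr <- simulateFrap(kin, geometry = geom, times = times,
                         domainLength = 20 * w, nGrid = 480L)
      an <- freeRecoveryCurve(times, D, geom)
      expect_lt(max(abs(frapIntensity(tr) - an)), 0.01,
                label = sprintf("sup-norm at D=%g w=%g", D, w))
    }
  }
})

test_that("two-exponential curve covers its degenerate and generic cases", {
  t <- seq(0, 100, by = 1)
  # A2 = 0 collapses to a single exponential
  expect_equal(twoExpCurve(t, A1 = 0.8, A2 = 0, tau1 = 5, tau2 = 50),
               1 - 0.8 * exp(-t / 5))
  expect_equal(twoExpCurve(0, 0.4, 0.3, 2, 60, plateau = 0.95), 0.25)
  y <- twoExpCurve(t, 0.5, 0.5, 2, 60)
  expect_true(all(diff(y) > 0))
  expect_error(twoExpCurve(t, 0.5, 0.5, -2, 60), class = "frapkdInvalidParameter")
  expect_error(twoExpCurve(t, -0.1, 0.5, 2, 60), class = "frapkdInvalidParameter")
})

test_that("two-thirds recovery time is exact on closed forms", {
  t <- seq(0, 120, by = 0.01)
  # single exponential with tau = 10: t(2/3) = -10 log(1/3)
  y <- 1 - exp(-t / 10)
  expect_equal(tauTwoThirds(t, intensity = y, plateau = 1),
               -10 * log(1 / 3), tolerance = 1e-4)
  # free-diffusion curve: tau = c w^2 / D by construction
  iN <- freeRecoveryCurve(t, D = 3, bleachGeometry(6))
  expect_equal(tauTwoThirds(t, intensity = iN, plateau = 1),
               cTwoThirds() * 36 / 3, tolerance = 1e-3)
  # a flat curve never converges
  expect_error(tauTwoThirds(t, intensity = rep(0.2, length(t)), plateau = 0.2),
               class = "frapkdNotConverged")
})

test_that("the dimensionless recovery constant is stable to 6 digits", {
  expect_equal(cTwoThirds(), 0.631325, tolerance = 1e-6)
})

test_that("effective diffusion recovers D for free traces and scales as w^2", {
  geom <- bleachGeometry(w = 7.5)
  t <- seq(0, 60, length.out = 600)
  iN <- freeRecoveryCurve(t, D = 3.75, geom)
  tau <- tauTwoThirds(t, intensity = iN, plateau = 1)
  expect_equal(effectiveDiffusion(tau, geom), 3.75, tolerance = 0.02)
  # doubling w at fixed tau quadruples D_E
  expect_equal(effectiveDiffusion(10, bleachGeometry(15)) /
                 effectiveDiffusion(10, bleachGeometry(7.5)), 4)
  expect_error(effectiveDiffusion(-1, geom), class = "frapkdInvalidParameter")
})

test_that("strong fast binding collapses to the effective-diffusion limit", {
  # K sigma = 150 with fast exchange: recovery behaves like free diffusion
  # with D / (1 + K sigma)
  kin <- bindingKinetics(K = 1.5, kOff = 1, sigmaFree = 100, dFree = 8)
  ks <- bindingStrength(kin)
  dEff <- 8 / (1 + ks)
  geom <- bleachGeometry(7.5)
  tauExp <- cTwoThirds() * 7.5^2 / dEff
  L <- 15 * 7.5
  times <- seq(0, 2 * tauExp, length.out = 120)
  tr <- simulateFrap(kin, geometry = geom, times = times,
                     domainLength = L, nGrid = 384L)
  plateau <- 1 - geom@w / L   # reflecting-domain mass limit
  tau <- tauTwoThirds(frapTimes(tr), intensity = frapIntensity(tr),
                      plateau = plateau)
  expect_equal(effectiveDiffusion(tau, geom), dEff, tolerance = 0.2)
})

test_that("characteristic-time predictions hold in their regimes", {
  geom <- bleachGeometry(7.5)
  # no binding centres: pure free diffusion, alpha diverges
  kin0 <- bindingKinetics(K = 0.5, kOff = 0.01, sigmaFree = 0, dFree = 8)
  ct0 <- characteristicTimes(kin0, geom)
  expect_equal(ct0$tau1, cTwoThirds() * 7.5^2 / 8)
  expect_identical(ct0$alpha, Inf)
  # K sigma = 1: equal free and bound pools
  kin1 <- bindingKinetics(K = 0.01, kOff = 0.01, sigmaFree = 100, dFree = 8)
  expect_equal(characteristicTimes(kin1, geom)$alpha, 1)
  # slow-exchange regime: adsorption-driven time and amplitude ratio agree
  # with a two-exponential fit of the simulated recovery within 30%
  kin <- bindingKinetics(K = 0.03, kOff = 1e-3, sigmaFree = 100, dFree = 8)
  ct <- characteristicTimes(kin, geom)
  expect_equal(ct$tau2, 1000)
  expect_equal(ct$alpha, 1 / 3)
  ds <- simFrapAdsorption(kin, geom, times = seq(0, 2400, by = 10),
                          nGrid = 256L)
  fit <- suppressWarnings(fitTwoExponential(ds$traces[[1]]))
  expect_equal(coef(fit)[["tau2"]], ct$tau2, tolerance = 0.3)
  expect_equal(coef(fit)[["alpha"]], ct$alpha, tolerance = 0.3)
})

test_that("alpha equals the mass-action free/bound ratio exactly", {
  for (ks in c(0.2, 1, 5, 50, 200)) {
    kin <- bindingKinetics(K = ks / 80, kOff = 0.01, sigmaFree = 80, dFree = 4)
    ss <- steadyState(kin, 100)
    expect_equal(characteristicTimes(kin)$alpha, ss$free / ss$bound,
                 tolerance = 1e-12)
  }
})

test_that("Stokes-Einstein conversion and proportionality are correct", {
  # halving viscosity doubles D
  expect_equal(stokesEinstein(3, viscosityPoise = 0.025),
               2 * stokesEinstein(3, viscosityPoise = 0.05))
  # radius giving D = 8 um^2/s at 0.05 P, 293 K is about 5.4 nm
  r <- 1.380649e-23 * 293 / (6 * pi * 0.005 * 8e-12) * 1e9
  expect_equal(r, 5.4, tolerance = 0.02)
  expect_equal(stokesEinstein(r), 8, tolerance = 1e-6)
  # hand-computed water-viscosity check: R = 2.3 nm, 0.01 P, 293 K
  dHand <- 1.380649e-23 * 293 / (6 * pi * 0.001 * 2.3e-9) * 1e12
  expect_equal(stokesEinstein(2.3, viscosityPoise = 0.01), dHand)
  expect_equal(dHand, 93.3, tolerance = 0.001)
})
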
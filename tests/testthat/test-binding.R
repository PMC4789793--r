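# Equilibrium solvers and dissociation-constant estimators.

test_that("the quadratic 1:1 equilibrium matches its limits and closed form", {
  # stoichiometric limit: Kd -> 0 gives min(N, W)
  expect_equal(binaryEquilibrium(100, 40, 1e-12)$complex, 40, tolerance = 1e-6)
  expect_equal(binaryEquilibrium(0, 40, 10)$complex, 0)
  # closed-form evaluation: N = W = 1000, Kd = 100
  eq <- binaryEquilibrium(1000, 1000, 100)
  expect_equal(eq$complex, (2100 - sqrt(2100^2 - 4e6)) / 2, tolerance = 1e-12)
  expect_equal(eq$complex, 729.84, tolerance = 1e-4)
  # mass-action residual over a parameter grid
  for (kd in c(1, 10, 100, 1000)) {
    for (nt in c(5, 50, 500)) {
      e <- binaryEquilibrium(nt, 200, kd)
      expect_lt(abs(e$freeN * e$freeW / e$complex - kd) / kd, 1e-9)
      expect_lte(e$complex, min(nt, 200) + 1e-12)
    }
  }
})

test_that("the amplitude-ratio inversion round-trips the 1:1 equilibrium", {
  # worked case: alpha from C = 729.84 at 1 uM / 1 uM gives back Kd = 100
  eq <- binaryEquilibrium(1000, 1000, 100)
  alpha <- eq$freeN / eq$complex
  expect_equal(alpha, 0.3702, tolerance = 1e-3)
  expect_equal(kdFromAmplitudeRatio(alpha, 1000, 1000), 100, tolerance = 1e-9)
  # identity over a wide Kd range and asymmetric totals
  for (kd in c(1, 10, 100, 1000, 1e4)) {
    for (tt in list(c(1000, 1000), c(500, 2000), c(2000, 300))) {
      e <- binaryEquilibrium(tt[1], tt[2], kd)
      a <- e$freeN / e$complex
      expect_equal(kdFromAmplitudeRatio(a, tt[1], tt[2]), kd,
                   tolerance = 1e-6)
    }
  }
  # no binding at all
  expect_identical(kdFromAmplitudeRatio(Inf, 1000, 1000), Inf)
  # implied complex larger than the partner pool is infeasible
  expect_error(kdFromAmplitudeRatio(1e-4, 1000, 500),
               class = "frapkdInfeasibleRatio")
  expect_error(kdFromAmplitudeRatio(-1, 1000, 1000),
               class = "frapkdInvalidParameter")
})

test_that("competition equilibrium satisfies conservation, Kd residuals and symmetry", {
  sys <- equilibriumSystem(c(W = 50, F = 50, N = 50), c(WF = 10, WN = 100))
  eq <- competitionEquilibrium(sys)
  expect_equal(eq$wf + eq$wn + eq$freeW, 50, tolerance = 1e-9 * 50)
  expect_equal(eq$wf + eq$freeF, 50, tolerance = 1e-9 * 50)
  expect_equal(eq$wn + eq$freeN, 50, tolerance = 1e-9 * 50)
  expect_lt(abs(eq$freeW * eq$freeF / eq$wf - 10) / 10, 1e-7)
  expect_lt(abs(eq$freeW * eq$freeN / eq$wn - 100) / 100, 1e-7)
  # against the brute-force residual-grid oracle
  ref <- refCompetition(50, 50, 50, 10, 100)
  expect_equal(eq$wf, ref$wf, tolerance = 1e-3)
  # no inhibitor reduces to the binary equilibrium
  eq0 <- competitionEquilibrium(
    equilibriumSystem(c(W = 30, F = 60, N = 0), c(WF = 10, WN = 100)))
  expect_equal(eq0$wf, binaryEquilibrium(60, 30, 10)$complex,
               tolerance = 1e-9)
  # symmetric competitors split the ligand equally
  eqs <- competitionEquilibrium(
    equilibriumSystem(c(W = 40, F = 25, N = 25), c(WF = 20, WN = 20)))
  expect_equal(eqs$wf, eqs$wn, tolerance = 1e-10)
})

test_that("raising the inhibitor never increases the receptor complex", {
  for (kdWN in c(10, 100, 1000)) {
    wf <- vapply(c(0, 10, 50, 200, 1000), function(nt) {
      competitionEquilibrium(equilibriumSystem(
        c(W = 50, F = 50, N = nt), c(WF = 10, WN = kdWN)))$wf
    }, numeric(1))
    expect_true(all(diff(wf) < 0))
  }
})

test_that("the Langmuir fit inverts noise-free isotherms and flags flat data", {
  x <- 10^seq(1, 3, length.out = 8)
  y <- 100 * x / (90 + x)
  fit <- fitIsotherm(x, y, nBoot = 25)
  expect_equal(fit$kd, 90, tolerance = 1e-4)
  expect_equal(fit$rmax, 100, tolerance = 1e-4)
  # half-saturation: the fitted curve passes Rmax/2 at x = Kd
  expect_equal(fit$rmax * 90 / (fit$kd + 90), fit$rmax / 2, tolerance = 1e-6)
  # fixed-Rmax mode
  expect_equal(fitIsotherm(x, y, fixedRmax = 100, nBoot = 0)$kd, 90,
               tolerance = 1e-6)
  # no curvature: concentrations far below Kd
  xf <- seq(1, 12, length.out = 6)
  yf <- 100 * xf / (5000 + xf)
  expect_warning(flat <- fitIsotherm(xf, yf + rnorm(6, 0, 1e-4), nBoot = 25),
                 "weakly identified")
  expect_true(flat$flagged)
  # preconditions
  expect_error(fitIsotherm(c(1, 2, 3), c(1, 2, 3)), class = "frapkdInvalidInput")
  expect_error(fitIsotherm(c(10, 20, 30, 40), c(1, 2, 3, 4)),
               class = "frapkdInvalidInput")
})

test_that("Langmuir recovery from noisy replicates is accurate and unbiased", {
  ds <- simCoipSeries(kd = 10, noiseSd = 0.05, nReplicates = 200, seed = 7)
  kds <- vapply(ds$data, function(d)
    fitIsotherm(d$free_nM, d$bound_nM, nBoot = 0)$kd, numeric(1))
  expect_lt(abs(kds[1] - 10) / 10, 0.3)        # single-replicate accuracy
  expect_lt(abs(mean(kds) - 10) / 10, 0.05)    # bias over 200 replicates
})

test_that("band densities convert to molar concentrations through the standards", {
  # 50 ng of a 50 kDa protein in 50 uL is 20 nM
  expect_equal(wbToConcentration(50, c(10, 30, 90), c(10, 30, 90),
                                 reactionVolumeUl = 50,
                                 molecularWeightKda = 50), 20)
  # a density equal to a standard's returns that standard's amount
  expect_equal(wbToConcentration(30, c(10, 30, 90), c(100, 300, 900) / 10,
                                 reactionVolumeUl = 100,
                                 molecularWeightKda = 25),
               30 * 1e3 / (25 * 100), tolerance = 1e-9)
  # dilution factor propagates linearly
  expect_equal(wbToConcentration(50, c(10, 30, 90), c(10, 30, 90), 50, 50,
                                 dilution = 4), 80)
  expect_warning(wbToConcentration(200, c(10, 30, 90), c(10, 30, 90), 50, 50),
                 "extrapolating")
  expect_error(wbToConcentration(50, c(10, 30, 90), c(10, 90, 30), 50, 50),
               class = "frapkdCalibrationError")
})
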
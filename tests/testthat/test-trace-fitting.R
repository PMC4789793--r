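# Trace normalisation, model fitting, model selection and pooling.

test_that("normalisation maps pre-bleach to 1 and background to 0", {
  tr <- frapTrace(0:20, c(200, 200, 125, seq(130, 200, length.out = 18)),
                  preBleachFrames = 2L)
  ntr <- normalizeTrace(tr, background = 50)
  expect_equal(frapIntensity(ntr)[1], 0.5)     # (125 - 50) / (200 - 50)
  expect_equal(frapTimes(ntr)[1], 0)           # re-zeroed at first post frame
  expect_true(isNormalized(ntr))
  # background at or above the pre-bleach mean is rejected
  expect_error(normalizeTrace(tr, background = 200), class = "frapkdInvalidInput")
  expect_error(normalizeTrace(tr, background = 250), class = "frapkdInvalidInput")
  # fewer than 2 pre-bleach frames is rejected
  tr1 <- frapTrace(0:20, c(200, rep(150, 20)), preBleachFrames = 1L)
  expect_error(normalizeTrace(tr1, background = 0), class = "frapkdInvalidInput")
})

test_that("normalisation round-trips a scaled and offset model curve", {
  t <- seq(0, 40, by = 0.5)
  iN <- freeRecoveryCurve(t, D = 2, bleachGeometry(7.5))
  raw <- frapTrace(c(-2, -1, t), c(1, 1, iN) * 180 + 40, preBleachFrames = 2L,
                   geometry = bleachGeometry(7.5))
  ntr <- normalizeTrace(raw, background = 40)
  expect_equal(frapIntensity(ntr), iN, tolerance = 1e-12)
})

test_that("the free-diffusion fit inverts its own forward model", {
  geom <- bleachGeometry(7.5)
  t <- seq(0, 60, length.out = 120)
  tr <- frapTrace(t, freeRecoveryCurve(t, 3.75, geom), geometry = geom,
                  normalized = TRUE)
  fit <- fitFreeDiffusion(tr)
  expect_equal(coef(fit)[["D"]], 3.75, tolerance = 1e-4)
  expect_equal(coef(fit)[["bleachDepth"]], 1, tolerance = 1e-4)
  # D_E equals the fitted D identically for the free model
  expect_equal(dEffective(fit), coef(fit)[["D"]], tolerance = 1e-10)
  expect_gt(rSquared(fit), 0.999999)
})

test_that("the free-diffusion fit recovers D from a zero-binding simulation", {
  kin <- bindingKinetics(K = 0, kOff = 1, sigmaFree = 0, dFree = 3.75)
  tr <- simulateFrap(kin, geometry = bleachGeometry(7.5),
                     times = seq(0, 50, by = 0.5), nGrid = 800L,
                     domainLength = 112.5)
  fit <- fitFreeDiffusion(tr)
  expect_equal(coef(fit)[["D"]], 3.75, tolerance = 0.05)
})

test_that("the two-exponential fit inverts its own forward model", {
  t <- c(seq(0, 20, by = 0.25), seq(21, 400, by = 2))
  tr <- frapTrace(t, twoExpCurve(t, 0.5, 0.5, 2, 60, plateau = 1),
                  normalized = TRUE)
  fit <- fitTwoExponential(tr)
  co <- coef(fit)
  expect_equal(co[["A1"]], 0.5, tolerance = 1e-3)
  expect_equal(co[["A2"]], 0.5, tolerance = 1e-3)
  expect_equal(co[["tau1"]], 2, tolerance = 1e-3)
  expect_equal(co[["tau2"]], 60, tolerance = 1e-3)
  expect_equal(co[["plateau"]], 1, tolerance = 1e-3)
  expect_equal(co[["alpha"]], 1, tolerance = 5e-3)
  expect_lt(co[["tau1"]], co[["tau2"]])      # ordering convention
})

test_that("the two-exponential fit reproduces an adsorption simulation", {
  kin <- bindingKinetics(K = 0.5, kOff = 0.01, sigmaFree = 100, dFree = 8)
  ds <- simFrapAdsorption(kin, bleachGeometry(7.5), nGrid = 300L)
  fit <- suppressWarnings(fitTwoExponential(ds$traces[[1]]))
  expect_gte(rSquared(fit), 0.99)
})

test_that("a pure free-diffusion trace degenerates to a single exponential", {
  t <- seq(0, 80, by = 0.5)
  tr <- frapTrace(t, 1 - 0.9 * exp(-t / 8), normalized = TRUE)
  expect_warning(fit <- fitTwoExponential(tr), "degenerate")
  expect_equal(coef(fit)[["A2"]], 0)
  expect_identical(coef(fit)[["alpha"]], Inf)
})

test_that("model selection discriminates free from adsorption-hindered traces", {
  geom <- bleachGeometry(7.5)
  t <- seq(0, 60, length.out = 100)
  free <- frapTrace(t, freeRecoveryCurve(t, 3.75, geom), geometry = geom,
                    normalized = TRUE)
  expect_identical(modelSelect(free)$selected, "free")
  # slow-exchange two-component trace: two_exp must win
  t2 <- c(seq(0, 30, by = 0.5), seq(32, 1500, by = 8))
  two <- frapTrace(t2, twoExpCurve(t2, 0.3, 0.65, 6, 500), geometry = geom,
                   normalized = TRUE)
  expect_identical(modelSelect(two)$selected, "two_exp")
  # too few points to select a model
  short <- frapTrace(0:4, c(0, 0.3, 0.5, 0.6, 0.65), normalized = TRUE)
  expect_error(modelSelect(short), class = "frapkdInsufficientData")
})

test_that("fitting a trace is deterministic", {
  ds <- simFrapFree(D = 3.75, noiseSd = 0.1, seed = 11)
  f1 <- fitFreeDiffusion(ds$traces[[1]])
  f2 <- fitFreeDiffusion(ds$traces[[1]])
  expect_identical(coef(f1), coef(f2))
})

test_that("parameter recovery under noise is unbiased at the pooled level", {
  ds <- simFrapFree(D = 3.75, noiseSd = 0.15, nReplicates = 25, seed = 101)
  fits <- lapply(ds$traces, fitFreeDiffusion)
  pooled <- poolResults(fits, rep("noggin4_like", 25), statistic = "D")
  expect_equal(pooled$n, 25L)
  # pooled mean within ~3 sem of the truth
  expect_lt(abs(pooled$mean - 3.75), 3 * pooled$sem + 0.02)
  expect_gt(pooled$sd, 0)
})

test_that("pooled summaries expose spread and fold changes faithfully", {
  same <- lapply(rep(2.5, 3), fitStub)
  pooled <- poolResults(same, rep("a", 3))
  expect_equal(pooled$sd, 0)
  two <- poolResults(c(lapply(c(3.7, 3.8), fitStub),
                       lapply(c(0.118, 0.122), fitStub)),
                     c("alone", "alone", "with_partner", "with_partner"))
  fc <- foldChange(two, "alone", "with_partner")
  expect_equal(fc$ratio, 3.75 / 0.12, tolerance = 1e-9)
  expect_error(poolResults(list(fitStub(1)), "only_one"),
               class = "frapkdInvalidInput")
  expect_error(foldChange(two, "alone", "nope"), class = "frapkdInvalidInput")
})

test_that("traces survive a CSV round trip with their sidecar", {
  ds <- simFrapFree(D = 1.5, noiseSd = 0.05, seed = 4)
  f <- file.path(tempdir(), "trace_roundtrip.csv")
  writeFrapTrace(ds$traces[[1]], f)
  back <- readFrapTrace(f)
  expect_equal(frapTimes(back), frapTimes(ds$traces[[1]]))
  expect_equal(frapIntensity(back), frapIntensity(ds$traces[[1]]))
  expect_equal(bleachWindow(back), 7.5)
  expect_true(isNormalized(back))
  expect_error(readFrapTrace(file.path(tempdir(), "nope.csv")),
               class = "frapkdIOError")
})
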
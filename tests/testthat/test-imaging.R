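# Drift registration, trace extraction, calibration and diffusion paths.

rollM <- function(m, dr, dc) {
  d <- dim(m)
  m[((seq_len(d[1]) - 1 - dr) %% d[1]) + 1,
    ((seq_len(d[2]) - 1 - dc) %% d[2]) + 1]
}

test_that("registration recovers integer and subpixel translations", {
  img <- matrix(0.05, 64, 64)
  img[20:40, 28:36] <- 1
  arr <- array(0, c(64, 64, 3))
  arr[, , 1] <- img
  arr[, , 2] <- img                     # identical frame: zero shift
  arr[, , 3] <- rollM(img, 3, -2)       # content moved +3 rows, -2 cols
  reg <- registerFrames(frameStack(arr, 0.25, 0:2))
  expect_equal(reg@shifts[2, ], c(0, 0))
  expect_equal(reg@shifts[3, ], c(-3, 2))   # correction = minus the drift
  expect_equal(reg@frames[, , 3], img)      # aligned back onto frame 1
  # subpixel: smooth blob shifted by (-0.7 rows, +1.4 cols) with 5% noise
  x <- outer(rep(1, 128), 1:128); y <- t(x)
  blob <- function(dr, dc) exp(-((y - 70 - dr)^2 + (x - 60 - dc)^2) / 450)
  set.seed(21)
  arr2 <- array(0, c(128, 128, 2))
  arr2[, , 1] <- blob(0, 0) + rnorm(128^2, 0, 0.05)
  arr2[, , 2] <- blob(-0.7, 1.4) + rnorm(128^2, 0, 0.05)
  reg2 <- registerFrames(frameStack(arr2, 1, 0:1))
  expect_lt(max(abs(reg2@shifts[2, ] - c(0.7, -1.4))), 0.25)
})

test_that("registration plus extraction reproduces the rendered recovery", {
  ds <- simImageStack(driftPxPerFrame = c(1, -1), noiseSd = 0.005, seed = 3)
  reg <- registerFrames(ds$stack)
  tr <- extractIsTrace(reg, ds$segment$from, ds$segment$to, widthPx = 3L,
                       preBleachFrames = 2L)
  ntr <- normalizeTrace(tr, background = 0)
  true <- freeRecoveryCurve(frapTimes(ntr), ds$manifest$D,
                            bleachGeometry(ds$manifest$w))
  expect_lt(max(abs(frapIntensity(ntr) - true)), 0.1)
  # rigid whole-stack translation leaves the extracted trace unchanged
  arr2 <- ds$stack@frames
  for (k in seq_len(dim(arr2)[3])) arr2[, , k] <- rollM(arr2[, , k], 4, 5)
  reg2 <- registerFrames(frameStack(arr2, ds$stack@pixelSize,
                                    ds$stack@timestamps))
  ps <- ds$stack@pixelSize
  tr2 <- extractIsTrace(reg2, ds$segment$from + c(5, 4) * ps,
                        ds$segment$to + c(5, 4) * ps, widthPx = 3L,
                        preBleachFrames = 2L)
  expect_lt(max(abs(frapIntensity(tr2) - frapIntensity(tr))),
            0.01 * max(frapIntensity(tr)))
})

test_that("trace extraction validates its segment and handles uniform frames", {
  arr <- array(0.4, c(32, 32, 5))
  st <- frameStack(arr, 0.5, 0:4)
  tr <- extractIsTrace(st, from = c(4, 4), to = c(4, 11))
  expect_equal(frapIntensity(tr), rep(0.4, 5))
  expect_equal(bleachWindow(tr), 7)
  expect_error(extractIsTrace(st, from = c(4, 4), to = c(4, 4)),
               class = "frapkdInvalidInput")
  expect_error(extractIsTrace(st, from = c(100, 100), to = c(120, 120)),
               class = "frapkdInvalidInput")
})

test_that("image stacks survive a TIFF round trip", {
  ds <- simImageStack(nFrames = 5L, seed = 8)
  f <- file.path(tempdir(), "stack_roundtrip.tif")
  writeFrameStack(ds$stack, f)
  back <- readFrameStack(f, pixelSize = ds$stack@pixelSize,
                         timestamps = ds$stack@timestamps)
  expect_equal(dim(back@frames), dim(ds$stack@frames))
  # 16-bit quantisation error only
  expect_lt(max(abs(back@frames - pmin(pmax(ds$stack@frames, 0), 1))),
            1 / 65535 + 1e-9)
})

test_that("calibration inverts exactly on linear standards", {
  cal <- calibrationCurve(c(0, 1, 2, 5), 10 + 100 * c(0, 1, 2, 5))
  expect_equal(cal@slope, 100)
  expect_equal(intensityToConcentration(cal, 10), 0)          # blank
  expect_equal(intensityToConcentration(cal, 210), 2)         # a standard
  expect_equal(intensityToConcentration(cal, 260), 2.5)       # interpolation
  expect_warning(intensityToConcentration(cal, 10 + 100 * 8),
                 "extrapolating")
  expect_error(calibrationCurve(c(0, 1, 2), c(5, 30, 20)),
               class = "frapkdCalibrationError")
  # generator round trip
  ds <- simCalibration(slope = 80, intercept = 5, noiseSd = 0)
  cal2 <- calibrationCurve(ds$data$conc_uM, ds$data$intensity)
  expect_equal(intensityToConcentration(cal2, 5 + 80 * 1.7), 1.7,
               tolerance = 1e-9)
})

test_that("diffusion paths match analytic crossings and detect asymmetry", {
  n <- 101
  rr <- sqrt(outer((0:100 - 50)^2, rep(1, n)) +
             t(outer((0:100 - 50)^2, rep(1, n))))
  theta <- seq(0, 2 * pi, length.out = 33)[-33]
  poly <- cbind(50 + 10 * sin(theta), 50 + 10 * cos(theta))
  # flat background outside the graft: DP = 0 everywhere
  flat <- matrix(0.1, n, n); flat[rr <= 10] <- 1
  dpFlat <- diffusionPath(flat, c(50, 50), poly, backgroundLevel = 0.1,
                          pixelSize = 0.5)
  expect_true(all(dpFlat$dp_um < 1))
  # radially symmetric exponential halo: equal rays at the analytic distance
  halo <- 0.02 + 0.9 * exp(-pmax(rr - 10, 0) / 8)
  dp <- diffusionPath(halo, c(50, 50), poly, backgroundLevel = 0.1,
                      pixelSize = 0.5)
  analytic <- 8 * log(0.9 / (0.1 - 0.02)) * 0.5
  expect_equal(dp$mean_um, analytic, tolerance = 0.02)
  expect_lt(dp$sd_um, 0.05)
  expect_false(any(dp$censored))
  # asymmetric halo: per-ray DPs differ, mean matches a finer pixel walk
  xk <- outer(rep(1, n), 0:100) - 50
  haloA <- 0.02 + 0.9 * exp(-pmax(rr - 10, 0) / ifelse(xk > 0, 12, 5))
  dpA <- diffusionPath(haloA, c(50, 50), poly, backgroundLevel = 0.1,
                       pixelSize = 0.5)
  expect_gt(max(dpA$dp_um) / min(dpA$dp_um), 1.5)
  fine <- diffusionPath(haloA, c(50, 50), poly, backgroundLevel = 0.1,
                        pixelSize = 0.5, stepPx = 0.05)
  expect_equal(dpA$mean_um, fine$mean_um, tolerance = 0.05)
  # rotation equivariance: rotating the scene by 90 deg relabels the rays
  halo90 <- t(haloA)[n:1, ]   # 90 degree rotation of the image
  dp90 <- diffusionPath(halo90, c(50, 50), poly, backgroundLevel = 0.1,
                        pixelSize = 0.5, nRays = 4L)
  dp4 <- diffusionPath(haloA, c(50, 50), poly, backgroundLevel = 0.1,
                       pixelSize = 0.5, nRays = 4L)
  expect_equal(sort(dp90$dp_um), sort(dp4$dp_um), tolerance = 0.05)
})

test_that("a halo that never decays is censored with a warning", {
  img <- matrix(0.9, 64, 64)
  theta <- seq(0, 2 * pi, length.out = 17)[-17]
  poly <- cbind(32 + 8 * sin(theta), 32 + 8 * cos(theta))
  expect_warning(dp <- diffusionPath(img, c(32, 32), poly,
                                     backgroundLevel = 0.1),
                 "censored")
  expect_true(all(dp$censored))
  expect_true(is.na(dp$mean_um))
})
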
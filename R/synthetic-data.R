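## Seeded generators for every input the analysis consumes.
##
## Replicate k of a generation call runs under a child seed derived
## deterministically from (seed, k), so any subset of replicates is
## reproducible on its own. Noise is multiplicative Gaussian throughout
## (typical confocal intensity noise; 10-15% in vivo).

.childSeed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% .Machine$integer.max)

.mnoise <- function(y, noiseSd) {
  if (noiseSd < 0)
    .frapkdStop("frapkdInvalidParameter", "'noiseSd' must be >= 0")
  if (noiseSd == 0) return(y)
  y * (1 + rnorm(length(y), 0, noiseSd))
}

# default post-bleach sampling: 1 pre-bleach + nFrames frames over
# horizon = mult * tau_{2/3}, evenly spaced (short single-IS acquisition)
.defaultTimes <- function(tau, nFrames = 100L, mult = 10)
  seq(0, mult * tau, length.out = nFrames + 1L)

#' Synthetic free-diffusion FRAP traces
#'
#' Noise-free traces come straight from the analytic forward model
#' [freeRecoveryCurve()]; multiplicative Gaussian noise is added per
#' replicate under a deterministic child seed.
#'
#' @param D ground-truth diffusion coefficient, um^2/s.
#' @param geometry a [BleachGeometry-class].
#' @param times post-bleach sampling times, s; default 101 frames over ten
#'   two-thirds-recovery times.
#' @param noiseSd multiplicative noise fraction.
#' @param nReplicates number of traces.
#' @param seed generation seed.
#' @return List with `traces` (list of normalized [FrapTrace-class]) and
#'   `manifest` (true parameters).
#' @examples
#' ds <- simFrapFree(D = 3.75, noiseSd = 0.1, nReplicates = 3, seed = 7)
#' fitFreeDiffusion(ds$traces[[1]])
#' @export
simFrapFree <- function(D = 3.75, geometry = bleachGeometry(), times = NULL,
                        noiseSd = 0, nReplicates = 1L, seed = 1L) {
  .assertScalar(D, "D")
  if (is.null(times))
    times <- .defaultTimes(.tauTwoThirdsFree(D, geometry@w))
  pure <- freeRecoveryCurve(times, D, geometry)
  traces <- lapply(seq_len(nReplicates), function(k) {
    set.seed(.childSeed(seed, k))
    frapTrace(times, .mnoise(pure, noiseSd), preBleachFrames = 0L,
              geometry = geometry, normalized = TRUE,
              meta = list(kind = "frap_free", trueD = D, replicate = k,
                          noiseSd = noiseSd))
  })
  list(traces = traces,
       manifest = list(kind = "frap_free", D = D, w = geometry@w,
                       bleachDepth = geometry@bleachDepth, noiseSd = noiseSd,
                       nReplicates = nReplicates, seed = seed))
}

#' Synthetic adsorption-hindered FRAP traces
#'
#' Ground truth comes from the reaction-diffusion simulator
#' [simulateFrap()]; noise is added per replicate as in [simFrapFree()].
#'
#' @param kinetics a [BindingKinetics-class].
#' @param geometry a [BleachGeometry-class].
#' @param times sampling times, s; the default covers the fast
#'   (diffusion-driven) and slow (adsorption-driven) phases.
#' @param nGrid oracle grid cells.
#' @param domainLength simulated IS length, um.
#' @param noiseSd,nReplicates,seed as in [simFrapFree()].
#' @return List with `traces` and `manifest`.
#' @export
simFrapAdsorption <- function(kinetics, geometry = bleachGeometry(),
                              times = NULL, nGrid = 400L,
                              domainLength = 10 * geometry@w, noiseSd = 0,
                              nReplicates = 1L, seed = 1L) {
  validObject(kinetics)
  ct <- characteristicTimes(kinetics, geometry)
  if (is.null(times)) {
    early <- seq(0, 5 * min(ct$tau1, ct$tau2), length.out = 121L)
    late <- seq(0, 3 * max(ct$tau1, ct$tau2), length.out = 121L)
    times <- sort(unique(round(c(early, late), 6)))
  }
  base <- simulateFrap(kinetics, geometry = geometry, times = times,
                       nGrid = nGrid, domainLength = domainLength)
  pure <- frapIntensity(base)
  traces <- lapply(seq_len(nReplicates), function(k) {
    set.seed(.childSeed(seed, k))
    frapTrace(times, .mnoise(pure, noiseSd), preBleachFrames = 0L,
              geometry = geometry, normalized = TRUE,
              meta = list(kind = "frap_adsorption", replicate = k,
                          noiseSd = noiseSd, predicted = ct))
  })
  list(traces = traces,
       manifest = list(kind = "frap_adsorption", kOn = kinetics@kOn,
                       kOff = kinetics@kOff, sigmaFree = kinetics@sigmaFree,
                       dFree = kinetics@dFree,
                       bindingStrength = bindingStrength(kinetics),
                       predicted = ct, w = geometry@w, noiseSd = noiseSd,
                       nReplicates = nReplicates, seed = seed))
}

#' Synthetic in-vivo binding-partner FRAP experiment
#'
#' Emulates the in-vivo affinity measurement: a fast-diffusing labelled
#' tracer whose binding partner is quasi-immobile (adsorbed on the
#' intercellular matrix). The free-partner concentration at mass-action
#' equilibrium of the stated totals and ground-truth Kd supplies the
#' binding-centre concentration of the reaction-diffusion simulation; the
#' returned traces feed [fitTwoExponential()] +
#' [kdFromAmplitudeRatio()].
#'
#' @param kd ground-truth dissociation constant, nM.
#' @param nTotal labelled-tracer total, nM (the in-vivo calibration puts
#'   both at about 1 uM).
#' @param wTotal quasi-immobile partner total, nM.
#' @param dFree tracer free diffusivity, um^2/s.
#' @param kOff dissociation rate of the complex, 1/s. The default (2e-4/s)
#'   puts the adsorption-driven time two orders of magnitude above the
#'   diffusion-driven time, the separation the amplitude-ratio inversion
#'   assumes; with faster exchange the slow exponential absorbs part of
#'   the diffusion tail and the method under-reports the affinity (it is
#'   an upper-bound method).
#' @param geometry,times,nGrid,domainLength,noiseSd,nReplicates,seed as in
#'   [simFrapAdsorption()]. The default sampling is one frame every 30 s
#'   out to 2.4 adsorption-driven times.
#' @return List with `traces` and `manifest` (including the true amplitude
#'   ratio `alphaTrue`).
#' @export
simFrapBindingPartner <- function(kd = 90, nTotal = 1000, wTotal = 1000,
                                  dFree = 3.8, kOff = 2e-4,
                                  geometry = bleachGeometry(), times = NULL,
                                  nGrid = 384L,
                                  domainLength = 15 * geometry@w,
                                  noiseSd = 0, nReplicates = 1L, seed = 1L) {
  .assertScalar(kd, "kd")
  eq <- binaryEquilibrium(nTotal, wTotal, kd)
  kin <- bindingKinetics(K = 1 / kd, kOff = kOff, sigmaFree = eq$freeW,
                         dFree = dFree)
  if (is.null(times)) times <- seq(0, 2.4 / kOff, by = 30)
  ds <- simFrapAdsorption(kin, geometry, times = times, nGrid = nGrid,
                          domainLength = domainLength, noiseSd = noiseSd,
                          nReplicates = nReplicates, seed = seed)
  for (k in seq_along(ds$traces))
    ds$traces[[k]]@meta$kind <- "frap_quasi_immobile_partner"
  ds$manifest <- c(list(kind = "frap_quasi_immobile_partner", trueKd = kd,
                        nTotal = nTotal, wTotal = wTotal,
                        alphaTrue = eq$freeN / eq$complex,
                        sigmaFree = eq$freeW),
                   ds$manifest[setdiff(names(ds$manifest), "kind")])
  ds
}

#' Synthetic equilibrium binding isotherms (SPR-style)
#'
#' Langmuir 1:1 responses `R = Rmax c / (Kd + c)` at the given analyte
#' concentrations, with multiplicative Gaussian noise per replicate.
#'
#' @param kd ground-truth Kd, nM.
#' @param rmax saturation response.
#' @param conc analyte concentrations, nM; default 8 points log-spaced
#'   over 10-1000 nM.
#' @param noiseSd,nReplicates,seed as elsewhere.
#' @return List with `data` (list of data.frames `conc_nM`, `response`)
#'   and `manifest`.
#' @export
simIsotherm <- function(kd = 90, rmax = 100,
                        conc = 10^seq(1, 3, length.out = 8), noiseSd = 0.05,
                        nReplicates = 1L, seed = 1L) {
  .assertScalar(kd, "kd"); .assertScalar(rmax, "rmax")
  pure <- rmax * conc / (kd + conc)
  data <- lapply(seq_len(nReplicates), function(k) {
    set.seed(.childSeed(seed, k))
    data.frame(conc_nM = conc, response = .mnoise(pure, noiseSd))
  })
  list(data = data,
       manifest = list(kind = "spr", kd = kd, rmax = rmax, conc = conc,
                       noiseSd = noiseSd, nReplicates = nReplicates,
                       seed = seed))
}

#' Synthetic quantitative co-immunoprecipitation dilution series
#'
#' Gradually decreasing ligand totals are added to a fixed amount of the
#' immobilised binder; bound and free ligand concentrations follow the
#' exact quadratic 1:1 equilibrium, and multiplicative noise is applied to
#' the measured bound fraction.
#'
#' @param kd ground-truth Kd, nM.
#' @param binderTotal immobilised binder total, nM.
#' @param ligandTotals ligand totals of the dilution series, nM; default a
#'   2-fold series from 500 nM down.
#' @param noiseSd,nReplicates,seed as elsewhere.
#' @return List with `data` (list of data.frames `free_nM`, `bound_nM`)
#'   and `manifest`.
#' @export
simCoipSeries <- function(kd = 10, binderTotal = 20,
                          ligandTotals = 500 / 2^(0:8), noiseSd = 0.1,
                          nReplicates = 1L, seed = 1L) {
  .assertScalar(kd, "kd"); .assertScalar(binderTotal, "binderTotal")
  eq <- t(vapply(ligandTotals, function(w) {
    e <- binaryEquilibrium(binderTotal, w, kd)
    c(free = e$freeW, bound = e$complex)
  }, numeric(2)))
  data <- lapply(seq_len(nReplicates), function(k) {
    set.seed(.childSeed(seed, k))
    data.frame(free_nM = eq[, "free"],
               bound_nM = .mnoise(eq[, "bound"], noiseSd))
  })
  list(data = data,
       manifest = list(kind = "isotherm", kd = kd,
                       binderTotal = binderTotal,
                       ligandTotals = ligandTotals, noiseSd = noiseSd,
                       nReplicates = nReplicates, seed = seed))
}

#' Synthetic fluorescence calibration series
#'
#' Linear intensity-vs-concentration standards with a blank, from a known
#' line.
#'
#' @param slope,intercept true calibration line.
#' @param conc standard concentrations, uM (a blank at 0 is prepended if
#'   absent).
#' @param noiseSd,seed as elsewhere.
#' @return List with `data` (data.frame `conc_uM`, `intensity`) and
#'   `manifest`.
#' @export
simCalibration <- function(slope = 100, intercept = 10,
                           conc = c(0, 0.5, 1, 2, 5), noiseSd = 0,
                           seed = 1L) {
  if (min(conc) > 0) conc <- c(0, conc)
  set.seed(.childSeed(seed, 1L))
  intensity <- intercept + slope * conc
  if (noiseSd > 0)
    intensity <- intensity + rnorm(length(conc), 0, noiseSd * max(intensity))
  list(data = data.frame(conc_uM = conc, intensity = intensity),
       manifest = list(kind = "calibration", slope = slope,
                       intercept = intercept, noiseSd = noiseSd, seed = seed))
}

# analytic two-cell scene: two dim cell bodies (with fixed granular
# texture so drift is identifiable in both axes) separated by a bright
# vertical IS line at column x0 (um), whose bleached segment recovers per
# the free model; coordinates in um, 0-based
.renderScene <- function(nrow, ncol, pixelSize, x0, segRows, t, D, w,
                         drift = c(0, 0), texture = NULL) {
  rows <- (seq_len(nrow) - 1) * pixelSize - drift[1]
  cols <- (seq_len(ncol) - 1) * pixelSize - drift[2]
  img <- matrix(0.25, nrow, ncol)            # cytoplasm of the two cells
  if (!is.null(texture)) {
    for (j in seq_len(nrow(texture))) {
      g <- outer(rows - texture[j, 1], cols - texture[j, 2],
                 function(r, c) exp(-(r^2 + c^2) / (2 * texture[j, 4]^2)))
      img <- img + texture[j, 3] * g
    }
  }
  lineCols <- which(abs(cols - x0) <= 1.5 * pixelSize)
  if (length(lineCols)) {
    lineI <- rep(0.9, nrow)
    inSeg <- rows >= segRows[1] & rows <= segRows[2]
    if (t >= 0 && any(inSeg)) {
      rec <- freeRecoveryCurve(max(t, 0), D, bleachGeometry(w = w))
      lineI[inSeg] <- 0.9 * rec
    }
    img[, lineCols] <- matrix(rep(lineI, length(lineCols)), nrow)
  }
  img
}

#' Synthetic drifting two-cell image stack
#'
#' Renders a pair of dim cells separated by a bright intercellular line
#' with a bleached segment that recovers by free diffusion, under a
#' constant per-frame drift, for testing registration and trace
#' extraction end to end.
#'
#' @param D true diffusion coefficient, um^2/s.
#' @param nFrames post-bleach frames.
#' @param preBleachFrames leading frames rendered before the bleach.
#' @param frameInterval s between frames.
#' @param pixelSize um per pixel.
#' @param size frame size, px (square).
#' @param w bleached-segment length, um.
#' @param driftPxPerFrame (row, col) drift per frame, px.
#' @param noiseSd additive Gaussian noise (fraction of full scale).
#' @param seed generation seed.
#' @return List with `stack` (raw, drifting [FrameStack-class]),
#'   `segment` (endpoints `from`/`to`, um, in the first frame) and
#'   `manifest`.
#' @export
simImageStack <- function(D = 3.75, nFrames = 40L, preBleachFrames = 2L,
                          frameInterval = 0.5,
                          pixelSize = 0.25, size = 96L, w = 7.5,
                          driftPxPerFrame = c(0.2, -0.3), noiseSd = 0.01,
                          seed = 1L) {
  set.seed(.childSeed(seed, 1L))
  fov <- size * pixelSize
  x0 <- fov / 2
  segRows <- c((fov - w) / 2, (fov + w) / 2)
  nTot <- nFrames + preBleachFrames
  times <- (seq_len(nTot) - 1L - preBleachFrames) * frameInterval
  # fixed granular texture (vesicles/yolk platelets) riding with the tissue
  nSpots <- 30L
  texture <- cbind(runif(nSpots, 0, fov), runif(nSpots, 0, fov),
                   runif(nSpots, 0.05, 0.25), runif(nSpots, 0.5, 1.5))
  arr <- array(0, dim = c(size, size, nTot))
  for (k in seq_len(nTot)) {
    drift <- (k - 1) * driftPxPerFrame * pixelSize
    img <- .renderScene(size, size, pixelSize, x0, segRows, times[k], D, w,
                        drift = drift, texture = texture)
    if (noiseSd > 0) img <- img + rnorm(length(img), 0, noiseSd)
    arr[, , k] <- img
  }
  list(stack = frameStack(arr, pixelSize, times),
       segment = list(from = c(x0, segRows[1]), to = c(x0, segRows[2])),
       manifest = list(kind = "image_stack", D = D, w = w,
                       preBleachFrames = preBleachFrames,
                       pixelSize = pixelSize,
                       driftPxPerFrame = driftPxPerFrame, noiseSd = noiseSd,
                       frameInterval = frameInterval, seed = seed))
}

#' Generate a synthetic dataset by kind
#'
#' Single seeded entry point over all generators. `kind` selects the
#' generator; `params` are passed through to it. Fixed (kind, params,
#' seed) give byte-identical output.
#'
#' @param kind one of `"frap_free"`, `"frap_adsorption"`,
#'   `"frap_quasi_immobile_partner"`, `"isotherm"`, `"spr"`,
#'   `"calibration"`, `"image_stack"`, `"gradient_scenario"`.
#' @param params named list of generator arguments.
#' @param noiseSd noise fraction (ignored by `gradient_scenario`).
#' @param nReplicates replicate count (where applicable).
#' @param seed generation seed.
#' @return The generator's list, always carrying a `manifest` of true
#'   parameters.
#' @examples
#' ds <- generateDataset("frap_free", list(D = 3.75), noiseSd = 0, seed = 1)
#' ds$manifest$D
#' @export
generateDataset <- function(kind, params = list(), noiseSd = 0,
                            nReplicates = 1L, seed = 1L) {
  common <- list(noiseSd = noiseSd, nReplicates = nReplicates, seed = seed)
  switch(kind,
    frap_free = do.call(simFrapFree, c(params, common)),
    frap_adsorption = do.call(simFrapAdsorption, c(params, common)),
    frap_quasi_immobile_partner =
      do.call(simFrapBindingPartner, c(params, common)),
    spr = do.call(simIsotherm, c(params, common)),
    isotherm = do.call(simCoipSeries, c(params, common)),
    calibration = do.call(simCalibration,
                          c(params, list(noiseSd = noiseSd, seed = seed))),
    image_stack = do.call(simImageStack,
                          c(params, list(noiseSd = noiseSd, seed = seed))),
    gradient_scenario = {
      sc <- do.call(gradientScenario, params)
      list(scenario = sc, manifest = c(list(kind = "gradient_scenario"),
                                       params, list(seed = seed)))
    },
    .frapkdStop("frapkdSpecError", sprintf("unknown dataset kind '%s'", kind))
  )
}

#' Write a generated dataset to a directory
#'
#' Traces go to `trace_<k>.csv` (+ JSON sidecars), tabular data to
#' `data_<k>.csv`, image stacks to `stack.tif`, and the manifest of true
#' parameters to `manifest.json`.
#'
#' @param dataset a list from [generateDataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(dataset$traces))
    for (k in seq_along(dataset$traces))
      writeFrapTrace(dataset$traces[[k]],
                     file.path(dir, sprintf("trace_%03d.csv", k)))
  if (!is.null(dataset$data)) {
    dl <- dataset$data
    if (is.data.frame(dl)) dl <- list(dl)
    for (k in seq_along(dl))
      write.csv(dl[[k]], file.path(dir, sprintf("data_%03d.csv", k)),
                row.names = FALSE)
  }
  if (!is.null(dataset$stack))
    writeFrameStack(dataset$stack, file.path(dir, "stack.tif"))
  man <- dataset$manifest
  man <- man[!vapply(man, is.object, logical(1))]
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
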
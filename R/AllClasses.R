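## S4 classes for the FRAP / binding / gradient data model.

#' Bleach-stripe geometry
#'
#' Geometry of the photobleached linear zone of an intercellular space:
#' the stripe length `w` (micrometres) and the fraction of fluorescence
#' removed inside the stripe at `t = 0`.
#'
#' @slot w numeric(1). Length of the bleached zone, um. The field-typical
#'   value for a single-IS experiment is 7.5 um.
#' @slot bleachDepth numeric(1). Fraction of fluorescence removed at t = 0
#'   inside the stripe, in (0, 1].
#' @aliases BleachGeometry
#' @exportClass BleachGeometry
setClass("BleachGeometry",
  slots = c(w = "numeric", bleachDepth = "numeric"),
  prototype = list(w = 7.5, bleachDepth = 1))

setValidity("BleachGeometry", function(object) {
  if (length(object@w) != 1L || !is.finite(object@w) || object@w <= 0)
    return("'w' must be a positive finite scalar (um)")
  d <- object@bleachDepth
  if (length(d) != 1L || !is.finite(d) || d <= 0 || d > 1)
    return("'bleachDepth' must be in (0, 1]")
  TRUE
})

#' @param w bleach-stripe length, um.
#' @param bleachDepth fraction of fluorescence removed at t = 0, in (0, 1].
#' @return `bleachGeometry()` returns a [BleachGeometry-class] object.
#' @examples
#' bleachGeometry(w = 7.5, bleachDepth = 1)
#' @rdname BleachGeometry-class
#' @export
bleachGeometry <- function(w = 7.5, bleachDepth = 1) {
  new("BleachGeometry", w = as.numeric(w), bleachDepth = as.numeric(bleachDepth))
}

#' Microscopic kinetics of reversible adsorption
#'
#' Rate constants of reversible binding of a diffusible tracer to immobile
#' binding centres, plus the free-species diffusivity. The binding constant
#' K = kOn/kOff (1/nM) and the dimensionless binding strength
#' K * sigmaFree are derived via [bindingConstant()] and
#' [bindingStrength()].
#'
#' @slot kOn numeric(1). Association rate constant, 1/(nM s).
#' @slot kOff numeric(1). Dissociation rate constant, 1/s.
#' @slot sigmaFree numeric(1). Concentration of free binding centres, nM.
#'   May be zero (no binding).
#' @slot dFree numeric(1). Diffusivity of the unbound species, um^2/s.
#' @aliases BindingKinetics
#' @exportClass BindingKinetics
setClass("BindingKinetics",
  slots = c(kOn = "numeric", kOff = "numeric",
            sigmaFree = "numeric", dFree = "numeric"))

setValidity("BindingKinetics", function(object) {
  for (nm in c("kOn", "kOff", "sigmaFree", "dFree")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      return(sprintf("'%s' must be a non-negative finite scalar", nm))
  }
  if (object@kOff <= 0) return("'kOff' must be positive")
  if (object@dFree < 0) return("'dFree' must be non-negative")
  TRUE
})

#' @param kOn association rate constant, 1/(nM s). Exactly one of `kOn` and
#'   `K` must be given.
#' @param kOff dissociation rate constant, 1/s.
#' @param sigmaFree concentration of free binding centres, nM.
#' @param dFree diffusivity of the unbound species, um^2/s.
#' @param K association (binding) constant kOn/kOff, 1/nM; convenience
#'   alternative to `kOn`.
#' @return `bindingKinetics()` returns a [BindingKinetics-class] object.
#' @examples
#' kin <- bindingKinetics(K = 50 / 100, kOff = 0.01, sigmaFree = 100, dFree = 8)
#' bindingStrength(kin)
#' @rdname BindingKinetics-class
#' @export
bindingKinetics <- function(kOn = NULL, kOff, sigmaFree, dFree, K = NULL) {
  if (is.null(kOn) == is.null(K))
    .frapkdStop("frapkdInvalidParameter",
                "give exactly one of 'kOn' and 'K'")
  if (is.null(kOn)) kOn <- K * kOff
  new("BindingKinetics", kOn = as.numeric(kOn), kOff = as.numeric(kOff),
      sigmaFree = as.numeric(sigmaFree), dFree = as.numeric(dFree))
}

#' A FRAP recovery trace
#'
#' Time-ordered fluorescence record of one bleach event in a single
#' intercellular space, together with the bleach geometry. Raw traces carry
#' arbitrary intensity units and pre-bleach frames; [normalizeTrace()]
#' rescales them so the pre-bleach mean maps to 1 and the background to 0,
#' and re-zeroes time at the first post-bleach frame.
#'
#' @slot time numeric. Acquisition times, s, strictly increasing.
#' @slot intensity numeric. Fluorescence, arbitrary units (or normalized).
#' @slot preBleachFrames integer(1). Number of leading pre-bleach frames.
#' @slot geometry [BleachGeometry-class].
#' @slot normalized logical(1). TRUE once [normalizeTrace()] has been applied
#'   (or for model-generated traces, which are born normalized).
#' @slot meta list. Free-form labels (protein, embryo, IS id, generator
#'   manifest, ...).
#' @aliases FrapTrace
#' @exportClass FrapTrace
setClass("FrapTrace",
  slots = c(time = "numeric", intensity = "numeric",
            preBleachFrames = "integer", geometry = "BleachGeometry",
            normalized = "logical", meta = "list"))

setValidity("FrapTrace", function(object) {
  if (length(object@time) != length(object@intensity))
    return("'time' and 'intensity' must have equal length")
  if (length(object@time) < 3L)
    return("a trace needs at least 3 frames")
  if (any(!is.finite(object@time)) || any(!is.finite(object@intensity)))
    return("non-finite values in trace")
  if (any(diff(object@time) <= 0))
    return("'time' must be strictly increasing")
  if (object@preBleachFrames < 0L ||
      object@preBleachFrames >= length(object@time))
    return("invalid 'preBleachFrames'")
  TRUE
})

#' @param time acquisition times, s.
#' @param intensity fluorescence values, same length as `time`.
#' @param preBleachFrames number of leading pre-bleach frames.
#' @param geometry a [BleachGeometry-class].
#' @param normalized logical; is the trace already normalized?
#' @param meta free-form list of labels.
#' @return `frapTrace()` returns a [FrapTrace-class] object.
#' @rdname FrapTrace-class
#' @export
frapTrace <- function(time, intensity, preBleachFrames = 0L,
                      geometry = bleachGeometry(), normalized = FALSE,
                      meta = list()) {
  new("FrapTrace", time = as.numeric(time), intensity = as.numeric(intensity),
      preBleachFrames = as.integer(preBleachFrames), geometry = geometry,
      normalized = isTRUE(normalized), meta = meta)
}

#' Result of fitting a recovery model to a FRAP trace
#'
#' @slot model character(1). `"free"` (1D free-diffusion recovery) or
#'   `"two_exp"` (two-exponential diffusion + adsorption recovery).
#' @slot coefficients named numeric. `D`, `bleachDepth` for the free model;
#'   `A1`, `A2`, `tau1`, `tau2`, `plateau`, `alpha` for the two-exponential
#'   model (`alpha = A1/A2`, weight of the fast exponent).
#' @slot tauTwoThirds numeric(1). Time to recover 2/3 of the plateau, s,
#'   from the fitted model.
#' @slot dEffective numeric(1). Effective diffusion coefficient, um^2/s.
#' @slot rSquared numeric(1). Coefficient of determination.
#' @slot residualSd numeric(1). Residual standard deviation.
#' @slot nPoints integer(1). Number of post-bleach points fitted.
#' @slot fitted numeric. Fitted intensities at the trace's time points.
#' @slot info list. Optimiser diagnostics, degeneracy flags.
#' @aliases FrapFit
#' @exportClass FrapFit
setClass("FrapFit",
  slots = c(model = "character", coefficients = "numeric",
            tauTwoThirds = "numeric", dEffective = "numeric",
            rSquared = "numeric", residualSd = "numeric",
            nPoints = "integer", fitted = "numeric", info = "list"))

setValidity("FrapFit", function(object) {
  if (!object@model %in% c("free", "two_exp"))
    return("'model' must be 'free' or 'two_exp'")
  if (length(object@rSquared) == 1L && is.finite(object@rSquared) &&
      object@rSquared > 1 + 1e-12)
    return("rSquared cannot exceed 1")
  if (is.finite(object@dEffective) && object@dEffective <= 0)
    return("dEffective must be positive")
  TRUE
})

#' Point equilibrium system of totals and dissociation constants
#'
#' Total concentrations of a ligand and its binder(s) at one spatial point,
#' with the dissociation constant of each complex. Two layouts are used:
#' 1:1 (`W`, `N`; complex `WN`) and competitive three-species
#' (`W`, `F`, `N`; complexes `WF`, `WN`) in which receptor F and inhibitor N
#' compete for ligand W.
#'
#' @slot totals named numeric, nM, non-negative.
#' @slot kds named numeric, nM, positive.
#' @aliases EquilibriumSystem
#' @exportClass EquilibriumSystem
setClass("EquilibriumSystem",
  slots = c(totals = "numeric", kds = "numeric"))

setValidity("EquilibriumSystem", function(object) {
  if (is.null(names(object@totals)) || is.null(names(object@kds)))
    return("'totals' and 'kds' must be named")
  if (any(!is.finite(object@totals)) || any(object@totals < 0))
    return("'totals' must be non-negative and finite")
  if (any(!is.finite(object@kds)) || any(object@kds <= 0))
    return("'kds' must be positive and finite")
  TRUE
})

#' @param totals named numeric vector of total concentrations, nM.
#' @param kds named numeric vector of dissociation constants, nM.
#' @return `equilibriumSystem()` returns an [EquilibriumSystem-class] object.
#' @examples
#' equilibriumSystem(c(W = 50, F = 50, N = 50), c(WF = 10, WN = 100))
#' @rdname EquilibriumSystem-class
#' @export
equilibriumSystem <- function(totals, kds) {
  new("EquilibriumSystem", totals = totals, kds = kds)
}

#' Configuration of the reaction-diffusion FRAP simulator
#'
#' @slot kinetics [BindingKinetics-class].
#' @slot geometry [BleachGeometry-class].
#' @slot domainLength numeric(1). 1D domain length, um; at least 10 bleach
#'   windows so reflecting boundaries approximate an unbounded IS.
#' @slot nGrid integer(1). Number of grid cells.
#' @slot times numeric. Output times, s, starting at 0 (bleach instant).
#' @slot dt numeric(1). Time step, s; `NA` selects a stable step
#'   automatically. An explicit value must satisfy dt <= 0.4 dx^2 / dFree.
#' @slot boundary character(1). `"reflecting"` or `"periodic"`.
#' @slot saturating logical(1). If TRUE, binding centres are depleted by
#'   complex formation (sigmaTotal finite); default FALSE treats sigmaFree
#'   as constant (linearised, far-from-saturation regime).
#' @slot sigmaTotal numeric(1). Total binding-centre concentration, nM; used
#'   only when `saturating`, in which case the pre-bleach equilibrium is the
#'   quadratic 1:1 partition of `totalLabel` against `sigmaTotal` (the
#'   kinetics' `sigmaFree` is ignored).
#' @slot totalLabel numeric(1). Total tracer concentration, nM; only
#'   meaningful in saturating mode (the linear mode is scale-free).
#' @slot bleachCenter numeric(1). Centre of the bleach window, um.
#' @aliases OracleConfig
#' @exportClass OracleConfig
setClass("OracleConfig",
  slots = c(kinetics = "BindingKinetics", geometry = "BleachGeometry",
            domainLength = "numeric", nGrid = "integer", times = "numeric",
            dt = "numeric", boundary = "character", saturating = "logical",
            sigmaTotal = "numeric", totalLabel = "numeric",
            bleachCenter = "numeric"))

setValidity("OracleConfig", function(object) {
  w <- object@geometry@w
  if (object@domainLength < 10 * w)
    return("'domainLength' must be at least 10 bleach-window lengths")
  if (object@nGrid < 32L) return("'nGrid' too small (need >= 32)")
  if (length(object@times) < 2L || object@times[1] < 0 ||
      any(diff(object@times) <= 0))
    return("'times' must be increasing and start at >= 0")
  if (!object@boundary %in% c("reflecting", "periodic"))
    return("'boundary' must be 'reflecting' or 'periodic'")
  dx <- object@domainLength / object@nGrid
  if (!is.na(object@dt)) {
    if (object@dt <= 0) return("'dt' must be positive")
    if (object@kinetics@dFree > 0 &&
        object@dt > 0.4 * dx^2 / object@kinetics@dFree + 1e-15)
      return("stability bound violated: need dt <= 0.4*dx^2/dFree")
  }
  if (object@saturating &&
      (!is.finite(object@sigmaTotal) || object@sigmaTotal <= 0 ||
       !is.finite(object@totalLabel) || object@totalLabel <= 0))
    return("'sigmaTotal' and 'totalLabel' must be positive when saturating")
  hw <- w / 2
  if (object@bleachCenter - hw < 0 ||
      object@bleachCenter + hw > object@domainLength)
    return("bleach window must lie inside the domain")
  TRUE
})

#' @param kinetics a [BindingKinetics-class].
#' @param geometry a [BleachGeometry-class].
#' @param times output time grid, s (first element 0 = bleach instant).
#' @param domainLength domain length, um (default 10 bleach windows).
#' @param nGrid number of grid cells.
#' @param dt explicit time step, s, or `NA` for automatic stable choice.
#' @param boundary `"reflecting"` or `"periodic"`.
#' @param saturating logical; deplete binding centres?
#' @param sigmaTotal total binding-centre concentration, nM (saturating mode).
#' @param totalLabel total tracer concentration, nM (saturating mode).
#' @param bleachCenter centre of the bleach window, um.
#' @return `oracleConfig()` returns an [OracleConfig-class] object.
#' @rdname OracleConfig-class
#' @export
oracleConfig <- function(kinetics, geometry = bleachGeometry(), times,
                         domainLength = 10 * geometry@w, nGrid = 400L,
                         dt = NA_real_, boundary = "reflecting",
                         saturating = FALSE, sigmaTotal = NA_real_,
                         totalLabel = 1, bleachCenter = domainLength / 2) {
  new("OracleConfig", kinetics = kinetics, geometry = geometry,
      domainLength = as.numeric(domainLength), nGrid = as.integer(nGrid),
      times = as.numeric(times), dt = as.numeric(dt), boundary = boundary,
      saturating = isTRUE(saturating), sigmaTotal = as.numeric(sigmaTotal),
      totalLabel = as.numeric(totalLabel),
      bleachCenter = as.numeric(bleachCenter))
}

#' Scenario for the ligand/receptor/inhibitor gradient model
#'
#' A posterior-to-anterior sigmoid total-ligand (Wnt8) gradient over an axis
#' of length `axisLength`, partitioned at equilibrium between a uniformly
#' distributed receptor (Frizzled8) and a uniformly distributed diffusible
#' inhibitor (Noggin4). Orientation: x = 0 is posterior (ligand maximum,
#' presumptive hind-midbrain border), x = axisLength is anterior.
#'
#' @slot axisLength numeric(1). Axis length, um.
#' @slot nPositions integer(1). Number of evaluation positions.
#' @slot wMax numeric(1). Ligand concentration at the posterior end, nM.
#' @slot midpoint numeric(1). Sigmoid midpoint, um.
#' @slot steepness numeric(1). Sigmoid steepness, 1/um.
#' @slot fTotal numeric(1). Uniform receptor total, nM.
#' @slot nTotal numeric(1). Uniform inhibitor total, nM.
#' @slot kdWF numeric(1). Ligand-receptor dissociation constant, nM.
#' @slot kdWN numeric(1). Ligand-inhibitor dissociation constant, nM.
#' @aliases GradientScenario
#' @exportClass GradientScenario
setClass("GradientScenario",
  slots = c(axisLength = "numeric", nPositions = "integer", wMax = "numeric",
            midpoint = "numeric", steepness = "numeric", fTotal = "numeric",
            nTotal = "numeric", kdWF = "numeric", kdWN = "numeric"))

setValidity("GradientScenario", function(object) {
  for (nm in c("axisLength", "wMax", "steepness", "kdWF", "kdWN")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("'%s' must be a positive finite scalar", nm))
  }
  if (object@fTotal < 0 || object@nTotal < 0)
    return("'fTotal' and 'nTotal' must be non-negative")
  if (object@nPositions < 5L) return("'nPositions' must be >= 5")
  if (object@midpoint < 0 || object@midpoint > object@axisLength)
    return("'midpoint' must lie on the axis")
  TRUE
})

#' @param axisLength axis length, um. Default 300 (midline of the anterior
#'   expression territory).
#' @param nPositions number of evaluation positions.
#' @param wMax posterior-end ligand total, nM.
#' @param midpoint sigmoid midpoint, um.
#' @param steepness sigmoid steepness, 1/um.
#' @param fTotal uniform receptor total, nM.
#' @param nTotal uniform inhibitor total, nM.
#' @param kdWF ligand-receptor Kd, nM.
#' @param kdWN ligand-inhibitor Kd, nM.
#' @return `gradientScenario()` returns a [GradientScenario-class] object.
#'   A warning is raised if the profile does not fall below 2% of `wMax`
#'   at the anterior end.
#' @examples
#' sc <- gradientScenario()
#' head(wnt8Profile(sc))
#' @rdname GradientScenario-class
#' @export
gradientScenario <- function(axisLength = 300, nPositions = 301L, wMax = 50,
                             midpoint = axisLength / 2, steepness = 0.04,
                             fTotal = 50, nTotal = 50, kdWF = 10, kdWN = 100) {
  obj <- new("GradientScenario", axisLength = as.numeric(axisLength),
             nPositions = as.integer(nPositions), wMax = as.numeric(wMax),
             midpoint = as.numeric(midpoint), steepness = as.numeric(steepness),
             fTotal = as.numeric(fTotal), nTotal = as.numeric(nTotal),
             kdWF = as.numeric(kdWF), kdWN = as.numeric(kdWN))
  wEnd <- .sigmoidW(obj@axisLength, obj)
  if (wEnd >= 0.02 * obj@wMax)
    warning(sprintf(paste0("ligand profile does not vanish at the anterior ",
                           "end: W(L) = %.3g nM (%.1f%% of wMax)"),
                    wEnd, 100 * wEnd / obj@wMax))
  obj
}

#' A registered (or raw) time-lapse image stack
#'
#' @slot frames numeric 3D array, rows x cols x time.
#' @slot pixelSize numeric(1). um per pixel.
#' @slot timestamps numeric. Acquisition times, s, one per frame.
#' @slot shifts numeric matrix (frames x 2) of applied (row, col) shifts in
#'   px; zero for an unregistered stack.
#' @aliases FrameStack
#' @exportClass FrameStack
setClass("FrameStack",
  slots = c(frames = "array", pixelSize = "numeric",
            timestamps = "numeric", shifts = "matrix"))

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("'frames' must be a 3D array (rows, cols, time)")
  if (object@pixelSize <= 0) return("'pixelSize' must be positive")
  if (length(object@timestamps) != d[3])
    return("'timestamps' must have one entry per frame")
  if (any(diff(object@timestamps) <= 0))
    return("'timestamps' must be strictly increasing")
  if (!all(dim(object@shifts) == c(d[3], 2L)))
    return("'shifts' must be a frames x 2 matrix")
  TRUE
})

#' @param frames 3D numeric array (rows, cols, time).
#' @param pixelSize um per pixel.
#' @param timestamps acquisition times, s.
#' @param shifts optional frames x 2 matrix of applied shifts (px).
#' @return `frameStack()` returns a [FrameStack-class] object.
#' @rdname FrameStack-class
#' @export
frameStack <- function(frames, pixelSize, timestamps = seq_len(dim(frames)[3]),
                       shifts = matrix(0, dim(frames)[3], 2L)) {
  new("FrameStack", frames = frames, pixelSize = as.numeric(pixelSize),
      timestamps = as.numeric(timestamps), shifts = shifts)
}

#' Linear fluorescence-to-concentration calibration
#'
#' Standards of known fluorophore concentration imaged under the microscopy
#' settings of the FRAP experiments, with a blank as the zero point, fitted
#' by a straight line (intensity = intercept + slope * concentration).
#'
#' @slot concentration numeric. Standard concentrations, uM (>= 3 points,
#'   including a blank at 0).
#' @slot intensity numeric. Mean signal density per standard.
#' @slot slope numeric(1). Fitted slope (> 0).
#' @slot intercept numeric(1). Fitted intercept.
#' @aliases CalibrationCurve
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  slots = c(concentration = "numeric", intensity = "numeric",
            slope = "numeric", intercept = "numeric"))

setValidity("CalibrationCurve", function(object) {
  if (length(object@concentration) < 3L)
    return("need at least 3 calibration standards")
  if (length(object@concentration) != length(object@intensity))
    return("'concentration' and 'intensity' must match in length")
  if (min(object@concentration) > 0)
    return("calibration requires a blank (zero-concentration) point")
  if (!is.finite(object@slope) || object@slope <= 0)
    return("calibration slope must be positive (non-monotone standards?)")
  TRUE
})

#' @param concentration standard concentrations, uM (include a blank at 0).
#' @param intensity measured mean signal density per standard.
#' @return `calibrationCurve()` returns a fitted [CalibrationCurve-class].
#' @examples
#' cal <- calibrationCurve(c(0, 1, 2, 5), c(10, 110, 210, 510))
#' intensityToConcentration(cal, 260)
#' @rdname CalibrationCurve-class
#' @export
calibrationCurve <- function(concentration, intensity) {
  o <- order(concentration)
  concentration <- as.numeric(concentration[o])
  intensity <- as.numeric(intensity[o])
  if (length(concentration) >= 3L && any(diff(intensity) <= 0))
    .frapkdStop("frapkdCalibrationError",
                "calibration standards are not monotone in intensity")
  fit <- lm(intensity ~ concentration)
  new("CalibrationCurve", concentration = concentration,
      intensity = intensity, slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]))
}
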
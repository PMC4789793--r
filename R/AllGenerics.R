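## Generics and accessors.

#' @name frapkd-accessors
#' @title Accessors for frapkd S4 classes
#' @description Small accessor generics; prefer these over direct slot
#'   access.
#' @param object an S4 object from this package.
#' @return The corresponding slot value (see individual methods).
NULL

#' @rdname frapkd-accessors
#' @export
setGeneric("frapTimes", function(object) standardGeneric("frapTimes"))
#' @rdname frapkd-accessors
#' @export
setGeneric("frapIntensity", function(object) standardGeneric("frapIntensity"))
#' @rdname frapkd-accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname frapkd-accessors
#' @export
setGeneric("bleachWindow", function(object) standardGeneric("bleachWindow"))
#' @rdname frapkd-accessors
#' @export
setGeneric("preBleachFrames", function(object) standardGeneric("preBleachFrames"))
#' @rdname frapkd-accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname frapkd-accessors
#' @export
setGeneric("traceMeta", function(object) standardGeneric("traceMeta"))
#' @rdname frapkd-accessors
#' @export
setGeneric("bindingConstant", function(object) standardGeneric("bindingConstant"))
#' @rdname frapkd-accessors
#' @export
setGeneric("bindingStrength", function(object) standardGeneric("bindingStrength"))
#' @rdname frapkd-accessors
#' @export
setGeneric("fitModel", function(object) standardGeneric("fitModel"))
#' @rdname frapkd-accessors
#' @export
setGeneric("dEffective", function(object) standardGeneric("dEffective"))
#' @rdname frapkd-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' Two-thirds recovery time
#'
#' Earliest time at which the normalized recovery
#' (I(t) - I(0)) / (plateau - I(0)) reaches 2/3. For a [FrapFit-class] the
#' plateau and the curve come from the fitted model (never from the last
#' sample); for a raw curve supply `intensity` and `plateau` explicitly.
#'
#' @param object a [FrapFit-class], or a numeric vector of times.
#' @param ... further arguments (see methods).
#' @return The two-thirds recovery time, s.
#' @seealso [effectiveDiffusion()]
#' @export
setGeneric("tauTwoThirds", function(object, ...) standardGeneric("tauTwoThirds"))

## -- FrapTrace ---------------------------------------------------------------

#' @rdname frapkd-accessors
setMethod("frapTimes", "FrapTrace", function(object) object@time)
#' @rdname frapkd-accessors
setMethod("frapIntensity", "FrapTrace", function(object) object@intensity)
#' @rdname frapkd-accessors
setMethod("geometry", "FrapTrace", function(object) object@geometry)
#' @rdname frapkd-accessors
setMethod("preBleachFrames", "FrapTrace", function(object) object@preBleachFrames)
#' @rdname frapkd-accessors
setMethod("isNormalized", "FrapTrace", function(object) object@normalized)
#' @rdname frapkd-accessors
setMethod("traceMeta", "FrapTrace", function(object) object@meta)
#' @rdname frapkd-accessors
setMethod("bleachWindow", "BleachGeometry", function(object) object@w)
#' @rdname frapkd-accessors
setMethod("bleachWindow", "FrapTrace", function(object) object@geometry@w)

setMethod("show", "FrapTrace", function(object) {
  n <- length(object@time)
  cat(sprintf("FrapTrace: %d frames (%d pre-bleach), w = %g um%s\n",
              n, object@preBleachFrames, object@geometry@w,
              if (object@normalized) ", normalized" else ""))
  cat(sprintf("  time: %g .. %g s | intensity: %.4g .. %.4g\n",
              object@time[1], object@time[n],
              min(object@intensity), max(object@intensity)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

## -- BindingKinetics ---------------------------------------------------------

#' @rdname frapkd-accessors
setMethod("bindingConstant", "BindingKinetics",
          function(object) object@kOn / object@kOff)
#' @rdname frapkd-accessors
setMethod("bindingStrength", "BindingKinetics",
          function(object) object@kOn / object@kOff * object@sigmaFree)

setMethod("show", "BindingKinetics", function(object) {
  cat(sprintf(paste0("BindingKinetics: kOn = %g /(nM s), kOff = %g /s, ",
                     "sigmaFree = %g nM, dFree = %g um^2/s\n"),
              object@kOn, object@kOff, object@sigmaFree, object@dFree))
  cat(sprintf("  K = %g /nM, K*sigmaFree = %g\n",
              bindingConstant(object), bindingStrength(object)))
})

## -- FrapFit -----------------------------------------------------------------

#' @rdname frapkd-accessors
setMethod("fitModel", "FrapFit", function(object) object@model)
#' @rdname frapkd-accessors
setMethod("dEffective", "FrapFit", function(object) object@dEffective)
#' @rdname frapkd-accessors
setMethod("rSquared", "FrapFit", function(object) object@rSquared)

#' @rdname frapkd-accessors
#' @export
setMethod("coef", "FrapFit", function(object, ...) object@coefficients)

setMethod("show", "FrapFit", function(object) {
  cat(sprintf("FrapFit (%s model), %d points\n", object@model, object@nPoints))
  co <- object@coefficients
  cat("  ", paste(sprintf("%s = %.4g", names(co), co), collapse = ", "), "\n")
  cat(sprintf("  tau_2/3 = %.4g s, D_E = %.4g um^2/s, R^2 = %.4f\n",
              object@tauTwoThirds, object@dEffective, object@rSquared))
})

## -- GradientScenario --------------------------------------------------------

setMethod("show", "GradientScenario", function(object) {
  cat(sprintf("GradientScenario: L = %g um (x=0 posterior), %d positions\n",
              object@axisLength, object@nPositions))
  cat(sprintf("  W: max %g nM, sigmoid midpoint %g um, steepness %g /um\n",
              object@wMax, object@midpoint, object@steepness))
  cat(sprintf("  F_total = %g nM (Kd_WF = %g), N_total = %g nM (Kd_WN = %g)\n",
              object@fTotal, object@kdWF, object@nTotal, object@kdWN))
})

## -- FrameStack --------------------------------------------------------------

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d x %d px, %d frames, %g um/px\n",
              d[1], d[2], d[3], object@pixelSize))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: %d standards, slope %.4g / uM, intercept %.4g\n",
              length(object@concentration), object@slope, object@intercept))
})

setMethod("show", "OracleConfig", function(object) {
  cat(sprintf("OracleConfig: L = %g um, n = %d cells, %s boundaries%s\n",
              object@domainLength, object@nGrid, object@boundary,
              if (object@saturating) ", saturating sites" else ""))
  show(object@kinetics)
})
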
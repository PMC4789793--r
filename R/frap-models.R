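## Closed-form forward models for single-IS FRAP recovery.
##
## The free model is the window average over the bleach stripe [-w/2, w/2]
## of the 1D heat-kernel solution for an initial step bleach:
##   I_N(t) = 1 - bleachDepth * B(a),  a = w / (2 sqrt(D t)),
##   B(a)   = erf(a) + (exp(-a^2) - 1) / (a sqrt(pi)),
## with B(Inf) = 1 (t = 0) and B -> 0 as t -> Inf (complete recovery).

.erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Remaining bleached fraction (window-averaged) as a function of the
# dimensionless group a = w / (2 sqrt(D t)); decreasing from 1 to 0.
.bleachB <- function(a) {
  out <- numeric(length(a))
  inf <- !is.finite(a)
  out[inf] <- 1
  a <- a[!inf]
  # guard tiny a: B(a) ~ a/sqrt(pi) as a -> 0
  small <- a < 1e-6
  v <- numeric(length(a))
  v[small] <- a[small] / sqrt(pi)
  ab <- a[!small]
  v[!small] <- .erf(ab) + (exp(-ab^2) - 1) / (ab * sqrt(pi))
  out[!inf] <- v
  out
}

#' Dimensionless two-thirds-recovery constant
#'
#' The constant `c` linking the bleach-window length, the diffusion
#' coefficient and the two-thirds recovery time of the free-diffusion
#' recovery model: tau_{2/3} = c w^2 / D, equivalently
#' D_E = c w^2 / tau_{2/3}. It is defined by the identity that the
#' effective diffusion coefficient of a purely free recovery equals the
#' Fickian D, computed once from the analytic curve (full bleach) and
#' cached.
#'
#' @return The dimensionless constant (about 0.631).
#' @examples
#' cTwoThirds()
#' @export
cTwoThirds <- function() {
  if (is.null(.frapkdEnv$cTwoThirds)) {
    aStar <- uniroot(function(a) .bleachB(a) - 1 / 3,
                     interval = c(0.05, 5), tol = 1e-13)$root
    .frapkdEnv$cTwoThirds <- 1 / (4 * aStar^2)
  }
  .frapkdEnv$cTwoThirds
}

#' Free-diffusion FRAP recovery curve
#'
#' Normalized recovery of the window-averaged fluorescence after bleaching
#' a stripe of length `w` in a one-dimensional intercellular space in which
#' the tracer diffuses freely (Fickian coefficient `D`). Pre-bleach
#' intensity is 1; I(0) = 1 - bleachDepth; I -> 1 as t -> Inf.
#'
#' @param t time grid, s, non-negative and increasing.
#' @param D Fickian diffusion coefficient, um^2/s.
#' @param geometry a [BleachGeometry-class].
#' @return Numeric vector of normalized intensities, same length as `t`.
#' @examples
#' t <- seq(0, 60, by = 0.5)
#' iN <- freeRecoveryCurve(t, D = 3.75, geometry = bleachGeometry(7.5))
#' @seealso [simulateFrap()] for the reaction-diffusion ground truth,
#'   [fitFreeDiffusion()] for the inverse problem.
#' @export
freeRecoveryCurve <- function(t, D, geometry = bleachGeometry()) {
  .assertScalar(D, "D")
  validObject(geometry)
  if (any(!is.finite(t)) || any(t < 0))
    .frapkdStop("frapkdInvalidParameter", "'t' must be non-negative and finite")
  if (length(t) > 1L && any(diff(t) < 0))
    .frapkdStop("frapkdInvalidParameter", "'t' must be non-decreasing")
  a <- ifelse(t > 0, geometry@w / (2 * sqrt(D * t)), Inf)
  1 - geometry@bleachDepth * .bleachB(a)
}

#' Two-exponential FRAP recovery curve
#'
#' Recovery model for diffusion hindered by reversible adsorption:
#' `I(t) = plateau - A1 exp(-t/tau1) - A2 exp(-t/tau2)`, with a fast
#' diffusion-driven component (A1, tau1) and a slow adsorption-driven
#' component (A2, tau2). The weight of the fast exponent alpha = A1/A2
#' reflects the free-to-adsorbed ratio of the tracer.
#'
#' @param t time grid, s.
#' @param A1,A2 amplitudes of the fast and slow components (>= 0,
#'   A1 + A2 <= plateau).
#' @param tau1,tau2 characteristic times, s (> 0).
#' @param plateau asymptotic normalized intensity (default 1).
#' @return Numeric vector of normalized intensities.
#' @examples
#' twoExpCurve(0:100, A1 = 0.5, A2 = 0.5, tau1 = 2, tau2 = 60)
#' @export
twoExpCurve <- function(t, A1, A2, tau1, tau2, plateau = 1) {
  .assertScalar(tau1, "tau1"); .assertScalar(tau2, "tau2")
  .assertScalar(plateau, "plateau")
  .assertScalar(A1, "A1", positive = FALSE)
  .assertScalar(A2, "A2", positive = FALSE)
  if (A1 < 0 || A2 < 0)
    .frapkdStop("frapkdInvalidParameter", "amplitudes must be non-negative")
  plateau - A1 * exp(-t / tau1) - A2 * exp(-t / tau2)
}

#' @describeIn tauTwoThirds interpolated two-thirds time of a sampled curve.
#'   `object` is the time grid; supply `intensity` and the model-estimated
#'   `plateau`.
#' @param intensity sampled curve values (numeric method).
#' @param plateau asymptotic intensity estimated from a fitted model.
#' @export
setMethod("tauTwoThirds", "numeric", function(object, intensity, plateau) {
  time <- object
  if (length(time) != length(intensity))
    .frapkdStop("frapkdInvalidParameter", "time/intensity length mismatch")
  .assertScalar(plateau, "plateau", positive = FALSE)
  i0 <- intensity[1]
  if (plateau <= i0)
    .frapkdStop("frapkdNotConverged",
                "curve does not recover: plateau <= starting intensity")
  target <- i0 + (2 / 3) * (plateau - i0)
  above <- which(intensity >= target)
  if (!length(above))
    .frapkdStop("frapkdNotConverged",
                "curve never reaches 2/3 of the plateau")
  k <- above[1]
  if (k == 1L) return(time[1])
  # linear interpolation between the bracketing samples
  t0 <- time[k - 1]; t1 <- time[k]
  y0 <- intensity[k - 1]; y1 <- intensity[k]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
})

#' @describeIn tauTwoThirds exact/numeric two-thirds time of a fitted model.
#' @export
setMethod("tauTwoThirds", "FrapFit", function(object, ...) object@tauTwoThirds)

# two-thirds time from model parameters (internal)
.tauTwoThirdsFree <- function(D, w) cTwoThirds() * w^2 / D

.tauTwoThirdsTwoExp <- function(A1, A2, tau1, tau2, plateau) {
  i0 <- plateau - A1 - A2
  target <- i0 + (2 / 3) * (plateau - i0)   # = plateau - (A1+A2)/3
  f <- function(t) plateau - A1 * exp(-t / tau1) - A2 * exp(-t / tau2) - target
  if (A1 + A2 <= 0)
    .frapkdStop("frapkdNotConverged", "flat curve: no recovery amplitude")
  upper <- max(tau1, tau2) * 60
  uniroot(f, c(0, upper), tol = 1e-10 * upper)$root
}

#' Effective diffusion coefficient from the two-thirds recovery time
#'
#' Diffusivity of the virtual free-diffusion process whose two-thirds
#' recovery time matches the observed one: `D_E = c w^2 / tau_{2/3}` with
#' `c` = [cTwoThirds()]. For a purely free recovery D_E equals the Fickian
#' D identically.
#'
#' @param tauTwoThirds two-thirds recovery time, s.
#' @param geometry a [BleachGeometry-class].
#' @return Effective diffusion coefficient, um^2/s.
#' @examples
#' w <- 7.5
#' effectiveDiffusion(cTwoThirds() * w^2 / 3.75, bleachGeometry(w)) # 3.75
#' @export
effectiveDiffusion <- function(tauTwoThirds, geometry = bleachGeometry()) {
  .assertScalar(tauTwoThirds, "tauTwoThirds")
  validObject(geometry)
  cTwoThirds() * geometry@w^2 / tauTwoThirds
}

#' Predicted characteristic times from binding kinetics
#'
#' Limit expressions for the two-exponential recovery of a tracer that
#' reversibly binds immobile centres: the diffusion-driven time
#' `tau1 = c w^2 (1 + K sigmaFree) / dFree` (effective-diffusion limit),
#' the adsorption-driven time `tau2 = 1 / kOff`, and the fast-exponent
#' weight `alpha = A1/A2 = 1 / (K sigmaFree)` (the mass-action
#' free-to-bound pool ratio). These are regime limits, validated against
#' the reaction-diffusion simulator rather than exact for all kinetics.
#'
#' @param kinetics a [BindingKinetics-class].
#' @param geometry a [BleachGeometry-class].
#' @return Named list with `tau1` (s), `tau2` (s) and `alpha`
#'   (dimensionless; `Inf` when sigmaFree = 0, i.e. pure free diffusion).
#' @examples
#' kin <- bindingKinetics(K = 0.5, kOff = 0.01, sigmaFree = 100, dFree = 8)
#' characteristicTimes(kin, bleachGeometry(7.5))
#' @export
characteristicTimes <- function(kinetics, geometry = bleachGeometry()) {
  validObject(kinetics); validObject(geometry)
  if (kinetics@dFree <= 0)
    .frapkdStop("frapkdInvalidParameter", "dFree must be positive here")
  ks <- bindingStrength(kinetics)
  list(tau1 = cTwoThirds() * geometry@w^2 * (1 + ks) / kinetics@dFree,
       tau2 = 1 / kinetics@kOff,
       alpha = if (ks > 0) 1 / ks else Inf)
}

#' Stokes-Einstein diffusivity of a spherical protein
#'
#' `D = kB T / (6 pi eta R)` for a sphere of hydrodynamic radius `radiusNm`
#' in a medium of dynamic viscosity `viscosityPoise`, converted to um^2/s.
#' The intercellular-fluid default is 0.05 Poise; temperature defaults to
#' 293 K.
#'
#' @param radiusNm hydrodynamic radius, nm.
#' @param viscosityPoise dynamic viscosity, Poise (1 P = 0.1 Pa s).
#' @param temperatureK absolute temperature, K.
#' @return Diffusion coefficient, um^2/s.
#' @examples
#' stokesEinstein(5.4, viscosityPoise = 0.05)  # about 8 um^2/s
#' @export
stokesEinstein <- function(radiusNm, viscosityPoise = 0.05,
                           temperatureK = 293) {
  .assertScalar(radiusNm, "radiusNm")
  .assertScalar(viscosityPoise, "viscosityPoise")
  .assertScalar(temperatureK, "temperatureK")
  kB <- 1.380649e-23                      # J/K
  etaPaS <- viscosityPoise * 0.1          # Poise -> Pa s
  rM <- radiusNm * 1e-9                   # nm -> m
  dM2 <- kB * temperatureK / (6 * pi * etaPaS * rM)   # m^2/s
  dM2 * 1e12                              # -> um^2/s
}
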
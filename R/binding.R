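## Equilibrium binding solvers and dissociation-constant estimators.

#' 1:1 binding equilibrium (quadratic closed form)
#'
#' Complex concentration of a bimolecular 1:1 equilibrium from the totals
#' and the dissociation constant:
#' `C = ((N + W + Kd) - sqrt((N + W + Kd)^2 - 4 N W)) / 2`,
#' evaluated in the numerically stable form `2 N W / (s + sqrt(s^2 - 4NW))`.
#'
#' @param nTotal,wTotal total concentrations of the two partners, nM.
#' @param kd dissociation constant, nM.
#' @return Named list `complex`, `freeN`, `freeW` (nM).
#' @examples
#' binaryEquilibrium(1000, 1000, 100)$complex  # 729.84 nM
#' @export
binaryEquilibrium <- function(nTotal, wTotal, kd) {
  .assertScalar(kd, "kd")
  .assertScalar(nTotal, "nTotal", positive = FALSE)
  .assertScalar(wTotal, "wTotal", positive = FALSE)
  if (nTotal < 0 || wTotal < 0)
    .frapkdStop("frapkdInvalidParameter", "totals must be non-negative")
  s <- nTotal + wTotal + kd
  disc <- s^2 - 4 * nTotal * wTotal
  C <- if (nTotal * wTotal == 0) 0 else 2 * nTotal * wTotal / (s + sqrt(disc))
  list(complex = C, freeN = nTotal - C, freeW = wTotal - C)
}

#' Dissociation constant from a FRAP amplitude ratio
#'
#' In-vivo affinity estimation for a fast-diffusing labelled tracer bound
#' by a quasi-immobile partner: the fast (diffusion-driven) amplitude of
#' the two-exponential recovery reports the free fraction of the tracer,
#' the slow (adsorption-driven) amplitude its partner-bound fraction. With
#' `alpha = A1/A2`, free fraction `f = alpha / (1 + alpha)`, complex
#' `C = nTotal (1 - f)` and
#' `Kd = (nTotal - C)(wTotal - C) / C`.
#'
#' @param alpha fast/slow amplitude ratio A1/A2 (> 0; `Inf` means no
#'   binding and returns `Inf`).
#' @param nTotal total labelled-tracer concentration, nM.
#' @param wTotal total quasi-immobile partner concentration, nM.
#' @return Dissociation constant, nM. Round-trips [binaryEquilibrium()]:
#'   feeding the alpha implied by a Kd recovers that Kd.
#' @examples
#' eq <- binaryEquilibrium(1000, 1000, 100)
#' alpha <- eq$freeN / eq$complex
#' kdFromAmplitudeRatio(alpha, 1000, 1000)  # 100 nM
#' @export
kdFromAmplitudeRatio <- function(alpha, nTotal, wTotal) {
  .assertScalar(nTotal, "nTotal"); .assertScalar(wTotal, "wTotal")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    .frapkdStop("frapkdInvalidParameter", "'alpha' must be positive")
  if (!is.finite(alpha)) return(Inf)
  f <- alpha / (1 + alpha)
  C <- nTotal * (1 - f)
  if (C >= wTotal || C >= nTotal || C <= 0)
    .frapkdStop("frapkdInfeasibleRatio",
                sprintf(paste0("amplitude ratio implies a complex of %.3g nM, ",
                               "infeasible for totals %g/%g nM"),
                        C, nTotal, wTotal))
  (nTotal - C) * (wTotal - C) / C
}

#' Competitive three-species binding equilibrium
#'
#' Simultaneous mass-action equilibrium of a ligand W bound by a receptor F
#' and a competing inhibitor N (complexes WF, WN; no ternary complex).
#' Solved on the free ligand concentration as the single unknown of a
#' monotone scalar equation (bracketed root), which is robust for any
#' totals; conservation holds to 1e-9 relative and each pairwise Kd to
#' 1e-7 relative.
#'
#' @param system an [EquilibriumSystem-class] with totals `W`, `F`, `N` and
#'   kds `WF`, `WN`.
#' @return Named list `wf`, `wn`, `freeW`, `freeF`, `freeN` (nM).
#' @examples
#' sys <- equilibriumSystem(c(W = 50, F = 50, N = 50), c(WF = 10, WN = 100))
#' competitionEquilibrium(sys)
#' @export
competitionEquilibrium <- function(system) {
  validObject(system)
  need <- c("W", "F", "N")
  if (!all(need %in% names(system@totals)) ||
      !all(c("WF", "WN") %in% names(system@kds)))
    .frapkdStop("frapkdInvalidParameter",
                "system needs totals W, F, N and kds WF, WN")
  Wt <- system@totals[["W"]]; Ft <- system@totals[["F"]]
  Nt <- system@totals[["N"]]
  kWF <- system@kds[["WF"]]; kWN <- system@kds[["WN"]]
  if (Wt == 0)
    return(list(wf = 0, wn = 0, freeW = 0, freeF = Ft, freeN = Nt))
  # conservation residual, strictly increasing in free W
  g <- function(w) w * (1 + Ft / (kWF + w) + Nt / (kWN + w)) - Wt
  sol <- uniroot(g, c(0, Wt), tol = 1e-14 * (1 + Wt))
  w <- sol$root
  # one Newton polish step for residual tightness
  gp <- 1 + Ft * kWF / (kWF + w)^2 + Nt * kWN / (kWN + w)^2
  w <- w - g(w) / gp
  freeF <- Ft * kWF / (kWF + w)
  freeN <- Nt * kWN / (kWN + w)
  list(wf = w * freeF / kWF, wn = w * freeN / kWN,
       freeW = w, freeF = freeF, freeN = freeN)
}

#' Fit a 1:1 Langmuir binding isotherm
#'
#' Nonlinear least-squares fit of `response = Rmax x / (Kd + x)` to an
#' equilibrium binding dataset (SPR response vs analyte concentration, or
#' bound vs free concentration from a quantitative co-immunoprecipitation
#' dilution series). Confidence limits come from a seeded residual
#' bootstrap. An unidentifiable Kd (no curvature in the sampled range) is
#' flagged, never silently reported.
#'
#' @param x analyte/free concentrations, nM (>= 4 points spanning at least
#'   a 10-fold range).
#' @param y equilibrium response (RU) or bound concentration (nM).
#' @param fixedRmax optional known saturation value; when given only Kd is
#'   estimated.
#' @param nBoot residual-bootstrap replicates for the confidence interval.
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return List with `kd`, `rmax`, `ci` (percentile interval for Kd),
#'   `rSquared`, `flagged` (TRUE when Kd is weakly identified) and
#'   `fitted`.
#' @examples
#' x <- c(10, 20, 50, 100, 200, 500, 1000)
#' y <- 100 * x / (90 + x)
#' fitIsotherm(x, y, nBoot = 50)$kd  # 90
#' @export
fitIsotherm <- function(x, y, fixedRmax = NULL, nBoot = 199L, seed = 1L,
                        level = 0.95) {
  if (length(x) != length(y) || length(x) < 4L)
    .frapkdStop("frapkdInvalidInput",
                "need >= 4 matched concentration/response points")
  if (any(x < 0))
    .frapkdStop("frapkdInvalidInput", "concentrations must be >= 0")
  xp <- x[x > 0]
  if (max(xp) / min(xp) < 10)
    .frapkdStop("frapkdInvalidInput",
                "concentrations must span at least a 10-fold range")

  fitOnce <- function(yy) {
    kd0 <- {
      half <- max(yy) / 2
      x[which.min(abs(yy - half))]
    }
    kd0 <- max(kd0, min(xp) / 10)
    if (is.null(fixedRmax)) {
      fit <- minpack.lm::nlsLM(yy ~ Rmax * x / (Kd + x),
                               start = list(Rmax = max(yy) * 1.1, Kd = kd0),
                               lower = c(Rmax = 1e-12, Kd = 1e-9),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      coef(fit)
    } else {
      fit <- minpack.lm::nlsLM(yy ~ fixedRmax * x / (Kd + x),
                               start = list(Kd = kd0), lower = c(Kd = 1e-9),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      c(Rmax = fixedRmax, coef(fit))
    }
  }
  co <- tryCatch(fitOnce(y), error = function(e)
    .frapkdStop("frapkdFitFailure",
                paste("isotherm fit failed:", conditionMessage(e))))
  kd <- unname(co["Kd"]); rmax <- unname(co["Rmax"])
  yhat <- rmax * x / (kd + x)
  st <- .fitStats(y, yhat, if (is.null(fixedRmax)) 2L else 1L)

  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    res <- y - yhat
    set.seed(seed)
    boot <- vapply(seq_len(nBoot), function(b) {
      yb <- yhat + sample(res, replace = TRUE)
      out <- tryCatch(unname(fitOnce(yb)["Kd"]), error = function(e) NA_real_)
      out
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    if (length(boot) >= 10)
      ci <- unname(quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  flagged <- kd > 2 * max(x) ||
    (all(is.finite(ci)) && ci[1] > 0 && ci[2] / ci[1] > 20)
  if (flagged)
    warning("Kd weakly identified: no curvature in the sampled range")
  list(kd = kd, rmax = rmax, ci = ci, rSquared = st$r2,
       residualSd = st$sd, flagged = flagged, fitted = yhat)
}

#' Western-blot band density to molar concentration
#'
#' Converts a quantified band density into a molar concentration via a
#' linear calibration through a standard dilution series of known protein
#' mass, then normalises to the dilution and the reaction volume and
#' converts mass to moles with the molecular weight.
#'
#' @param density band density (or densities) to convert.
#' @param standardsNg known standard masses, ng (>= 3, monotone).
#' @param standardsDensity measured densities of the standards.
#' @param reactionVolumeUl precipitation-reaction volume, uL.
#' @param molecularWeightKda molecular weight of the protein, kDa.
#' @param dilution dilution factor applied before loading (multiplies the
#'   recovered mass).
#' @return Concentration(s), nM. Densities outside the standard range
#'   raise an extrapolation warning.
#' @examples
#' wbToConcentration(50, c(10, 30, 90), c(10, 30, 90),
#'                   reactionVolumeUl = 50, molecularWeightKda = 50)  # 20 nM
#' @export
wbToConcentration <- function(density, standardsNg, standardsDensity,
                              reactionVolumeUl, molecularWeightKda,
                              dilution = 1) {
  if (length(standardsNg) < 3L || length(standardsNg) != length(standardsDensity))
    .frapkdStop("frapkdInvalidInput", "need >= 3 matched standards")
  o <- order(standardsNg)
  standardsNg <- standardsNg[o]; standardsDensity <- standardsDensity[o]
  if (any(diff(standardsDensity) <= 0))
    .frapkdStop("frapkdCalibrationError", "standard series must be monotone")
  .assertScalar(reactionVolumeUl, "reactionVolumeUl")
  .assertScalar(molecularWeightKda, "molecularWeightKda")
  .assertScalar(dilution, "dilution")
  fit <- lm(standardsNg ~ standardsDensity)
  if (any(density < min(standardsDensity) | density > max(standardsDensity)))
    warning("density outside the standard range; extrapolating")
  ng <- unname(predict(fit, data.frame(standardsDensity = density))) * dilution
  # ng / (kDa * uL): ng*1e-9 g / (kDa*1e3 g/mol) / (uL*1e-6 L) * 1e9 nM/M
  ng * 1e3 / (molecularWeightKda * reactionVolumeUl)
}
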
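## Receptor-competition model of a sigmoid ligand signalling gradient.
##
## Axis convention: x = 0 posterior (ligand maximum), x = axisLength
## anterior. Total ligand W(x) follows a posterior-normalized logistic
## sigmoid; at each position the ligand is partitioned at equilibrium
## between the receptor F and the diffusible inhibitor N.

# total ligand at position x (internal; used by the scenario validity check)
.sigmoidW <- function(x, scenario) {
  s <- function(z) 1 / (1 + exp(scenario@steepness * (z - scenario@midpoint)))
  scenario@wMax * s(x) / s(0)
}

#' Total-ligand sigmoid profile
#'
#' `W(x) = wMax * s(x)/s(0)` with
#' `s(x) = 1 / (1 + exp(steepness (x - midpoint)))`, normalized so the
#' posterior end carries `wMax`.
#'
#' @param scenario a [GradientScenario-class].
#' @return data.frame with columns `x_um` and `w_nM`.
#' @examples
#' wnt8Profile(gradientScenario())[c(1, 151, 301), ]
#' @export
wnt8Profile <- function(scenario) {
  validObject(scenario)
  x <- seq(0, scenario@axisLength, length.out = scenario@nPositions)
  data.frame(x_um = x, w_nM = .sigmoidW(x, scenario))
}

#' Spatial profile of the ligand-receptor signalling complex
#'
#' Pointwise competitive equilibrium along the axis: at each position the
#' total ligand W(x) is partitioned between the receptor (complex WF, the
#' signalling species) and the inhibitor (complex WN) via
#' [competitionEquilibrium()].
#'
#' @param scenario a [GradientScenario-class].
#' @return data.frame with columns `x_um`, `w_nM` (total ligand), `wf_nM`,
#'   `wn_nM`, `freeW_nM`, `freeF_nM`, `freeN_nM`. The scenario is attached
#'   as attribute `"scenario"`.
#' @examples
#' prof <- signalProfile(gradientScenario())
#' head(prof)
#' @export
signalProfile <- function(scenario) {
  validObject(scenario)
  wp <- wnt8Profile(scenario)
  n <- nrow(wp)
  out <- matrix(0, n, 5,
                dimnames = list(NULL, c("wf", "wn", "freeW", "freeF", "freeN")))
  for (i in seq_len(n)) {
    eq <- tryCatch(
      competitionEquilibrium(equilibriumSystem(
        c(W = wp$w_nM[i], F = scenario@fTotal, N = scenario@nTotal),
        c(WF = scenario@kdWF, WN = scenario@kdWN))),
      error = function(e)
        .frapkdStop("frapkdNumericalFailure",
                    sprintf("equilibrium failed at position %d (x = %.1f um): %s",
                            i, wp$x_um[i], conditionMessage(e))))
    out[i, ] <- c(eq$wf, eq$wn, eq$freeW, eq$freeF, eq$freeN)
  }
  prof <- data.frame(x_um = wp$x_um, w_nM = wp$w_nM,
                     wf_nM = out[, "wf"], wn_nM = out[, "wn"],
                     freeW_nM = out[, "freeW"], freeF_nM = out[, "freeF"],
                     freeN_nM = out[, "freeN"])
  attr(prof, "scenario") <- scenario
  prof
}

#' Threshold position of a signalling profile
#'
#' Anterior-most position at which the signalling complex still meets a
#' threshold, by linear interpolation between grid points. The profile
#' must be non-increasing along the axis.
#'
#' @param profile data.frame from [signalProfile()] (columns `x_um`,
#'   `wf_nM`), or any data.frame with those columns.
#' @param threshold signalling-complex threshold, nM; must lie within the
#'   profile's range.
#' @return Threshold position x*, um.
#' @examples
#' prof <- data.frame(x_um = 0:300, wf_nM = 10 * (1 - 0:300 / 300))
#' thresholdPosition(prof, 5)  # 150
#' @export
thresholdPosition <- function(profile, threshold) {
  .assertScalar(threshold, "threshold", positive = FALSE)
  x <- profile$x_um; wf <- profile$wf_nM
  if (is.null(x) || is.null(wf))
    .frapkdStop("frapkdInvalidInput", "profile needs columns x_um, wf_nM")
  if (threshold > wf[1])
    .frapkdStop("frapkdOutOfRange",
                "threshold never reached: exceeds the posterior maximum")
  n <- length(x)
  if (threshold <= wf[n]) {
    if (threshold < wf[n])
      .frapkdStop("frapkdOutOfRange",
                  "threshold always exceeded along the whole axis")
    return(x[n])
  }
  k <- which(wf < threshold)[1]  # first position strictly below
  x0 <- x[k - 1]; x1 <- x[k]; y0 <- wf[k - 1]; y1 <- wf[k]
  x0 + (threshold - y0) / (y1 - y0) * (x1 - x0)
}

#' Threshold-shift analysis under inhibitor perturbation
#'
#' Recomputes the signalling profile at each supplied inhibitor level and
#' locates the threshold position of each: raising the diffusible
#' inhibitor moves the threshold crossing monotonically toward the
#' high-ligand (posterior, x = 0) side. Levels at which the threshold is
#' out of range are flagged and excluded with a warning.
#'
#' @param scenario the baseline [GradientScenario-class]; its `nTotal` is
#'   the wild-type level and (with the default `threshold = NULL`) defines
#'   the threshold as the wild-type complex concentration at mid-axis.
#' @param nogginLevels inhibitor totals to evaluate, nM (>= 2 levels).
#' @param threshold signalling threshold, nM, or `NULL` for the wild-type
#'   mid-axis default.
#' @return List with `table` (data.frame `level_nM`, `xStar_um`,
#'   `shift_um` relative to the first level), `range_um`
#'   (max minus min threshold position over usable levels) and
#'   `threshold_nM`.
#' @examples
#' sa <- shiftAnalysis(gradientScenario(), c(0, 50, 500))
#' sa$table
#' @export
shiftAnalysis <- function(scenario, nogginLevels, threshold = NULL) {
  validObject(scenario)
  if (length(nogginLevels) < 2L)
    .frapkdStop("frapkdInvalidInput", "need at least 2 inhibitor levels")
  if (any(nogginLevels < 0))
    .frapkdStop("frapkdInvalidParameter", "inhibitor levels must be >= 0")
  if (is.null(threshold)) {
    wt <- signalProfile(scenario)
    threshold <- approx(wt$x_um, wt$wf_nM, xout = scenario@axisLength / 2)$y
  }
  xs <- vapply(nogginLevels, function(lev) {
    sc <- scenario
    sc@nTotal <- as.numeric(lev)
    prof <- signalProfile(sc)
    tryCatch(thresholdPosition(prof, threshold),
             frapkdOutOfRange = function(e) {
               warning(sprintf(
                 "inhibitor level %g nM: threshold out of range; excluded", lev))
               NA_real_
             })
  }, numeric(1))
  tab <- data.frame(level_nM = nogginLevels, xStar_um = xs,
                    shift_um = xs - xs[1])
  ok <- is.finite(xs)
  list(table = tab,
       range_um = if (sum(ok) >= 2) max(xs[ok]) - min(xs[ok]) else NA_real_,
       threshold_nM = threshold)
}

#' Write a signalling profile as CSV
#'
#' @param profile data.frame from [signalProfile()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSignalProfile <- function(profile, file) {
  write.csv(profile, file, row.names = FALSE)
  invisible(file)
}
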
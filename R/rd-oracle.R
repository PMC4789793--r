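## Brute-force 1D reaction-diffusion FRAP simulator.
##
## Ground truth for the closed-form models: a fluorescent tracer A diffuses
## in a 1D intercellular space and reversibly binds immobile centres B,
## forming an immobile complex C. Bleaching converts fluorescent species
## inside the stripe into bleached counterparts that obey identical
## dynamics (and, in saturating mode, compete for the same centres, as they
## physically must).

#' Mass-action pre-bleach steady state
#'
#' Partition of the total labelled tracer between the free and bound pools
#' at equilibrium with constant free-centre concentration:
#' bound/free = K sigmaFree.
#'
#' @param kinetics a [BindingKinetics-class].
#' @param totalLabel total tracer concentration, nM.
#' @return Named list `free`, `bound` (nM); `free * K * sigmaFree == bound`.
#' @examples
#' kin <- bindingKinetics(K = 0.5, kOff = 0.01, sigmaFree = 100, dFree = 8)
#' steadyState(kin, totalLabel = 100)
#' @export
steadyState <- function(kinetics, totalLabel) {
  validObject(kinetics)
  .assertScalar(totalLabel, "totalLabel", positive = FALSE)
  if (totalLabel < 0)
    .frapkdStop("frapkdInvalidParameter", "'totalLabel' must be >= 0")
  ks <- bindingStrength(kinetics)
  free <- totalLabel / (1 + ks)
  list(free = free, bound = totalLabel - free)
}

#' Simulate a FRAP experiment by finite differences
#'
#' Solves the 1D reaction-diffusion system
#' `da/dt = D d2a/dx2 - kOn a sigmaFree + kOff c`,
#' `dc/dt = kOn a sigmaFree - kOff c` (c immobile) for fluorescent and
#' bleached pools, starting from the mass-action pre-bleach steady state,
#' with the fluorophores inside the bleach window converted to bleached
#' species at t = 0 (fraction `bleachDepth`). Returns the total fluorescent
#' signal (free + bound) averaged over the bleach window, normalized to the
#' pre-bleach level.
#'
#' Numerics: conservative flux-form explicit diffusion step under the
#' stability bound `dt <= 0.4 dx^2 / dFree`, combined with an exact
#' closed-form update of the linear binding reaction (default, sigmaFree
#' constant) or an explicit reaction step (saturating mode).
#'
#' @param config an [OracleConfig-class] (or a [BindingKinetics-class], in
#'   which case the remaining arguments of [oracleConfig()] may be passed
#'   via `...`).
#' @param ... forwarded to [oracleConfig()] when `config` is kinetics.
#' @return A normalized [FrapTrace-class] with `preBleachFrames = 0` whose
#'   `meta` carries `massError` (relative drift of total label; ~1e-12
#'   under reflecting boundaries) and the configuration used.
#' @examples
#' kin <- bindingKinetics(K = 0, kOff = 1, sigmaFree = 0, dFree = 3.75)
#' tr <- simulateFrap(kin, times = seq(0, 40, by = 0.5), nGrid = 200L)
#' @export
simulateFrap <- function(config, ...) {
  if (is(config, "BindingKinetics")) config <- oracleConfig(config, ...)
  if (!is(config, "OracleConfig"))
    .frapkdStop("frapkdConfigError", "'config' must be an OracleConfig")
  validObject(config)

  kin <- config@kinetics
  geom <- config@geometry
  n <- config@nGrid
  L <- config@domainLength
  dx <- L / n
  x <- (seq_len(n) - 0.5) * dx
  # fractional overlap of each cell with the bleach stripe, so the
  # discretised stripe has exactly length w (edge cells bleach partially)
  lo <- config@bleachCenter - geom@w / 2
  hi <- config@bleachCenter + geom@w / 2
  ov <- (pmin(x + dx / 2, hi) - pmax(x - dx / 2, lo)) / dx
  ov <- pmin(pmax(ov, 0), 1)
  winIdx <- which(ov > 0)
  winWgt <- ov[winIdx]
  if (length(winIdx) < 5L)
    .frapkdStop("frapkdConfigError",
                "grid too coarse: fewer than 5 cells in the bleach window")

  konSigma <- kin@kOn * kin@sigmaFree
  tEnd <- max(config@times)

  dt <- config@dt
  if (is.na(dt)) {
    dtDiff <- if (kin@dFree > 0) 0.4 * dx^2 / kin@dFree else Inf
    # splitting accuracy: resolve the exchange timescale as well
    dtReac <- if (konSigma + kin@kOff > 0) 0.2 / (konSigma + kin@kOff) else Inf
    dt <- min(dtDiff, dtReac, tEnd / 200)
  } else {
    if (kin@dFree > 0 && dt > 0.4 * dx^2 / kin@dFree + 1e-15)
      .frapkdStop("frapkdConfigError",
                  "stability bound violated: need dt <= 0.4*dx^2/dFree")
  }
  if (config@saturating) {
    rate <- kin@kOn * config@sigmaTotal + kin@kOff
    if (rate > 0) dt <- min(dt, 0.1 / rate)
  }
  nSteps <- max(1L, as.integer(ceiling(tEnd / dt)))
  dt <- tEnd / nSteps
  recordAt <- as.integer(round(config@times / dt))
  if (anyDuplicated(recordAt))
    .frapkdStop("frapkdConfigError",
                "output times closer than the simulation step; coarsen 'times'")

  # pre-bleach steady state
  if (config@saturating) {
    # quadratic 1:1 equilibrium of the tracer against the total sites
    kdNm <- kin@kOff / kin@kOn
    eqb <- binaryEquilibrium(config@totalLabel, config@sigmaTotal, kdNm)
    total <- config@totalLabel
    a <- rep(eqb$freeN, n); c <- rep(eqb$complex, n)
  } else {
    ss <- steadyState(kin, 1)
    total <- 1
    a <- rep(ss$free, n); c <- rep(ss$bound, n)
  }
  ab <- numeric(n); cb <- numeric(n)
  # bleach: convert depth fraction inside the stripe (edge cells pro rata)
  d <- geom@bleachDepth * winWgt
  ab[winIdx] <- d * a[winIdx]; cb[winIdx] <- d * c[winIdx]
  a[winIdx] <- (1 - d) * a[winIdx]; c[winIdx] <- (1 - d) * c[winIdx]

  res <- frapSimC(a, c, ab, cb, kin@dFree, konSigma, kin@kOff, kin@kOn,
                  if (config@saturating) config@sigmaTotal else 0,
                  config@saturating, dx, dt, nSteps, recordAt, winIdx - 1L,
                  winWgt, config@boundary == "periodic")
  if (isTRUE(res$negative))
    .frapkdStop("frapkdNumericalFailure",
                "negative concentrations in the simulation")

  massError <- max(abs(res$mass - res$mass[1])) / res$mass[1]
  res$signal <- res$signal / total   # normalize to the pre-bleach level
  frapTrace(config@times, res$signal, preBleachFrames = 0L,
            geometry = geom, normalized = TRUE,
            meta = list(massError = massError, dt = dt, dx = dx,
                        kinetics = kin, boundary = config@boundary))
}
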
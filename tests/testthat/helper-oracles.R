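# Independent reference implementations used as oracles in the tests.
# These deliberately avoid the package's own code paths.

# Plain-R explicit reaction-diffusion stepper (fully explicit Euler for
# both transport and binding, 4 species, reflecting boundaries), cross-
# checking the package's compiled stepper on small problems.
refSimulateFrap <- function(D, konSigma, kOff, w, L, n, times, depth = 1) {
  dx <- L / n
  x <- (seq_len(n) - 0.5) * dx
  ov <- pmin(pmax((pmin(x + dx / 2, L / 2 + w / 2) -
                   pmax(x - dx / 2, L / 2 - w / 2)) / dx, 0), 1)
  win <- ov > 0
  wgt <- ov[win]
  ks <- if (kOff > 0) konSigma / kOff else 0
  aEq <- 1 / (1 + ks); cEq <- 1 - aEq
  a <- rep(aEq, n); cc <- rep(cEq, n); ab <- ad <- numeric(n)
  cb <- numeric(n)
  dd <- depth * ov[win]
  ab[win] <- dd * a[win]; cb[win] <- dd * cc[win]
  a[win] <- (1 - dd) * a[win]; cc[win] <- (1 - dd) * cc[win]
  dt <- min(if (D > 0) 0.2 * dx^2 / D else Inf,
            if (konSigma + kOff > 0) 0.02 / (konSigma + kOff) else Inf,
            max(times) / 50)
  nSteps <- ceiling(max(times) / dt); dt <- max(times) / nSteps
  rec <- as.integer(round(times / dt))
  out <- numeric(length(times)); ri <- 1L
  lap <- function(u) {
    c(u[2] - u[1], u[-c(1, 2)] - 2 * u[-c(1, n)] + u[-c(n - 1, n)],
      u[n - 1] - u[n]) / dx^2
  }
  for (s in 0:nSteps) {
    if (ri <= length(rec) && rec[ri] == s) {
      out[ri] <- sum(wgt * (a[win] + cc[win])) / sum(wgt); ri <- ri + 1L
    }
    if (s == nSteps) break
    fa <- konSigma * a - kOff * cc
    fb <- konSigma * ab - kOff * cb
    a <- a + dt * (D * lap(a) - fa)
    cc <- cc + dt * fa
    ab <- ab + dt * (D * lap(ab) - fb)
    cb <- cb + dt * fb
  }
  out
}

# Brute-force grid search minimising the mass-action residuals of the
# three-species competition equilibrium (two-stage refinement on free W).
refCompetition <- function(Wt, Ft, Nt, kWF, kWN) {
  resid <- function(w) {
    fF <- Ft * kWF / (kWF + w)
    fN <- Nt * kWN / (kWN + w)
    abs(w + w * fF / kWF + w * fN / kWN - Wt)
  }
  grid <- seq(0, Wt, length.out = 20001)
  w0 <- grid[which.min(vapply(grid, resid, 1))]
  step <- Wt / 20000
  grid2 <- seq(max(0, w0 - step), min(Wt, w0 + step), length.out = 20001)
  w <- grid2[which.min(vapply(grid2, resid, 1))]
  fF <- Ft * kWF / (kWF + w)
  list(wf = w * fF / kWF, freeW = w)
}

# minimal FrapFit stub carrying a chosen effective diffusion coefficient,
# for pooling printed per-condition values
fitStub <- function(dE) {
  new("FrapFit", model = "free", coefficients = c(D = dE, bleachDepth = 1),
      tauTwoThirds = frapkd::cTwoThirds() * 7.5^2 / dE, dEffective = dE,
      rSquared = 1, residualSd = 0, nPoints = 11L, fitted = numeric(0),
      info = list())
}
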
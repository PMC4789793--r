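## Image-side helpers: drift registration, IS trace extraction,
## fluorescence calibration and graft diffusion-path measurement.
##
## Pixel coordinates are 0-based (row, col); physical positions are um and
## converted through pixelSize.

#' Read a single-channel TIFF stack
#'
#' @param file path to an 8/16-bit single-channel TIFF (possibly
#'   multi-page).
#' @param pixelSize um per pixel.
#' @param timestamps acquisition times, s; defaults to frame index.
#' @return A [FrameStack-class].
#' @export
readFrameStack <- function(file, pixelSize, timestamps = NULL) {
  if (!file.exists(file))
    .frapkdStop("frapkdIOError", sprintf("no such file: %s", file))
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel
    p
  })
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (is.null(timestamps)) timestamps <- seq_along(pages) - 1
  frameStack(arr, pixelSize = pixelSize, timestamps = timestamps)
}

#' Write a stack as multi-page TIFF
#'
#' @param stack a [FrameStack-class]; intensities are clipped to [0, 1]
#'   for storage.
#' @param file output path.
#' @return `file`, invisibly.
#' @rdname readFrameStack
#' @export
writeFrameStack <- function(stack, file) {
  validObject(stack)
  d <- dim(stack@frames)
  pages <- lapply(seq_len(d[3]), function(k)
    pmin(pmax(stack@frames[, , k], 0), 1))
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  invisible(file)
}

# integer-shift cross-correlation via FFT, with quadratic subpixel peak
# refinement; returns c(rowShift, colShift) moving `frame` onto `ref`
.ccShift <- function(ref, frame) {
  fr <- stats::fft(ref)
  ff <- stats::fft(frame)
  cc <- Re(stats::fft(fr * Conj(ff), inverse = TRUE))
  d <- dim(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  peak <- max(cc)
  # subpixel refinement: least-squares parabola over 5 samples per axis
  # (circular indexing), vertex clamped to +/- 1 px
  sub <- numeric(2)
  u <- -2:2
  for (ax in 1:2) {
    idx <- ((pk[ax] - 1 + u) %% d[ax]) + 1
    yv <- if (ax == 1) cc[idx, pk[2]] else cc[pk[1], idx]
    fit <- stats::lm.fit(cbind(1, u, u^2), yv)$coefficients
    sub[ax] <- if (is.finite(fit[3]) && fit[3] < 0)
      max(-1, min(1, -fit[2] / (2 * fit[3]))) else 0
  }
  sh <- (pk - 1) + sub
  # wrap to signed shifts
  for (ax in 1:2) if (sh[ax] > d[ax] / 2) sh[ax] <- sh[ax] - d[ax]
  list(shift = sh, peak = peak / (sqrt(sum(ref^2) * sum(frame^2)) + 1e-30))
}

# circularly roll a matrix by integer (row, col)
.rollMatrix <- function(m, dr, dc) {
  d <- dim(m)
  ri <- ((seq_len(d[1]) - 1 - dr) %% d[1]) + 1
  ci <- ((seq_len(d[2]) - 1 - dc) %% d[2]) + 1
  m[ri, ci, drop = FALSE]
}

#' Register a drifting time-lapse stack
#'
#' Estimates the rigid translation of every frame against the first frame
#' by maximising the cross-correlation (computed by FFT), refines the peak
#' to subpixel precision by quadratic interpolation, and aligns the stack
#' by the integer part of each shift. Rotation is not modelled. A frame
#' whose correlation peak falls below `minPeak` is flagged and inherits
#' the previous frame's shift.
#'
#' @param stack a [FrameStack-class] with >= 2 frames.
#' @param minPeak minimum normalized correlation peak for a trusted
#'   registration.
#' @return A [FrameStack-class] whose `shifts` slot holds the estimated
#'   (row, col) subpixel shifts; flagged frames are listed in
#'   `attr(, "failedFrames")`.
#' @export
registerFrames <- function(stack, minPeak = 0.2) {
  validObject(stack)
  d <- dim(stack@frames)
  if (d[3] < 2L)
    .frapkdStop("frapkdInvalidInput", "need at least 2 frames to register")
  ref <- stack@frames[, , 1] - mean(stack@frames[, , 1])
  shifts <- matrix(0, d[3], 2L)
  failed <- integer(0)
  aligned <- stack@frames
  for (k in 2:d[3]) {
    fr <- stack@frames[, , k] - mean(stack@frames[, , k])
    cs <- .ccShift(ref, fr)
    if (cs$peak < minPeak) {
      failed <- c(failed, k)
      shifts[k, ] <- shifts[k - 1, ]          # carry the last shift forward
    } else {
      shifts[k, ] <- cs$shift
    }
    if (max(abs(shifts[k, ])) > min(d[1:2]) / 2)
      .frapkdStop("frapkdRegistrationFailure",
                  sprintf("frame %d: shift larger than half the frame", k))
    aligned[, , k] <- .rollMatrix(stack@frames[, , k],
                                  round(shifts[k, 1]), round(shifts[k, 2]))
  }
  if (length(failed))
    warning(sprintf("registration failed for frame(s) %s; shift carried forward",
                    paste(failed, collapse = ", ")))
  out <- frameStack(aligned, stack@pixelSize, stack@timestamps, shifts)
  attr(out, "failedFrames") <- failed
  out
}

#' Extract an intercellular-space FRAP trace from an aligned stack
#'
#' Mean intensity per frame over the pixel band of a linear segment (the
#' bleached IS stripe), producing a raw [FrapTrace-class] whose bleach
#' window equals the segment length.
#'
#' @param stack an aligned [FrameStack-class].
#' @param from,to segment endpoints, um, as `c(x, y)` (x = column
#'   direction, y = row direction).
#' @param widthPx full width of the averaged band, px (>= 1).
#' @param preBleachFrames leading frames acquired before the bleach.
#' @return A raw [FrapTrace-class] (arbitrary intensity units).
#' @export
extractIsTrace <- function(stack, from, to, widthPx = 3L,
                           preBleachFrames = 0L) {
  validObject(stack)
  if (length(from) != 2L || length(to) != 2L)
    .frapkdStop("frapkdInvalidInput", "'from'/'to' must be (x, y) in um")
  segLen <- sqrt(sum((to - from)^2))
  if (segLen <= 0)
    .frapkdStop("frapkdInvalidInput", "zero-length segment")
  if (widthPx < 1L)
    .frapkdStop("frapkdInvalidInput", "'widthPx' must be >= 1")
  d <- dim(stack@frames)
  ps <- stack@pixelSize
  nSamp <- max(2L, ceiling(segLen / ps) * 2L)
  tt <- seq(0, 1, length.out = nSamp)
  # sample positions in pixel coordinates (0-based): col = x/ps, row = y/ps
  colP <- (from[1] + tt * (to[1] - from[1])) / ps
  rowP <- (from[2] + tt * (to[2] - from[2])) / ps
  # perpendicular band offsets
  ux <- (to[1] - from[1]) / segLen; uy <- (to[2] - from[2]) / segLen
  half <- (widthPx - 1) / 2
  offs <- if (widthPx > 1) seq(-half, half) else 0
  rows <- round(outer(rowP, offs * ux, `+`)) + 1L
  cols <- round(outer(colP, -offs * uy, `+`)) + 1L
  inside <- rows >= 1 & rows <= d[1] & cols >= 1 & cols <= d[2]
  if (!all(inside)) {
    if (!any(inside))
      .frapkdStop("frapkdInvalidInput", "segment outside frame bounds")
    warning("segment partially leaves the frame; trace truncated to inside pixels")
  }
  idx <- cbind(as.vector(rows)[inside], as.vector(cols)[inside])
  vals <- vapply(seq_len(d[3]), function(k) mean(stack@frames[, , k][idx]),
                 numeric(1))
  frapTrace(stack@timestamps, vals, preBleachFrames = preBleachFrames,
            geometry = bleachGeometry(w = segLen),
            meta = list(widthPx = widthPx, from = from, to = to))
}

#' Convert measured intensity to concentration
#'
#' Inverse of the linear fluorescence calibration. Intensities implying
#' concentrations beyond 1.5x the largest standard raise an extrapolation
#' warning.
#'
#' @param curve a [CalibrationCurve-class].
#' @param intensity measured mean signal density (vectorised).
#' @return Concentration(s), uM.
#' @export
intensityToConcentration <- function(curve, intensity) {
  validObject(curve)
  conc <- (intensity - curve@intercept) / curve@slope
  if (any(conc > 1.5 * max(curve@concentration)))
    warning("intensity beyond 1.5x the largest standard; extrapolating")
  conc
}

# distance from center to the polygon boundary along direction (dx, dy);
# polygon given as matrix of (x, y) vertices in px
.rayBoundary <- function(center, dxy, poly) {
  n <- nrow(poly)
  best <- NA_real_
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[if (i == n) 1 else i + 1, ]
    e <- p2 - p1
    den <- dxy[1] * (-e[2]) - dxy[2] * (-e[1])
    if (abs(den) < 1e-12) next
    rhs <- p1 - center
    tRay <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    tEdge <- (dxy[1] * rhs[2] - dxy[2] * rhs[1]) / den
    if (tRay > 0 && tEdge >= 0 && tEdge <= 1)
      if (is.na(best) || tRay < best) best <- tRay
  }
  best
}

# bilinear interpolation at 0-based (row, col) positions
.bilinear <- function(img, row, col) {
  d <- dim(img)
  r0 <- pmin(pmax(floor(row), 0), d[1] - 1)
  c0 <- pmin(pmax(floor(col), 0), d[2] - 1)
  r1 <- pmin(r0 + 1, d[1] - 1); c1 <- pmin(c0 + 1, d[2] - 1)
  fr <- row - r0; fc <- col - c0
  v00 <- img[cbind(r0 + 1, c0 + 1)]; v01 <- img[cbind(r0 + 1, c1 + 1)]
  v10 <- img[cbind(r1 + 1, c0 + 1)]; v11 <- img[cbind(r1 + 1, c1 + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Graft diffusion-path measurement
#'
#' Distance over which a fluorescent protein secreted by an ectodermal
#' graft spreads into the recipient tissue: along each of `nRays` equally
#' spaced radial directions from the graft centre, the diffusion path (DP)
#' is the distance from the graft boundary to the first position at which
#' the (3-sample moving-mean smoothed) intensity drops to the background
#' level.
#'
#' @param image single frame (numeric matrix).
#' @param center graft centre, 0-based (row, col) px.
#' @param boundary graft boundary polygon: matrix of 0-based (row, col)
#'   vertices enclosing `center`.
#' @param backgroundLevel background fluorescence level.
#' @param nRays number of rays (default 6, i.e. every 60 degrees).
#' @param pixelSize um per pixel.
#' @param stepPx radial sampling step, px.
#' @return List with `dp_um` (per-ray DP; `NA` for censored rays that
#'   never decay to background inside the frame), `censored` (logical per
#'   ray), `mean_um` and `sd_um` over uncensored rays.
#' @export
diffusionPath <- function(image, center, boundary, backgroundLevel,
                          nRays = 6L, pixelSize = 1, stepPx = 0.5) {
  if (!is.matrix(image))
    .frapkdStop("frapkdInvalidInput", "'image' must be a matrix")
  if (nRays < 1L) .frapkdStop("frapkdInvalidInput", "'nRays' must be >= 1")
  d <- dim(image)
  # boundary is (row, col); work in (x=col, y=row) for the ray geometry
  polyXY <- cbind(boundary[, 2], boundary[, 1])
  centerXY <- c(center[2], center[1])
  angles <- (seq_len(nRays) - 1) * 2 * pi / nRays
  dp <- rep(NA_real_, nRays); censored <- logical(nRays)
  for (k in seq_len(nRays)) {
    dir <- c(cos(angles[k]), sin(angles[k]))
    r0 <- .rayBoundary(centerXY, dir, polyXY)
    if (is.na(r0))
      .frapkdStop("frapkdInvalidInput",
                  "graft boundary does not enclose the centre on every ray")
    # max radius before leaving the frame
    rmax <- r0
    repeat {
      p <- centerXY + (rmax + stepPx) * dir
      if (p[1] < 0 || p[1] > d[2] - 1 || p[2] < 0 || p[2] > d[1] - 1) break
      rmax <- rmax + stepPx
    }
    if (rmax <= r0) { censored[k] <- TRUE; next }
    rr <- seq(r0, rmax, by = stepPx)
    px <- centerXY[1] + rr * dir[1]
    py <- centerXY[2] + rr * dir[2]
    prof <- .bilinear(image, py, px)
    sm <- prof
    if (length(prof) >= 3)
      sm <- stats::filter(prof, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- prof[is.na(sm)]
    below <- which(sm <= backgroundLevel)
    if (!length(below)) { censored[k] <- TRUE; next }
    j <- below[1]
    if (j == 1L) { dp[k] <- 0; next }
    # linear interpolation to the crossing
    frac <- (sm[j - 1] - backgroundLevel) / (sm[j - 1] - sm[j])
    dp[k] <- (rr[j - 1] + frac * stepPx - r0) * pixelSize
  }
  if (any(censored))
    warning(sprintf("%d ray(s) never decayed to background; censored",
                    sum(censored)))
  ok <- !censored
  list(dp_um = dp, censored = censored,
       mean_um = if (any(ok)) mean(dp[ok]) else NA_real_,
       sd_um = if (sum(ok) > 1) sd(dp[ok]) else NA_real_)
}
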
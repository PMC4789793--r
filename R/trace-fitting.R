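## Normalisation and model fitting of measured FRAP traces.

#' Normalize a raw FRAP trace
#'
#' Background-subtracts and rescales a raw trace so the pre-bleach mean
#' maps to 1 and the background to 0, and re-zeroes time at the first
#' post-bleach frame. Requires at least 2 pre-bleach frames.
#'
#' @param trace a raw [FrapTrace-class].
#' @param background background intensity level (same units as the trace);
#'   must be below the pre-bleach mean.
#' @return A normalized [FrapTrace-class] with `preBleachFrames = 0`.
#' @examples
#' tr <- frapTrace(0:20, c(200, 200, rep(125, 19)), preBleachFrames = 2L)
#' normalizeTrace(tr, background = 50)
#' @export
normalizeTrace <- function(trace, background = 0) {
  validObject(trace)
  .assertScalar(background, "background", positive = FALSE)
  npre <- trace@preBleachFrames
  if (npre < 2L)
    .frapkdStop("frapkdInvalidInput",
                "need at least 2 pre-bleach frames to normalize")
  pre <- mean(trace@intensity[seq_len(npre)])
  if (background >= pre)
    .frapkdStop("frapkdInvalidInput",
                "background must be below the pre-bleach mean")
  post <- seq(npre + 1L, length(trace@time))
  frapTrace(time = trace@time[post] - trace@time[npre + 1L],
            intensity = (trace@intensity[post] - background) / (pre - background),
            preBleachFrames = 0L, geometry = trace@geometry,
            normalized = TRUE, meta = trace@meta)
}

.requireNormalized <- function(trace, minPoints = 10L) {
  validObject(trace)
  if (!trace@normalized)
    .frapkdStop("frapkdInvalidInput",
                "trace must be normalized (see normalizeTrace)")
  if (length(trace@time) - trace@preBleachFrames < minPoints)
    .frapkdStop("frapkdInsufficientData",
                sprintf("need at least %d post-bleach frames", minPoints))
  invisible(trace)
}

.fitStats <- function(y, yhat, nPar) {
  ss <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  list(sse = ss,
       r2 = if (sst > 0) 1 - ss / sst else NA_real_,
       sd = sqrt(ss / max(1L, length(y) - nPar)))
}

#' Fit the free-diffusion recovery model
#'
#' Least-squares estimation of the Fickian diffusion coefficient `D` (and
#' the bleach depth) from a normalized single-IS FRAP trace using the 1D
#' free-diffusion forward model [freeRecoveryCurve()]. The two-thirds
#' recovery time and the effective diffusion coefficient are derived from
#' the fitted curve (for this model D_E equals the fitted D identically).
#'
#' @param trace a normalized [FrapTrace-class].
#' @return A [FrapFit-class] with `model = "free"`.
#' @examples
#' tr <- simFrapFree(D = 3.75, seed = 1)$traces[[1]]
#' fitFreeDiffusion(tr)
#' @export
fitFreeDiffusion <- function(trace) {
  .requireNormalized(trace)
  w <- trace@geometry@w
  t <- trace@time - trace@time[1]
  y <- trace@intensity

  depth0 <- min(0.999, max(0.05, 1 - y[1]))
  # initial D from the 50%-recovery time heuristic: B(a50) = 1/2
  a50 <- uniroot(function(a) .bleachB(a) - 0.5, c(0.1, 5), tol = 1e-9)$root
  rec <- (y - y[1]) / max(1e-12, 1 - y[1])
  k50 <- which(rec >= 0.5)
  t50 <- if (length(k50) && t[k50[1]] > 0) t[k50[1]] else max(t) / 4
  d0 <- w^2 / (4 * a50^2 * t50)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 - depth * .bleachB(ifelse(t > 0, w / (2 * sqrt(D * t)), Inf)),
      start = list(D = d0, depth = depth0),
      lower = c(D = 1e-8, depth = 1e-3), upper = c(D = 1e4, depth = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      .frapkdStop("frapkdFitFailure",
                  paste("free-diffusion fit failed:", conditionMessage(e))))
  co <- coef(fit)
  dHat <- unname(co["D"])
  yhat <- 1 - co["depth"] * .bleachB(ifelse(t > 0, w / (2 * sqrt(dHat * t)), Inf))
  st <- .fitStats(y, yhat, 2L)
  tau <- .tauTwoThirdsFree(dHat, w)
  new("FrapFit", model = "free",
      coefficients = c(D = dHat, bleachDepth = unname(co["depth"])),
      tauTwoThirds = tau,
      dEffective = effectiveDiffusion(tau, trace@geometry),
      rSquared = st$r2, residualSd = st$sd, nPoints = length(y),
      fitted = as.numeric(yhat), info = list(sse = st$sse))
}

# fixed multi-start schedule for the two-exponential fit (deterministic)
.twoExpStarts <- function(tmax) {
  tau1 <- tmax * 10^seq(-2.5, -0.5, length.out = 5)
  data.frame(tau1 = tau1, tau2 = pmin(tau1 * 25, tmax * 3))
}

#' Fit the two-exponential recovery model
#'
#' Least-squares estimation of `(A1, A2, tau1, tau2, plateau)` from a
#' normalized trace, with the ordering convention `tau1 < tau2` (fast
#' diffusion-driven component first). A fixed schedule of 5 log-spaced
#' multi-starts resolves the non-convex landscape deterministically; the
#' best final sum of squares wins. The plateau is free in `[0.5, 1.2]`
#' because recovery completeness is not guaranteed. When the slow
#' amplitude is degenerate (`A2` below 2% of the total), a warning is
#' raised and a single-exponential fallback is fitted.
#'
#' @param trace a normalized [FrapTrace-class].
#' @return A [FrapFit-class] with `model = "two_exp"`; coefficient `alpha`
#'   is the fast-exponent weight A1/A2.
#' @export
fitTwoExponential <- function(trace) {
  .requireNormalized(trace)
  t <- trace@time - trace@time[1]
  y <- trace@intensity
  tmax <- max(t)

  plateau0 <- min(1.2, max(0.5, mean(tail(y, max(3L, length(y) %/% 10)))))
  amp0 <- max(0.05, plateau0 - y[1])
  starts <- .twoExpStarts(tmax)
  lower <- c(A1 = 0, A2 = 0, tau1 = tmax * 1e-5, tau2 = tmax * 1e-4,
             plateau = 0.5)
  upper <- c(A1 = 1.5, A2 = 1.5, tau1 = tmax * 50, tau2 = tmax * 500,
             plateau = 1.2)

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    st <- list(A1 = amp0 / 2, A2 = amp0 / 2,
               tau1 = starts$tau1[k], tau2 = starts$tau2[k],
               plateau = plateau0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ plateau - A1 * exp(-t / tau1) - A2 * exp(-t / tau2),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    .frapkdStop("frapkdFitFailure",
                "two-exponential fit failed from every start")
  co <- as.list(coef(best$fit))
  # ordering convention: tau1 < tau2
  if (co$tau1 > co$tau2) {
    co[c("tau1", "tau2")] <- co[c("tau2", "tau1")]
    co[c("A1", "A2")] <- co[c("A2", "A1")]
  }
  degenerate <- FALSE
  if (co$A2 < 0.02 * (co$A1 + co$A2) || co$A2 < 1e-4) {
    warning("slow component degenerate (A2 ~ 0); falling back to a single exponential")
    degenerate <- TRUE
    sfit <- minpack.lm::nlsLM(
      y ~ plateau - A1 * exp(-t / tau1),
      start = list(A1 = co$A1 + co$A2, tau1 = co$tau1, plateau = co$plateau),
      lower = c(A1 = 0, tau1 = tmax * 1e-5, plateau = 0.5),
      upper = c(A1 = 1.5, tau1 = tmax * 50, plateau = 1.2))
    sco <- as.list(coef(sfit))
    co <- list(A1 = sco$A1, A2 = 0, tau1 = sco$tau1, tau2 = sco$tau1,
               plateau = sco$plateau)
  }
  yhat <- twoExpCurve(t, co$A1, max(co$A2, 0), co$tau1, co$tau2, co$plateau)
  st <- .fitStats(y, yhat, if (degenerate) 3L else 5L)
  tau <- if (degenerate) -co$tau1 * log(1 / 3)
         else .tauTwoThirdsTwoExp(co$A1, co$A2, co$tau1, co$tau2, co$plateau)
  alpha <- if (co$A2 > 0) co$A1 / co$A2 else Inf
  new("FrapFit", model = "two_exp",
      coefficients = c(A1 = co$A1, A2 = co$A2, tau1 = co$tau1,
                       tau2 = co$tau2, plateau = co$plateau, alpha = alpha),
      tauTwoThirds = tau,
      dEffective = effectiveDiffusion(tau, trace@geometry),
      rSquared = st$r2, residualSd = st$sd, nPoints = length(y),
      fitted = as.numeric(yhat),
      info = list(sse = st$sse, degenerate = degenerate))
}

.aicc <- function(sse, n, p) {
  k <- p + 1  # + residual variance
  if (n - k - 1 <= 0) return(Inf)
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select between the free and two-exponential recovery models
#'
#' Fits both models and selects by the small-sample-corrected information
#' criterion (AICc); ties (within 2 units) break toward the free model,
#' which has fewer parameters.
#'
#' @param trace a normalized [FrapTrace-class] with at least 12 post-bleach
#'   frames.
#' @return A list with `selected` (`"free"` or `"two_exp"`), `free` and
#'   `twoExp` (both [FrapFit-class]), and the AICc values.
#' @export
modelSelect <- function(trace) {
  .requireNormalized(trace, minPoints = 12L)
  n <- length(trace@time)
  freeFit <- tryCatch(fitFreeDiffusion(trace), frapkdError = function(e) e)
  twoFit <- tryCatch(suppressWarnings(fitTwoExponential(trace)),
                     frapkdError = function(e) e)
  failedFree <- inherits(freeFit, "condition")
  failedTwo <- inherits(twoFit, "condition")
  if (failedFree && failedTwo)
    .frapkdStop("frapkdFitFailure", "both model fits failed")
  aFree <- if (failedFree) Inf else .aicc(freeFit@info$sse, n, 2L)
  aTwo <- if (failedTwo) Inf else .aicc(twoFit@info$sse, n, 5L)
  selected <- if (aFree <= aTwo + 2) "free" else "two_exp"
  list(selected = selected,
       free = if (failedFree) NULL else freeFit,
       twoExp = if (failedTwo) NULL else twoFit,
       aicc = c(free = aFree, two_exp = aTwo))
}

#' Pool fit results across replicates and conditions
#'
#' Per-condition mean, standard deviation, standard error and count of a
#' chosen statistic (the effective diffusion coefficient by default). No
#' silent exclusion: every supplied fit contributes.
#'
#' @param fits list of [FrapFit-class] objects.
#' @param conditions character/factor of condition labels, one per fit.
#' @param statistic `"dEffective"` (default), `"D"`, `"tauTwoThirds"` or
#'   the name of any fitted coefficient.
#' @return data.frame with columns `condition`, `n`, `mean`, `sd`, `sem`.
#' @seealso [foldChange()]
#' @export
poolResults <- function(fits, conditions, statistic = "dEffective") {
  if (!length(fits) || length(fits) != length(conditions))
    .frapkdStop("frapkdInvalidInput",
                "'fits' and 'conditions' must be non-empty and matched")
  vals <- vapply(fits, function(f) {
    stopifnot(is(f, "FrapFit"))
    switch(statistic,
           dEffective = f@dEffective,
           tauTwoThirds = f@tauTwoThirds,
           rSquared = f@rSquared,
           {
             v <- f@coefficients[statistic]
             if (is.na(v)) .frapkdStop("frapkdInvalidInput",
                                       sprintf("no statistic '%s'", statistic))
             unname(v)
           })
  }, numeric(1))
  conditions <- as.character(conditions)
  out <- do.call(rbind, lapply(split(vals, conditions), function(v) {
    if (length(v) < 2L)
      .frapkdStop("frapkdInvalidInput",
                  "each condition needs at least 2 results")
    data.frame(n = length(v), mean = mean(v), sd = sd(v),
               sem = sd(v) / sqrt(length(v)))
  }))
  out <- cbind(condition = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Fold change between pooled conditions
#'
#' Ratio of the pooled means of two conditions, with the value rounded to
#' one significant figure for "approximately n-fold" reporting.
#'
#' @param pooled data.frame from [poolResults()].
#' @param numerator,denominator condition labels.
#' @return List with `ratio` and `approx` (one significant figure).
#' @export
foldChange <- function(pooled, numerator, denominator) {
  m <- setNames(pooled$mean, pooled$condition)
  if (anyNA(m[c(numerator, denominator)]))
    .frapkdStop("frapkdInvalidInput", "unknown condition label")
  r <- unname(m[numerator] / m[denominator])
  list(ratio = r, approx = signif(r, 1))
}

## -- delimited-text trace I/O ------------------------------------------------

#' Read and write FRAP traces as delimited text
#'
#' Traces are stored as CSV with columns `time_s`, `intensity`, plus a JSON
#' sidecar (`<file>.json`) holding the bleach geometry, the pre-bleach
#' frame count and any metadata.
#'
#' @param trace a [FrapTrace-class].
#' @param file CSV path.
#' @return `readFrapTrace()` returns a [FrapTrace-class];
#'   `writeFrapTrace()` returns `file` invisibly.
#' @export
writeFrapTrace <- function(trace, file) {
  validObject(trace)
  write.csv(data.frame(time_s = trace@time, intensity = trace@intensity),
            file, row.names = FALSE)
  side <- list(w = trace@geometry@w, bleachDepth = trace@geometry@bleachDepth,
               preBleachFrames = trace@preBleachFrames,
               normalized = trace@normalized,
               meta = trace@meta[!vapply(trace@meta, is.object, logical(1))])
  jsonlite::write_json(side, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @param w,preBleachFrames geometry/frame-count overrides used when no
#'   sidecar file is present.
#' @rdname writeFrapTrace
#' @export
readFrapTrace <- function(file, w = 7.5, preBleachFrames = 0L) {
  if (!file.exists(file))
    .frapkdStop("frapkdIOError", sprintf("no such file: %s", file))
  df <- read.csv(file)
  if (!all(c("time_s", "intensity") %in% names(df)))
    .frapkdStop("frapkdIOError", "trace CSV needs columns time_s, intensity")
  side <- paste0(file, ".json")
  geom <- bleachGeometry(w = w)
  norm <- FALSE; meta <- list()
  if (file.exists(side)) {
    s <- jsonlite::read_json(side, simplifyVector = TRUE)
    geom <- bleachGeometry(w = s$w, bleachDepth = s$bleachDepth)
    preBleachFrames <- s$preBleachFrames
    norm <- isTRUE(s$normalized)
    if (!is.null(s$meta)) meta <- as.list(s$meta)
  }
  frapTrace(df$time_s, df$intensity, preBleachFrames = preBleachFrames,
            geometry = geom, normalized = norm, meta = meta)
}
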
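## Standard-curve fitting, intensity -> concentration inversion, and
## spatiotemporal photobleaching correction.

#' Fit the two-parameter saturation-growth calibration curve
#'
#' Least-squares fit of \code{y = a x / (b + x)} to (free-calcium level,
#' mean intensity) pairs from indicator standards. The linear range is
#' reported as the level where the local slope of the fitted curve falls to
#' half its initial value, which for this law is exactly \code{b}.
#'
#' @param levels free-calcium standards (uM); at least 3 distinct values.
#' @param meanIntensities mean intensities, offset-subtracted (>= 0).
#' @param offset camera offset subtracted from \code{meanIntensities} before
#'   fitting (default 0, i.e. already subtracted).
#' @return a \linkS4class{CalibrationFit}.
#' @export
fitSaturationCurve <- function(levels, meanIntensities, offset = 0) {
  stopifnot(length(levels) == length(meanIntensities))
  y <- meanIntensities - offset
  if (length(unique(levels)) < 3L)
    stop("need at least 3 distinct calibration levels")
  if (any(levels < 0)) stop("levels must be >= 0")
  a0 <- max(y) * 1.1
  half <- a0 / 2
  b0 <- levels[which.min(abs(y - half))]
  if (b0 <= 0) b0 <- median(levels[levels > 0])
  df <- data.frame(x = levels, y = y)
  fit <- minpack.lm::nlsLM(y ~ a * x / (b + x), data = df,
                           start = list(a = a0, b = b0),
                           lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  rms <- sqrt(mean(residuals(fit)^2))
  new("CalibrationFit", curve = SaturationCurve(cf[["a"]], cf[["b"]]),
      residualRms = rms, linearRangeMax = cf[["b"]],
      nPoints = length(levels))
}

#' Per-frame centred-region means of a standards stack
#'
#' Mean intensity over a centred square region of each frame, the statistic
#' used to build the calibration table. The side is clipped to the frame.
#'
#' @param stack an \linkS4class{ImageStack} with one frame per standard.
#' @param sidePx side of the centred square (px; default 1000, i.e. the
#'   whole frame for typical fields).
#' @return numeric vector of per-frame means.
#' @export
measureStandardMeans <- function(stack, sidePx = 1000) {
  d <- dim(stack@frames)
  half <- floor(min(sidePx, d[1], d[2]) / 2)
  ci <- floor(d[1] / 2) + 1L; cj <- floor(d[2] / 2) + 1L
  ii <- max(1, ci - half):min(d[1], ci + half - 1)
  jj <- max(1, cj - half):min(d[2], cj + half - 1)
  vapply(seq_len(d[3]), function(k) mean(stack@frames[ii, jj, k]), numeric(1))
}

#' Estimate the camera offset from pre-stimulus frames
#'
#' Density mode of the pixel values of the given frames (the background is
#' the dominant population before stimulation).
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param frames frame indices to pool (default first frame).
#' @return scalar offset estimate.
#' @export
estimateCameraOffset <- function(stack, frames = 1L) {
  v <- as.vector(stack@frames[, , frames])
  d <- stats::density(v, n = 512)
  d$x[which.max(d$y)]
}

#' Build a spatiotemporal photobleaching reference
#'
#' Divides each offset-subtracted frame of a saturated-indicator stack by
#' its first frame at the pixel level:
#' \code{factor(x, y, t) = S(x, y, t) / S(x, y, 1)}. Pixels whose first
#' frame is not strictly positive are masked (NA) with a warning. The
#' factors are optionally Gaussian-smoothed per frame so the reference's own
#' shot noise is not injected into corrected data; the first frame is
#' identically 1 by construction.
#'
#' @param saturatedStack saturated-indicator \linkS4class{ImageStack}
#'   acquired under the experiment's exposure protocol.
#' @param offset camera offset subtracted before forming ratios.
#' @param smoothSigma Gaussian sigma (px) for per-frame smoothing of the
#'   factors; 0 disables.
#' @return a \linkS4class{BleachReference}.
#' @export
buildBleachReference <- function(saturatedStack, offset = 0, smoothSigma = 2) {
  d <- dim(saturatedStack@frames)
  s0 <- saturatedStack@frames[, , 1] - offset
  bad <- s0 <= 0
  if (any(bad))
    warning(sum(bad), " first-frame pixel(s) not strictly positive; masked")
  fac <- array(NA_real_, d)
  for (k in seq_len(d[3])) {
    f <- (saturatedStack@frames[, , k] - offset) / s0
    if (smoothSigma > 0 && min(d[1:2]) > 8)
      f <- as.matrix(EBImage::gblur(f, sigma = smoothSigma))
    f[bad] <- NA_real_
    fac[, , k] <- f
  }
  fac[, , 1][!bad] <- 1
  new("BleachReference", factors = fac, source = saturatedStack@channel,
      offset = offset)
}

#' Apply a photobleaching correction to a stack
#'
#' Divides the bleaching trend out of the offset-subtracted signal:
#' \code{corrected = offset + (raw - offset) / factor}. A stack that
#' bleaches identically to the reference becomes time-constant. Pixels whose
#' factor falls below \code{floorFactor} are masked NA as unreliable. The
#' literal multiply direction (which doubles, rather than removes, a
#' bleaching trend) is available for comparison via
#' \code{direction = "multiply"}.
#'
#' @param stack the \linkS4class{ImageStack} to correct (same geometry and
#'   clock as the reference).
#' @param ref a \linkS4class{BleachReference}.
#' @param floorFactor factors below this are masked (default 0.05).
#' @param direction "divide" (default) or "multiply".
#' @return corrected \linkS4class{ImageStack}.
#' @export
applyBleachCorrection <- function(stack, ref, floorFactor = 0.05,
                                  direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  if (!identical(dim(stack@frames), dim(ref@factors)))
    stop("stack and bleach reference shapes differ")
  fac <- ref@factors
  fac[fac < floorFactor] <- NA_real_
  sig <- stack@frames - ref@offset
  out <- if (direction == "divide") sig / fac else sig * fac
  stack@frames <- out + ref@offset
  stack
}

#' Convert a corrected fluorescence stack to free calcium
#'
#' Per-pixel inversion of the calibration curve on the offset-subtracted,
#' bleach-corrected intensities. Saturated pixels (at or above the
#' saturation level) are flagged, not silently clipped.
#'
#' @param stack bleach-corrected fluorescence \linkS4class{ImageStack}.
#' @param fit a \linkS4class{CalibrationFit}.
#' @param offset camera offset (intensity units).
#' @return list with \code{conc} (uM array, NA at saturated/masked pixels),
#'   \code{saturated} (logical array), \code{saturatedFraction}, and the
#'   stack geometry (\code{pixelSize}, \code{frameInterval}, \code{times}).
#' @export
stackToFreeCa <- function(stack, fit, offset = 0) {
  if (!is(fit, "CalibrationFit")) stop("'fit' must be a CalibrationFit")
  ii <- stack@frames - offset
  sat <- !is.na(ii) & ii >= fit@curve@a
  conc <- suppressWarnings(invertSaturation(ii, fit@curve))
  conc[sat] <- NA_real_
  list(conc = conc, saturated = sat,
       saturatedFraction = mean(sat, na.rm = TRUE),
       pixelSize = stack@pixelSize, frameInterval = stack@frameInterval,
       times = frameTimes(stack))
}
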
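## Brightfield network segmentation, radial boundary tracking, outcome
## classification, and delay / growth-rate extraction.

.sobelMagnitude <- function(frame) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(frame, kx)
  gy <- EBImage::filter2(frame, t(kx))
  sqrt(gx^2 + gy^2)
}

.blurredEdge <- function(frame, blurRadius) {
  m <- .sobelMagnitude(frame)
  as.matrix(EBImage::gblur(m, sigma = blurRadius))
}

#' Background-robust detection threshold from pre-stimulus frames
#'
#' Threshold = median + thresholdK * MAD of the blurred edge-magnitude image
#' pooled over the given (pre-pulse) frames.
#'
#' @param stack brightfield \linkS4class{ImageStack}.
#' @param params a \linkS4class{DetectionParams}.
#' @param frames frame indices known to contain no network.
#' @return scalar threshold.
#' @export
detectionThreshold <- function(stack, params, frames = 1L) {
  v <- unlist(lapply(frames, function(k)
    as.vector(.blurredEdge(stack@frames[, , k], params@blurRadius))))
  median(v) + params@thresholdK * mad(v)
}

#' Segment the network in one brightfield frame
#'
#' Edge magnitude (Sobel) -> Gaussian blur -> threshold -> small-component
#' removal. With \code{thresholdMode = "background-robust"} the threshold
#' must be supplied (see \code{\link{detectionThreshold}}); with
#' \code{"fixed"} the params' \code{fixedThreshold} is used.
#'
#' @param frame 2-D intensity matrix.
#' @param params a \linkS4class{DetectionParams}.
#' @param threshold scalar threshold overriding the params.
#' @return logical mask matrix.
#' @export
detectNetworkMask <- function(frame, params = DetectionParams(),
                              threshold = NULL) {
  if (is.null(threshold)) {
    if (params@thresholdMode == "fixed" && !is.na(params@fixedThreshold))
      threshold <- params@fixedThreshold
    else
      stop("background-robust mode needs a threshold from pre-pulse frames; ",
           "see detectionThreshold()")
  }
  mask <- .blurredEdge(frame, params@blurRadius) > threshold
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params@minArea)
  matrix(lab %in% keep, nrow(frame), ncol(frame))
}

## least-squares (Kasa) circle fit; returns c(cx, cy, r) or NULL for
## degenerate (collinear/duplicated) point sets
.circleFit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol) || anyNA(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  c(sol[1], sol[2], sqrt(max(r2, 0)))
}

#' Radius of the outer network boundary
#'
#' Boundary pixels of the mask are grouped into angular sectors around the
#' given centre; the outermost point of each occupied sector is kept (so a
#' single outlier cannot dominate) and a least-squares circle is fit through
#' those points. Returns the fitted radius in micrometres, or NA when the
#' mask is empty or provides too few sectors.
#'
#' @param mask logical matrix (network mask).
#' @param center (x, y) centre in um.
#' @param pixelSize um per pixel.
#' @param nSectors angular sectors (default 36).
#' @return radius in um, or NA (not detected).
#' @export
fitBoundaryRadius <- function(mask, center, pixelSize, nSectors = 36L) {
  if (!any(mask)) return(NA_real_)
  er <- EBImage::erode(mask, EBImage::makeBrush(3, "box")) > 0
  bnd <- mask & !er
  if (!any(bnd)) bnd <- mask # single-pixel-thick features
  idx <- which(bnd, arr.ind = TRUE)
  x <- (idx[, 2] - 1) * pixelSize - center[1]
  y <- (idx[, 1] - 1) * pixelSize - center[2]
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x)
  sector <- pmin(floor((ang + pi) / (2 * pi) * nSectors) + 1, nSectors)
  pick <- vapply(split(seq_along(r), sector),
                 function(i) i[which.max(r[i])], integer(1))
  if (length(pick) < 4L) return(NA_real_)
  fit <- .circleFit(x[pick] + center[1], y[pick] + center[2])
  if (is.null(fit)) return(NA_real_)
  fit[3]
}

#' Expected outward dilation of the detected mask
#'
#' The edge -> blur -> threshold pipeline systematically extends the mask
#' beyond the true texture boundary; on speckled-disk phantoms with the
#' package camera model the dilation is linear in the blur radius,
#' approximately \code{1.81 * blurRadius - 0.27} pixels. Used by
#' \code{\link{trackRadius}} to debias fitted radii.
#'
#' @param params a \linkS4class{DetectionParams}.
#' @return expected dilation in pixels.
#' @export
maskDilationPx <- function(params) {
  max(1.81 * params@blurRadius - 0.27, 0)
}

#' Track the radial network boundary through a stack
#'
#' Runs the detector on every frame and fits the outer-boundary radius.
#' With the background-robust threshold mode the threshold is calibrated on
#' \code{prePulseFrames}. A detection is accepted only when it persists for
#' \code{params@persistence} consecutive frames. Fitted radii are corrected
#' for the detector's systematic mask dilation
#' (\code{\link{maskDilationPx}}) unless \code{compensateDilation} is
#' FALSE.
#'
#' @param stack brightfield \linkS4class{ImageStack}.
#' @param center (x, y) tracking centre in um.
#' @param params a \linkS4class{DetectionParams}.
#' @param prePulseFrames frame indices used to calibrate the threshold.
#' @param compensateDilation subtract the expected mask dilation from the
#'   fitted radii (default TRUE).
#' @return a \linkS4class{BoundaryTrace}.
#' @export
trackRadius <- function(stack, center, params = DetectionParams(),
                        prePulseFrames = 1L, compensateDilation = TRUE) {
  n <- nFrames(stack)
  thr <- if (params@thresholdMode == "background-robust")
    detectionThreshold(stack, params, prePulseFrames) else params@fixedThreshold
  radii <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    mask <- detectNetworkMask(stack@frames[, , k], params, threshold = thr)
    radii[k] <- fitBoundaryRadius(mask, center, stack@pixelSize,
                                  params@nSectors)
  }
  raw <- !is.na(radii)
  det <- raw
  if (params@persistence > 1L && any(raw)) {
    rl <- rle(raw)
    ok <- rep(rl$values & rl$lengths >= params@persistence, rl$lengths)
    det <- ok
  }
  if (compensateDilation)
    radii <- pmax(radii - maskDilationPx(params) * stack@pixelSize, 0)
  radii[!det] <- NA_real_
  new("BoundaryTrace", times = frameTimes(stack), radii = radii,
      detected = det, center = as.numeric(center),
      pixelSize = stack@pixelSize)
}

#' Delay from pulse onset to first detection
#'
#' @param trace a \linkS4class{BoundaryTrace} on the protocol's clock.
#' @param protocol the \linkS4class{PulseProtocol} applied.
#' @return delay in seconds, or NA if never detected. A detection before
#'   pulse onset raises a data-integrity warning.
#' @export
extractDelay <- function(trace, protocol) {
  if (!any(trace@detected)) return(NA_real_)
  t1 <- trace@times[which(trace@detected)[1]]
  if (t1 < protocol@start)
    warning("network detected before pulse onset; check clock alignment")
  t1 - protocol@start
}

#' Initial radial growth rate
#'
#' Slope of the least-squares line through the first \code{k} detected
#' (time, radius) points.
#'
#' @param trace a \linkS4class{BoundaryTrace}.
#' @param k number of leading detected frames used (default 5).
#' @return rate in um/s, or NA (with a "reason" attribute) when fewer than
#'   \code{k} detections exist.
#' @export
initialGrowthRate <- function(trace, k = 5L) {
  idx <- which(trace@detected)
  if (length(idx) < k) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("only %d detected frames (need %d)",
                                   length(idx), k)
    return(out)
  }
  idx <- idx[seq_len(k)]
  unname(coef(lm(trace@radii[idx] ~ trace@times[idx]))[2])
}

#' Classify the network outcome of a stimulation experiment
#'
#' \code{none} when nothing was ever detected. Otherwise the radius at the
#' end of the post-pulse window is compared with the maximum detected
#' radius: \code{sustained} when it holds at least \code{sustainFrac} of the
#' maximum, \code{transient} when it has fallen below \code{decayFrac}
#' (a vanished network counts as radius 0), and \code{ambiguous} in between.
#'
#' @param trace a \linkS4class{BoundaryTrace} extending at least
#'   \code{postWindow} seconds beyond the pulse end.
#' @param protocol the \linkS4class{PulseProtocol} applied.
#' @param postWindow evaluation window after pulse end (s).
#' @param sustainFrac,decayFrac classification fractions.
#' @return a \linkS4class{NetworkOutcome}.
#' @export
classifyOutcome <- function(trace, protocol, postWindow = 10,
                            sustainFrac = 0.8, decayFrac = 0.5) {
  pulseEnd <- protocol@start + protocol@duration
  if (max(trace@times) < pulseEnd + postWindow)
    stop(sprintf("trace ends %.3g s after the pulse; need %.3g s",
                 max(trace@times) - pulseEnd, postWindow))
  if (!any(trace@detected))
    return(new("NetworkOutcome", label = "none", delay = NA_real_,
               maxRadius = NA_real_, initialGrowthRate = NA_real_))
  maxR <- max(trace@radii, na.rm = TRUE)
  endSel <- trace@times <= pulseEnd + postWindow
  endIdx <- tail(which(endSel), 3L)
  endR <- mean(ifelse(trace@detected[endIdx], trace@radii[endIdx], 0))
  label <- if (endR >= sustainFrac * maxR) "sustained"
  else if (endR < decayFrac * maxR) "transient"
  else "ambiguous"
  new("NetworkOutcome", label = label,
      delay = extractDelay(trace, protocol), maxRadius = maxR,
      initialGrowthRate = as.numeric(initialGrowthRate(trace)))
}
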
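## Dual-channel competition inference of calcium-bound protein, boundary
## concentration extraction, ultrasensitive Hill-transition fitting, phase
## portraits, and group statistics.

#' Pixel-level intensity difference between reference and experiment
#'
#' \code{deltaI = I_ref - I_exp}: the fluorescence deficit caused by the
#' protein competing with the indicator for released calcium. Both stacks
#' must be bleach-corrected, spatially registered, and on the same clock.
#'
#' @param refStack indicator-only reference \linkS4class{ImageStack}.
#' @param expStack protein-containing experimental \linkS4class{ImageStack}.
#' @return an \linkS4class{ImageStack} of differences (channel "deltaI").
#' @export
deltaIntensity <- function(refStack, expStack) {
  if (!identical(dim(refStack@frames), dim(expStack@frames)))
    stop("reference and experimental stacks have different shapes")
  if (abs(refStack@frameInterval - expStack@frameInterval) > 1e-9 ||
      abs(refStack@clockOrigin - expStack@clockOrigin) > 1e-9)
    stop("reference and experimental stacks are on different clocks")
  if (abs(refStack@pixelSize - expStack@pixelSize) > 1e-9)
    stop("reference and experimental stacks have different pixel sizes")
  out <- refStack
  out@frames <- refStack@frames - expStack@frames
  out@channel <- "deltaI"
  out
}

#' Infer calcium-bound protein from the fluorescence deficit
#'
#' Converts a \code{deltaI} stack to bound-protein concentrations (uM).
#' Three estimators are available:
#' \describe{
#'   \item{linear-slope}{\code{conc = deltaI * b / a}, the inverse of the
#'     calibration curve's initial slope. First-order; accurate only well
#'     below the indicator's dissociation constant.}
#'   \item{inversion-difference}{\code{conc = invert(I_ref) - invert(I_exp)},
#'     the free-calcium deficit; exact in the saturation law, requires
#'     \code{refStack}.}
#'   \item{buffer-corrected}{the inversion difference multiplied by
#'     \code{1 + sum_j B_j K_j / (K_j + f)^2} over the \emph{known}
#'     competing buffers, evaluated at the mid free-calcium level: the
#'     uniform species (EGTA and the indicator itself) always, plus -- when
#'     \code{protocol} and \code{kPhot} are supplied -- the photolyzed
#'     chelator inside the ROI at its exposure-dependent concentration
#'     \code{total * (1 - exp(-kPhot * intensity/100 * t_on))}. The
#'     photolysis rate constant is obtainable by fitting the reference
#'     run's ROI release curve. Accounts for the deficit share absorbed by
#'     the other buffers; requires \code{refStack} and \code{panel}.}
#' }
#' Negative estimates are floored at 0 and counted; a floored fraction above
#' 10\% triggers a pairing-failure warning.
#'
#' @param delta \code{deltaI} \linkS4class{ImageStack} from
#'   \code{\link{deltaIntensity}}.
#' @param fit a \linkS4class{CalibrationFit}.
#' @param mode estimator (see above).
#' @param refStack the bleach-corrected reference stack (required by the
#'   inversion-based modes).
#' @param panel the \linkS4class{ReagentPanel} (buffer-corrected mode only).
#' @param offset camera offset (intensity units).
#' @param protocol optional \linkS4class{PulseProtocol}; enables the
#'   photolyzed-chelator term of the buffer correction.
#' @param kPhot photolysis rate constant at 100\% intensity (1/s) used for
#'   the photolyzed-chelator term.
#' @return a \linkS4class{BoundTcb2Stack}.
#' @export
boundTcb2FromDelta <- function(delta, fit,
                               mode = c("linear-slope", "inversion-difference",
                                        "buffer-corrected"),
                               refStack = NULL, panel = NULL, offset = 0,
                               protocol = NULL, kPhot = NA_real_) {
  mode <- match.arg(mode)
  a <- fit@curve@a; b <- fit@curve@b
  if (mode == "linear-slope") {
    conc <- delta@frames * b / a
  } else {
    if (is.null(refStack))
      stop("mode '", mode, "' needs the reference stack")
    iRef <- refStack@frames - offset
    iExp <- iRef - delta@frames
    fRef <- suppressWarnings(invertSaturation(iRef, fit@curve))
    fExp <- suppressWarnings(invertSaturation(iExp, fit@curve))
    conc <- fRef - fExp
    if (mode == "buffer-corrected") {
      if (is.null(panel))
        stop("mode 'buffer-corrected' needs the reagent panel")
      keep <- speciesNames(panel) %in% c("EGTA", "Rhod5N")
      B <- vapply(panel@species[keep], function(s) s@total, numeric(1))
      K <- vapply(panel@species[keep], function(s) s@kd, numeric(1))
      fMid <- (pmax(fRef, 0) + pmax(fExp, 0)) / 2
      corr <- 1 + .bufferingSlope(fMid, B, K)
      ip <- match("DMNP.photolyzed", speciesNames(panel))
      ic <- match("DMNP.caged", speciesNames(panel))
      if (!is.null(protocol) && !is.na(kPhot) && !is.na(ip)) {
        dmnpTot <- panel@species[[ip]]@total +
          if (!is.na(ic)) panel@species[[ic]]@total else 0
        kdP <- panel@species[[ip]]@kd
        d <- dim(conc)
        px <- delta@pixelSize
        xs <- (seq_len(d[2]) - 1) * px
        ys <- (seq_len(d[1]) - 1) * px
        inROI <- outer((ys - protocol@center[2])^2,
                       (xs - protocol@center[1])^2, "+") <=
          (protocol@diameter / 2)^2
        tms <- frameTimes(delta)
        for (k in seq_len(d[3])) {
          tOn <- min(max(tms[k] - protocol@start, 0), protocol@duration)
          P <- dmnpTot * (1 - exp(-kPhot * protocol@intensity / 100 * tOn))
          if (P <= 0) next
          corr[, , k] <- corr[, , k] +
            inROI * (P * kdP / (kdP + fMid[, , k])^2)
        }
      }
      conc <- conc * corr
    }
  }
  neg <- !is.na(conc) & conc < 0
  flooredFraction <- mean(neg)
  if (flooredFraction > 0.1)
    warning(sprintf(
      "%.1f%% of pixels had negative bound estimates: possible pairing failure",
      100 * flooredFraction))
  conc[neg] <- 0
  new("BoundTcb2Stack", conc = conc, mode = mode,
      flooredFraction = flooredFraction, pixelSize = delta@pixelSize,
      frameInterval = delta@frameInterval, times = frameTimes(delta))
}

## 3x3 median filter (NA-tolerant at borders via edge replication)
.median3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  shift <- function(di, dj)
    m[pmin(pmax(seq_len(ny) + di, 1), ny), pmin(pmax(seq_len(nx) + dj, 1), nx)]
  stack <- array(0, c(ny, nx, 9))
  k <- 1
  for (di in -1:1) for (dj in -1:1) {
    stack[, , k] <- shift(di, dj)
    k <- k + 1
  }
  apply(stack, c(1, 2), median)
}

#' Per-frame maximum bound protein within an ROI
#'
#' A 3x3 median filter suppresses single-pixel noise before taking the
#' per-frame maximum inside the circular ROI.
#'
#' @param bstack a \linkS4class{BoundTcb2Stack}.
#' @param center ROI centre (x, y) um.
#' @param radius ROI radius (um).
#' @return data.frame (time, maxBound).
#' @export
maxBoundTrace <- function(bstack, center, radius) {
  d <- dim(bstack@conc)
  px <- bstack@pixelSize
  x <- (seq_len(d[2]) - 1) * px
  y <- (seq_len(d[1]) - 1) * px
  inROI <- outer((y - center[2])^2, (x - center[1])^2, "+") <= radius^2
  if (!any(inROI)) stop("empty ROI")
  mx <- vapply(seq_len(d[3]), function(k) {
    f <- .median3x3(bstack@conc[, , k])
    max(f[inROI], na.rm = TRUE)
  }, numeric(1))
  data.frame(time = bstack@times, maxBound = mx)
}

#' Bound-protein concentration on the tracked network boundary
#'
#' For every detected frame, the mean bound-protein concentration over an
#' annulus of the given width centred on the fitted boundary circle. Frames
#' whose annulus extends beyond the field are flagged partial.
#'
#' @param bstack a \linkS4class{BoundTcb2Stack}.
#' @param trace a \linkS4class{BoundaryTrace} (same geometry and clock).
#' @param widthPx annulus width (px; default 3).
#' @return data.frame (time, radius, boundary, partial) with one row per
#'   detected frame.
#' @export
boundaryConcentration <- function(bstack, trace, widthPx = 3) {
  if (!any(trace@detected)) stop("trace contains no detected frames")
  d <- dim(bstack@conc)
  px <- bstack@pixelSize
  x <- (seq_len(d[2]) - 1) * px
  y <- (seq_len(d[1]) - 1) * px
  rmap <- sqrt(outer((y - trace@center[2])^2, (x - trace@center[1])^2, "+"))
  half <- widthPx * px / 2
  idx <- which(trace@detected)
  idx <- idx[!is.na(match(round(trace@times[idx], 9), round(bstack@times, 9)))]
  rows <- lapply(idx, function(k) {
    kk <- match(round(trace@times[k], 9), round(bstack@times, 9))
    R <- trace@radii[k]
    ring <- abs(rmap - R) <= half
    partial <- (R + half) > min(max(x) - trace@center[1], trace@center[1],
                                max(y) - trace@center[2], trace@center[2])
    data.frame(time = trace@times[k], radius = R,
               boundary = mean(bstack@conc[, , kk][ring], na.rm = TRUE),
               partial = partial)
  })
  do.call(rbind, rows)
}

#' Pool (bound protein, assembled?) observations from one pulse
#'
#' Samples the inferred bound-protein map and the brightfield network mask
#' at probe pixels spread over rings around the ROI during the stimulation
#' window, pairing each probe's local concentration (3x3 mean) with its
#' local binary assembly status from the detector. Because the assembled
#' fraction relaxes toward the Hill propensity of the local load, pooled
#' local observations across pulses trace out the ultrasensitive transition
#' for \code{\link{fitHillTransition}}. Observations are restricted to the
#' stimulation window: after the pulse, persistent networks remain detected
#' while the soluble load relaxes, which would pair assembled status with
#' concentrations unrelated to the triggering threshold.
#'
#' An alternative per-frame summary scheme ("roi-max") pairs the ROI-wide
#' maximum concentration with whole-frame detection, tracing the threshold
#' at which each pulse first triggers assembly.
#'
#' @param bstack a \linkS4class{BoundTcb2Stack}.
#' @param brightfield the paired brightfield \linkS4class{ImageStack}.
#' @param protocol the \linkS4class{PulseProtocol} applied.
#' @param params \linkS4class{DetectionParams} for the local masks.
#' @param prePulseFrames frames used to calibrate the detection threshold.
#' @param scheme "local" (default) or "roi-max".
#' @param trace \linkS4class{BoundaryTrace} (roi-max scheme only).
#' @param probeStride keep every probeStride-th pixel diagonal (local
#'   scheme); controls observation density.
#' @param frameStride sample every frameStride-th frame.
#' @param maxRadiusFactor probes out to this multiple of the ROI radius.
#' @param pulseId label recorded with the observations.
#' @return data.frame of \code{\link{AssemblyObservation}} rows.
#' @export
collectAssemblyObservations <- function(bstack, brightfield = NULL, protocol,
                                        params = DetectionParams(),
                                        prePulseFrames = 1L,
                                        scheme = c("local", "roi-max"),
                                        trace = NULL, probeStride = 3L,
                                        frameStride = 2L,
                                        maxRadiusFactor = 1.3,
                                        pulseId = "pulse") {
  scheme <- match.arg(scheme)
  pulseEnd <- protocol@start + protocol@duration + 1e-9
  if (scheme == "roi-max") {
    if (is.null(trace)) stop("scheme 'roi-max' needs the boundary trace")
    mt <- maxBoundTrace(bstack, protocol@center, protocol@diameter / 2)
    kk <- match(round(mt$time, 9), round(trace@times, 9))
    status <- ifelse(is.na(kk), FALSE, trace@detected[kk])
    keep <- mt$time <= pulseEnd
    return(AssemblyObservation(pmax(mt$maxBound[keep], 0), status[keep],
                               pulseId = pulseId, time = mt$time[keep]))
  }
  if (is.null(brightfield)) stop("scheme 'local' needs the brightfield stack")
  thr <- .halfAssemblyThreshold(brightfield, protocol, params, prePulseFrames)
  d <- dim(bstack@conc)
  px <- bstack@pixelSize
  xs <- (seq_len(d[2]) - 1) * px
  ys <- (seq_len(d[1]) - 1) * px
  rmap <- sqrt(outer((ys - protocol@center[2])^2,
                     (xs - protocol@center[1])^2, "+"))
  roiR <- protocol@diameter / 2
  inner <- matrix(FALSE, d[1], d[2])
  inner[2:(d[1] - 1), 2:(d[2] - 1)] <- TRUE
  sel <- which(rmap >= px & rmap <= maxRadiusFactor * roiR & inner &
                 (row(rmap) + col(rmap)) %% probeStride == 0L)
  frames <- which(bstack@times > protocol@start & bstack@times <= pulseEnd)
  frames <- frames[seq(1, length(frames), by = frameStride)]
  out <- vector("list", length(frames))
  for (q in seq_along(frames)) {
    k <- frames[q]
    kk <- match(round(bstack@times[k], 9),
                round(frameTimes(brightfield), 9))
    if (is.na(kk)) next
    mask <- detectNetworkMask(brightfield@frames[, , kk], params,
                              threshold = thr)
    est <- .mean3x3(bstack@conc[, , k])
    out[[q]] <- AssemblyObservation(pmax(est[sel], 0), mask[sel] > 0,
                                    pulseId = pulseId,
                                    time = bstack@times[k])
  }
  do.call(rbind, out)
}

## Local-status threshold calibrated to the half-assembled level: the
## blurred edge magnitude of the speckle texture is linear in the assembled
## fraction, so the midpoint between the background level and the mature
## network interior level reads a 50%-assembled region as assembled with
## probability ~1/2 (an unbiased binarization of the fraction). Falls back
## to the background-robust detection threshold when no network is present.
.halfAssemblyThreshold <- function(brightfield, protocol, params,
                                   prePulseFrames) {
  thrBg <- detectionThreshold(brightfield, params, prePulseFrames)
  l0 <- median(unlist(lapply(prePulseFrames, function(k)
    as.vector(.blurredEdge(brightfield@frames[, , k], params@blurRadius)))))
  d <- dim(brightfield@frames)
  px <- brightfield@pixelSize
  xs <- (seq_len(d[2]) - 1) * px
  ys <- (seq_len(d[1]) - 1) * px
  inROI <- outer((ys - protocol@center[2])^2,
                 (xs - protocol@center[1])^2, "+") <=
    (protocol@diameter / 2)^2
  lastK <- max(which(frameTimes(brightfield) <=
                       protocol@start + protocol@duration + 1e-9))
  e <- .blurredEdge(brightfield@frames[, , lastK], params@blurRadius)
  l1 <- quantile(e[inROI], 0.9, names = FALSE)
  if (l1 <= thrBg) return(thrBg) # no mature network: plain detection level
  max((l0 + l1) / 2, thrBg)
}

## 3x3 box mean with edge replication (NA-tolerant)
.mean3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  acc <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  for (di in -1:1) for (dj in -1:1) {
    sh <- m[pmin(pmax(seq_len(ny) + di, 1), ny),
            pmin(pmax(seq_len(nx) + dj, 1), nx)]
    ok <- !is.na(sh)
    sh[!ok] <- 0
    acc <- acc + sh
    cnt <- cnt + ok
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- NA_real_
  out
}

#' Fit the ultrasensitive assembly transition
#'
#' Fits assembly as a function of bound-protein concentration to the Hill
#' equation \code{y = x^N / (K^N + x^N)} by nonlinear least squares. With
#' \code{method = "binned"} (default) the binary observations are grouped
#' into equal-count concentration bins and the per-bin assembled fraction is
#' fit; \code{"binary"} fits the 0/1 status directly.
#'
#' @param observations data.frame with columns \code{boundTcb2} and
#'   \code{assembled} (see \code{\link{AssemblyObservation}}).
#' @param method "binned" or "binary".
#' @param nBins equal-count bins for the binned method.
#' @return a \linkS4class{HillFitResult}. When the two classes do not
#'   overlap the exponent is unidentifiable: the midpoint is reported as the
#'   geometric mid-gap, the exponent as Inf, and \code{separated} is TRUE.
#' @export
fitHillTransition <- function(observations, method = c("binned", "binary"),
                              nBins = 20L) {
  method <- match.arg(method)
  obs <- observations[!is.na(observations$boundTcb2), ]
  if (!any(obs$assembled) || all(obs$assembled))
    stop("need both assembled and unassembled observations")
  hi <- obs$boundTcb2[obs$assembled]
  lo <- obs$boundTcb2[!obs$assembled]
  if (min(hi) > max(lo)) {
    k <- sqrt(max(max(lo), 1e-6) * min(hi))
    return(new("HillFitResult", model = HillModel(Inf, k), seN = NA_real_,
               seK = NA_real_, nObs = nrow(obs), separated = TRUE))
  }
  if (method == "binned") {
    ord <- order(obs$boundTcb2)
    bins <- cut(seq_along(ord), breaks = min(nBins, max(3, nrow(obs) %/% 5)),
                labels = FALSE)
    x <- tapply(obs$boundTcb2[ord], bins, mean)
    y <- tapply(obs$assembled[ord], bins, mean)
  } else {
    x <- obs$boundTcb2
    y <- as.numeric(obs$assembled)
  }
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  df <- df[df$x > 0 | df$y == 0, ]
  ## starting values from the 0.5 crossing and quartile spread
  k0 <- {
    above <- df$x[df$y >= 0.5]
    below <- df$x[df$y < 0.5]
    if (length(above) && length(below)) sqrt(min(above) * max(below))
    else median(df$x[df$x > 0])
  }
  n0 <- 5
  eps <- 1e-9
  fit <- minpack.lm::nlsLM(
    y ~ stats::plogis(N * (log(pmax(x, eps)) - log(K))),
    data = df, start = list(N = n0, K = k0),
    lower = c(0.1, max(min(df$x[df$x > 0]) * 0.1, eps)),
    upper = c(1000, max(df$x) * 10),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  new("HillFitResult", model = HillModel(cf[["N"]], cf[["K"]]),
      seN = unname(se[1]), seK = unname(se[2]),
      nObs = nrow(obs), separated = FALSE)
}

#' Assemble a stimulus-to-outcome phase portrait
#'
#' @param protocols list of \linkS4class{PulseProtocol}s.
#' @param outcomes parallel list of \linkS4class{NetworkOutcome}s (or label
#'   strings).
#' @return a \linkS4class{PhasePortrait}; duplicate (duration, intensity)
#'   protocols are resolved by majority vote with a tie flag.
#' @export
buildPhasePortrait <- function(protocols, outcomes) {
  stopifnot(length(protocols) == length(outcomes), length(protocols) > 0)
  labels <- vapply(outcomes, function(o)
    if (is(o, "NetworkOutcome")) o@label else as.character(o), character(1))
  df <- data.frame(
    duration = vapply(protocols, function(p) p@duration, numeric(1)),
    intensity = vapply(protocols, function(p) p@intensity, numeric(1)),
    label = labels)
  agg <- lapply(split(df, list(df$duration, df$intensity), drop = TRUE),
                function(g) {
    tab <- sort(table(g$label), decreasing = TRUE)
    data.frame(duration = g$duration[1], intensity = g$intensity[1],
               label = names(tab)[1],
               tie = length(tab) > 1 && tab[1] == tab[2])
  })
  entries <- do.call(rbind, agg)
  rownames(entries) <- NULL
  entries <- entries[order(entries$duration, entries$intensity), ]
  new("PhasePortrait", entries = entries)
}

#' D'Agostino K-squared normality test
#'
#' Combines the z-transformed sample skewness and kurtosis into
#' \code{K2 = z1^2 + z2^2}, referred to a chi-squared distribution with 2
#' degrees of freedom.
#'
#' @param x numeric sample (n >= 8 for the transforms to be valid).
#' @return list(statistic, p.value, z.skewness, z.kurtosis).
#' @export
dagostinoK2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino's K-squared test needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  ## skewness transform
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  ## kurtosis transform
  Eg2 <- -6 / (n + 1)
  varg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  Xk <- (g2 - Eg2) / sqrt(varg2)
  sqB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqB1 * (2 / sqB1 + sqrt(1 + 4 / sqB1^2))
  cbrt <- function(v) sign(v) * abs(v)^(1 / 3)
  z2 <- ((1 - 2 / (9 * A)) -
           cbrt((1 - 2 / A) / (1 + Xk * sqrt(2 / (A - 4))))) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z.skewness = z1, z.kurtosis = z2)
}

#' Compare two groups with normality screening and a t-test
#'
#' Runs D'Agostino's K-squared normality test on each group (skipped with a
#' warning when a group has fewer than 8 observations), then an unpaired
#' two-tailed t-test (pooled variance by default; Welch available).
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param method "pooled" or "welch".
#' @return a \linkS4class{GroupComparison}.
#' @export
compareGroups <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  pa <- pb <- NA_real_
  if (length(a) >= 8 && length(b) >= 8) {
    pa <- dagostinoK2(a)$p.value
    pb <- dagostinoK2(b)$p.value
  } else {
    warning("group(s) too small for the normality test; skipped")
  }
  tt <- t.test(a, b, var.equal = (method == "pooled"))
  new("GroupComparison", nA = length(a), nB = length(b),
      meanA = mean(a), meanB = mean(b), sdA = sd(a), sdB = sd(b),
      normalityPA = pa, normalityPB = pb,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = unname(tt$p.value), method = method)
}

#' Pooled two-tailed t-test from group summary statistics
#'
#' Closed-form unpaired pooled-variance t-test when only means, standard
#' deviations and sizes are available (as for published group summaries).
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries.
#' @return list(t, df, p).
#' @export
tTestFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB) {
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  tstat <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}
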
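#' @import methods
#' @importFrom stats coef density lm mad median pchisq plogis pt quantile
#'   residuals rnorm runif sd setNames t.test uniroot var vcov
#' @importFrom utils head modifyList packageVersion read.csv tail write.csv
#' @useDynLib uncage, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## Chemistry containers
## ---------------------------------------------------------------------------

#' A 1:1 calcium-binding species
#'
#' Describes one calcium-binding component of the reaction (a chelator, an
#' indicator dye, or the self-assembling protein treated as a single effective
#' binding site). Concentrations are micromolar, diffusion coefficients
#' square micrometres per second.
#'
#' @slot name single character label, unique within a panel.
#' @slot total total concentration of the species (uM).
#' @slot kd 1:1 dissociation constant for calcium (uM).
#' @slot D diffusion coefficient (um^2/s).
#' @slot mobile logical; immobile species are excluded from transport.
#' @export
setClass("BindingSpecies",
  slots = c(name = "character", total = "numeric", kd = "numeric",
            D = "numeric", mobile = "logical"))

setValidity("BindingSpecies", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@total) != 1L || is.na(object@total) || object@total < 0)
    msg <- c(msg, "'total' must be a single value >= 0")
  if (length(object@kd) != 1L || is.na(object@kd) || object@kd <= 0)
    msg <- c(msg, "'kd' must be a single value > 0")
  if (length(object@D) != 1L || is.na(object@D) || object@D < 0)
    msg <- c(msg, "'D' must be a single value >= 0")
  if (length(object@mobile) != 1L || is.na(object@mobile))
    msg <- c(msg, "'mobile' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @param name,total,kd,D,mobile see slot descriptions.
#' @rdname BindingSpecies-class
#' @export
BindingSpecies <- function(name, total, kd, D = 400, mobile = D > 0) {
  new("BindingSpecies", name = as.character(name), total = as.numeric(total),
      kd = as.numeric(kd), D = as.numeric(D), mobile = as.logical(mobile))
}

#' Reaction composition: all calcium-binding species plus total calcium
#'
#' @slot species list of \linkS4class{BindingSpecies} with unique names.
#' @slot totalCalcium total calcium in the reaction (uM), free plus bound.
#' @export
setClass("ReagentPanel",
  slots = c(species = "list", totalCalcium = "numeric"))

setValidity("ReagentPanel", function(object) {
  msg <- character()
  ok <- vapply(object@species, is, logical(1), class2 = "BindingSpecies")
  if (!all(ok)) msg <- c(msg, "'species' must all be BindingSpecies objects")
  nm <- vapply(object@species, function(s) s@name, character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "species names must be unique")
  if (length(object@totalCalcium) != 1L || is.na(object@totalCalcium) ||
      object@totalCalcium < 0)
    msg <- c(msg, "'totalCalcium' must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' @param species,totalCalcium see slot descriptions.
#' @rdname ReagentPanel-class
#' @export
ReagentPanel <- function(species = list(), totalCalcium = 0) {
  new("ReagentPanel", species = species, totalCalcium = as.numeric(totalCalcium))
}

#' @rdname ReagentPanel-class
#' @param object,x a \code{ReagentPanel}.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname ReagentPanel-class
#' @export
setMethod("speciesNames", "ReagentPanel", function(x)
  vapply(x@species, function(s) s@name, character(1)))

#' @rdname ReagentPanel-class
#' @export
setGeneric("totalCalcium", function(x) standardGeneric("totalCalcium"))

#' @rdname ReagentPanel-class
#' @export
setMethod("totalCalcium", "ReagentPanel", function(x) x@totalCalcium)

setMethod("show", "ReagentPanel", function(object) {
  cat("ReagentPanel with", length(object@species), "species; total Ca",
      object@totalCalcium, "uM\n")
  for (s in object@species)
    cat(sprintf("  %-14s total %8.3f uM  Kd %10.4g uM  D %6.1f um^2/s%s\n",
                s@name, s@total, s@kd, s@D, if (s@mobile) "" else "  (immobile)"))
})

#' Result of a competitive binding equilibrium
#'
#' @slot freeCa free calcium (uM).
#' @slot bound named numeric vector of calcium bound to each species (uM).
#' @export
setClass("EquilibriumState",
  slots = c(freeCa = "numeric", bound = "numeric"))

setValidity("EquilibriumState", function(object) {
  if (length(object@freeCa) != 1L || object@freeCa < 0)
    return("'freeCa' must be a single value >= 0")
  if (any(object@bound < -1e-9)) return("bound amounts must be >= 0")
  TRUE
})

setMethod("show", "EquilibriumState", function(object) {
  cat("EquilibriumState: free Ca", format(object@freeCa, digits = 6), "uM\n")
  if (length(object@bound)) {
    b <- paste(sprintf("%s=%.4g", names(object@bound), object@bound),
               collapse = ", ")
    cat("  bound (uM):", b, "\n")
  }
})

#' Hill input-output model
#'
#' \code{y = x^N / (K^N + x^N)} with Hill exponent \code{N} (\code{nHill})
#' and half-maximal input \code{K} (\code{kHalf}, uM).
#'
#' @slot nHill Hill exponent (dimensionless, > 0).
#' @slot kHalf half-maximal input (uM, > 0).
#' @export
setClass("HillModel", slots = c(nHill = "numeric", kHalf = "numeric"))

setValidity("HillModel", function(object) {
  msg <- character()
  if (length(object@nHill) != 1L || is.na(object@nHill) || object@nHill <= 0)
    msg <- c(msg, "'nHill' must be a single value > 0")
  if (length(object@kHalf) != 1L || is.na(object@kHalf) || object@kHalf <= 0)
    msg <- c(msg, "'kHalf' must be a single value > 0")
  if (length(msg)) msg else TRUE
})

#' @param nHill,kHalf see slot descriptions.
#' @rdname HillModel-class
#' @export
HillModel <- function(nHill, kHalf)
  new("HillModel", nHill = as.numeric(nHill), kHalf = as.numeric(kHalf))

setMethod("show", "HillModel", function(object)
  cat(sprintf("HillModel: nHill = %.4g, kHalf = %.4g uM\n",
              object@nHill, object@kHalf)))

#' Two-parameter saturation ("saturation growth") curve
#'
#' \code{y = a x / (b + x)}: \code{a} is the saturation level in intensity
#' units, \code{b} the dissociation constant in uM.
#'
#' @slot a saturation level (> 0).
#' @slot b half-saturation input (uM, > 0).
#' @export
setClass("SaturationCurve", slots = c(a = "numeric", b = "numeric"))

setValidity("SaturationCurve", function(object) {
  msg <- character()
  if (length(object@a) != 1L || is.na(object@a) || object@a <= 0)
    msg <- c(msg, "'a' must be a single value > 0")
  if (length(object@b) != 1L || is.na(object@b) || object@b <= 0)
    msg <- c(msg, "'b' must be a single value > 0")
  if (length(msg)) msg else TRUE
})

#' @param a,b see slot descriptions.
#' @rdname SaturationCurve-class
#' @export
SaturationCurve <- function(a, b)
  new("SaturationCurve", a = as.numeric(a), b = as.numeric(b))

setMethod("show", "SaturationCurve", function(object)
  cat(sprintf("SaturationCurve: a = %.6g, b = %.6g uM\n", object@a, object@b)))

## ---------------------------------------------------------------------------
## Stimulus and simulation containers
## ---------------------------------------------------------------------------

#' Optical stimulation protocol
#'
#' A circular region of interest (ROI) illuminated for a fixed duration at a
#' fixed intensity. Physical coordinates are micrometres from the top-left
#' pixel centre.
#'
#' @slot center (x, y) of the ROI centre (um).
#' @slot diameter ROI diameter (um).
#' @slot duration pulse duration (s).
#' @slot intensity illumination intensity, percent of maximum (0-100).
#' @slot start pulse onset time (s) on the acquisition clock.
#' @export
setClass("PulseProtocol",
  slots = c(center = "numeric", diameter = "numeric", duration = "numeric",
            intensity = "numeric", start = "numeric"))

setValidity("PulseProtocol", function(object) {
  msg <- character()
  if (length(object@center) != 2L || anyNA(object@center))
    msg <- c(msg, "'center' must be (x, y) in um")
  if (length(object@diameter) != 1L || object@diameter <= 0)
    msg <- c(msg, "'diameter' must be > 0")
  if (length(object@duration) != 1L || object@duration <= 0)
    msg <- c(msg, "'duration' must be > 0")
  if (length(object@intensity) != 1L || object@intensity < 0 ||
      object@intensity > 100)
    msg <- c(msg, "'intensity' must lie in [0, 100]")
  if (length(object@start) != 1L || object@start < 0)
    msg <- c(msg, "'start' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param center,diameter,duration,intensity,start see slot descriptions.
#' @rdname PulseProtocol-class
#' @export
PulseProtocol <- function(center, diameter = 50, duration = 5,
                          intensity = 100, start = 0.5) {
  new("PulseProtocol", center = as.numeric(center),
      diameter = as.numeric(diameter), duration = as.numeric(duration),
      intensity = as.numeric(intensity), start = as.numeric(start))
}

setMethod("show", "PulseProtocol", function(object)
  cat(sprintf(
    "PulseProtocol: ROI %g um at (%g, %g) um; %g s pulse @ %g%% from t = %g s\n",
    object@diameter, object@center[1], object@center[2], object@duration,
    object@intensity, object@start)))

#' Forward-simulation configuration
#'
#' Groups the grid geometry, reagent panel, photolysis and assembly kinetics,
#' and the camera model. Build with \code{\link{defaultSimulationConfig}} and
#' override fields as needed.
#'
#' @slot gridShape (ny, nx) pixels.
#' @slot pixelSize um per pixel.
#' @slot frameInterval s between rendered frames.
#' @slot timeStep integration substep (s); 0 requests the automatic choice
#'   \code{min(frameInterval/20, 0.9 * pixelSize^2 / (4 * Dmax))}.
#' @slot panel \linkS4class{ReagentPanel}.
#' @slot kPhotolysisMax photolysis rate constant at 100\% intensity (1/s).
#' @slot transition \linkS4class{HillModel} for the assembly propensity as a
#'   function of calcium-bound protein (uM).
#' @slot hysteresis fraction in [0, 1): disassembly engages only once the
#'   propensity falls below (1 - hysteresis) times the assembled fraction.
#' @slot kAssembly,kDisassembly first-order relaxation rates (1/s).
#' @slot immobilizeCutoff assembled fraction above which the local network is
#'   immobile and protected from disassembly.
#' @slot maxPacking density cap of the assembled phase, as a multiple of the
#'   panel's initial protein total; further monomer addition stops at the cap
#'   (volume exclusion), so growth proceeds at the network edge.
#' @slot dyeCurve \linkS4class{SaturationCurve} mapping free calcium to
#'   fluorescence (b must equal the indicator Kd).
#' @slot cameraOffset,noiseSd fluorescence camera offset and Gaussian read
#'   noise sd (intensity units).
#' @slot bleachRate indicator photobleaching rate (1/s of cumulative exposure).
#' @slot bfOffset,bfNoiseSd brightfield background level and noise sd.
#' @slot textureContrast sd of the zero-mean speckle added per unit assembled
#'   fraction in the brightfield channel.
#' @slot seed integer RNG seed for rendering.
#' @export
setClass("SimulationConfig",
  slots = c(gridShape = "integer", pixelSize = "numeric",
            frameInterval = "numeric", timeStep = "numeric",
            panel = "ReagentPanel", kPhotolysisMax = "numeric",
            transition = "HillModel", hysteresis = "numeric",
            kAssembly = "numeric", kDisassembly = "numeric",
            immobilizeCutoff = "numeric", maxPacking = "numeric",
            dyeCurve = "SaturationCurve",
            cameraOffset = "numeric", noiseSd = "numeric",
            bleachRate = "numeric", bfOffset = "numeric",
            bfNoiseSd = "numeric", textureContrast = "numeric",
            seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 2L || any(object@gridShape < 4L))
    msg <- c(msg, "'gridShape' must be (ny, nx) with both >= 4")
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "'frameInterval' must be > 0")
  for (nm in c("kPhotolysisMax", "kAssembly", "kDisassembly", "bleachRate",
               "noiseSd", "bfNoiseSd", "textureContrast"))
    if (slot(object, nm) < 0) msg <- c(msg, paste0("'", nm, "' must be >= 0"))
  if (object@hysteresis < 0 || object@hysteresis >= 1)
    msg <- c(msg, "'hysteresis' must lie in [0, 1)")
  if (object@immobilizeCutoff <= 0 || object@immobilizeCutoff > 1)
    msg <- c(msg, "'immobilizeCutoff' must lie in (0, 1]")
  if (object@maxPacking <= 0) msg <- c(msg, "'maxPacking' must be > 0")
  dmax <- max(c(vapply(object@panel@species, function(s) s@D, numeric(1)),
                .D_FREE_CA))
  bound <- object@pixelSize^2 / (4 * dmax)
  if (object@timeStep > 0 && object@timeStep > bound)
    msg <- c(msg, sprintf(
      "timeStep %.3g s violates the diffusion stability bound %.3g s",
      object@timeStep, bound))
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d x %d px @ %g um; frame %g s; dt %g s; seed %d\n",
    object@gridShape[1], object@gridShape[2], object@pixelSize,
    object@frameInterval, effectiveTimeStep(object), object@seed))
  cat(sprintf("  k_photolysis(100%%) = %.3g /s; transition nH = %.3g, K = %.3g uM\n",
              object@kPhotolysisMax, object@transition@nHill,
              object@transition@kHalf))
  show(object@panel)
})

#' Spatial state of the reaction-diffusion simulation
#'
#' Per-species total-concentration maps (uM), the immobile assembled protein
#' map, exchangeable total calcium, and the last equilibrium partition.
#' Matrices are (ny, nx).
#'
#' @slot totals named list of per-species total maps (uM); for the
#'   self-assembling protein this is the soluble pool only.
#' @slot assembled assembled protein map (uM); carries one sequestered
#'   calcium per monomer, excluded from the exchange pool.
#' @slot caExchange exchangeable total calcium map (uM).
#' @slot freeCa,bound equilibrium partition of \code{caExchange} at the last
#'   equilibration (free map; named list of bound maps).
#' @slot elapsed simulation time (s).
#' @export
setClass("FieldState",
  slots = c(totals = "list", assembled = "matrix", caExchange = "matrix",
            freeCa = "matrix", bound = "list", elapsed = "numeric"))

setValidity("FieldState", function(object) {
  msg <- character()
  if (any(vapply(object@totals, function(m) any(m < -1e-9), logical(1))))
    msg <- c(msg, "species totals must be >= 0")
  if (any(object@assembled < -1e-9)) msg <- c(msg, "'assembled' must be >= 0")
  if (any(object@caExchange < -1e-9)) msg <- c(msg, "'caExchange' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Time-ordered single-channel image stack
#'
#' @slot frames numeric array (ny, nx, nframes).
#' @slot pixelSize um per pixel (> 0).
#' @slot frameInterval s between frames (> 0).
#' @slot channel label, e.g. "fluorescence" or "brightfield".
#' @slot clockOrigin acquisition-clock time of the first frame (s).
#' @export
setClass("ImageStack",
  slots = c(frames = "array", pixelSize = "numeric", frameInterval = "numeric",
            channel = "character", clockOrigin = "numeric"))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "'frames' must be a (ny, nx, nframes) array")
  if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "'frameInterval' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param frames,pixelSize,frameInterval,channel,clockOrigin see slots.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(frames, pixelSize, frameInterval,
                       channel = "unknown", clockOrigin = 0) {
  if (length(dim(frames)) == 2L)
    frames <- array(frames, c(dim(frames), 1L))
  new("ImageStack", frames = frames, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval), channel = as.character(channel),
      clockOrigin = as.numeric(clockOrigin))
}

#' @rdname ImageStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ImageStack-class
#' @param x an \code{ImageStack}.
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3])

#' @rdname ImageStack-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname ImageStack-class
#' @export
setMethod("frameTimes", "ImageStack", function(x)
  x@clockOrigin + (seq_len(nFrames(x)) - 1L) * x@frameInterval)

#' @rdname ImageStack-class
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname ImageStack-class
#' @param i frame index.
#' @export
setMethod("getFrame", "ImageStack", function(x, i) x@frames[, , i])

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ImageStack '%s': %d frames of %d x %d px @ %g um, every %g s (t0 = %g s)\n",
    object@channel, d[3], d[1], d[2], object@pixelSize, object@frameInterval,
    object@clockOrigin))
})

#' Simulated two-channel movie with retained ground truth
#'
#' @slot fluorescence,brightfield rendered \linkS4class{ImageStack}s.
#' @slot truthFreeCa,truthBoundTcb2 ground-truth concentration stacks (uM);
#'   bound protein includes the sequestered assembled pool.
#' @slot truthAssembledFraction assembled-fraction stack in [0, 1].
#' @slot truthTraces data.frame of per-frame ROI-centre ground truth
#'   (time, freeCa, boundTcb2, assembledFraction).
#' @slot protocol,config the generating stimulus and configuration.
#' @export
setClass("SyntheticMovie",
  slots = c(fluorescence = "ImageStack", brightfield = "ImageStack",
            truthFreeCa = "array", truthBoundTcb2 = "array",
            truthAssembledFraction = "array", truthTraces = "data.frame",
            protocol = "PulseProtocol", config = "SimulationConfig"))

setValidity("SyntheticMovie", function(object) {
  d <- dim(object@fluorescence@frames)
  same <- identical(d, dim(object@brightfield@frames)) &&
    identical(d, dim(object@truthFreeCa)) &&
    identical(d, dim(object@truthBoundTcb2)) &&
    identical(d, dim(object@truthAssembledFraction))
  if (!same) return("all channels and truth stacks must share dimensions")
  TRUE
})

setMethod("show", "SyntheticMovie", function(object) {
  cat("SyntheticMovie\n  ")
  show(object@protocol)
  cat("  ")
  show(object@fluorescence)
})

## ---------------------------------------------------------------------------
## Calibration containers
## ---------------------------------------------------------------------------

#' Fitted indicator calibration
#'
#' @slot curve fitted \linkS4class{SaturationCurve}.
#' @slot residualRms root-mean-square fit residual (intensity units).
#' @slot linearRangeMax free-calcium level (uM) where the local slope of the
#'   saturation curve falls to half its initial value (analytically = b).
#' @slot nPoints number of calibration points used.
#' @export
setClass("CalibrationFit",
  slots = c(curve = "SaturationCurve", residualRms = "numeric",
            linearRangeMax = "numeric", nPoints = "integer"))

setValidity("CalibrationFit", function(object) {
  msg <- character()
  if (object@residualRms < 0) msg <- c(msg, "'residualRms' must be >= 0")
  if (object@linearRangeMax <= 0) msg <- c(msg, "'linearRangeMax' must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationFit", function(object)
  cat(sprintf(
    "CalibrationFit: a = %.6g, b = %.6g uM (linear range < %.4g uM), rms %.3g, n = %d\n",
    object@curve@a, object@curve@b, object@linearRangeMax, object@residualRms,
    object@nPoints)))

#' Spatiotemporal photobleaching reference
#'
#' Per-pixel, per-frame multiplicative decay factors relative to the first
#' frame of a saturated-indicator reference stack (first frame identically 1).
#'
#' @slot factors array (ny, nx, nframes), values > 0 where valid, NA where the
#'   first frame was unusable.
#' @slot source label describing the reference stack.
#' @slot offset camera offset subtracted before forming the ratios.
#' @export
setClass("BleachReference",
  slots = c(factors = "array", source = "character", offset = "numeric"))

setMethod("show", "BleachReference", function(object) {
  d <- dim(object@factors)
  cat(sprintf(
    "BleachReference ('%s'): %d frames of %d x %d px; median final factor %.3f\n",
    object@source, d[3], d[1], d[2],
    median(object@factors[, , d[3]], na.rm = TRUE)))
})

## ---------------------------------------------------------------------------
## Tracking containers
## ---------------------------------------------------------------------------

#' Parameters of the edge -> blur -> threshold network detector
#'
#' @slot blurRadius Gaussian blur sigma applied to the edge-magnitude image
#'   (px; default 5).
#' @slot thresholdMode "background-robust" (median + thresholdK * MAD of the
#'   blurred edge image over pre-pulse frames) or "fixed".
#' @slot thresholdK robust-threshold multiplier.
#' @slot fixedThreshold threshold used when \code{thresholdMode == "fixed"}.
#' @slot minArea minimum connected-component area kept (px^2).
#' @slot nSectors angular sectors used for outer-boundary circle fitting.
#' @slot persistence consecutive detected frames required before a detection
#'   is accepted.
#' @export
setClass("DetectionParams",
  slots = c(blurRadius = "numeric", thresholdMode = "character",
            thresholdK = "numeric", fixedThreshold = "numeric",
            minArea = "numeric", nSectors = "integer", persistence = "integer"))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@blurRadius <= 0) msg <- c(msg, "'blurRadius' must be > 0")
  if (!object@thresholdMode %in% c("background-robust", "fixed"))
    msg <- c(msg, "'thresholdMode' must be 'background-robust' or 'fixed'")
  if (object@minArea < 1) msg <- c(msg, "'minArea' must be >= 1")
  if (object@nSectors < 4L) msg <- c(msg, "'nSectors' must be >= 4")
  if (object@persistence < 1L) msg <- c(msg, "'persistence' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param blurRadius,thresholdMode,thresholdK,fixedThreshold,minArea,nSectors,persistence
#'   see slot descriptions.
#' @rdname DetectionParams-class
#' @export
DetectionParams <- function(blurRadius = 5, thresholdMode = "background-robust",
                            thresholdK = 6, fixedThreshold = NA_real_,
                            minArea = 20, nSectors = 36L, persistence = 2L) {
  new("DetectionParams", blurRadius = as.numeric(blurRadius),
      thresholdMode = thresholdMode, thresholdK = as.numeric(thresholdK),
      fixedThreshold = as.numeric(fixedThreshold), minArea = as.numeric(minArea),
      nSectors = as.integer(nSectors), persistence = as.integer(persistence))
}

#' Radial boundary trace of a growing network
#'
#' @slot times frame times (s, strictly increasing).
#' @slot radii fitted boundary radii (um; NA where not detected).
#' @slot detected logical per frame.
#' @slot center (x, y) tracking centre (um).
#' @slot pixelSize um per pixel of the source stack.
#' @export
setClass("BoundaryTrace",
  slots = c(times = "numeric", radii = "numeric", detected = "logical",
            center = "numeric", pixelSize = "numeric"))

setValidity("BoundaryTrace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@radii) != n || length(object@detected) != n)
    msg <- c(msg, "'times', 'radii', 'detected' must share length")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (any(object@radii[object@detected] < 0, na.rm = TRUE))
    msg <- c(msg, "detected radii must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BoundaryTrace", function(object) {
  nd <- sum(object@detected)
  cat(sprintf("BoundaryTrace: %d frames, %d detected", length(object@times), nd))
  if (nd > 0)
    cat(sprintf("; max radius %.2f um", max(object@radii, na.rm = TRUE)))
  cat("\n")
})

#' Categorical outcome of a stimulation experiment
#'
#' @slot label "none", "transient", "sustained", or "ambiguous".
#' @slot delay s from pulse onset to first accepted detection (NA if none).
#' @slot maxRadius maximum detected radius (um; NA if none).
#' @slot initialGrowthRate um/s over the first detected frames (NA if none).
#' @export
setClass("NetworkOutcome",
  slots = c(label = "character", delay = "numeric", maxRadius = "numeric",
            initialGrowthRate = "numeric"))

setValidity("NetworkOutcome", function(object) {
  if (!object@label %in% c("none", "transient", "sustained", "ambiguous"))
    return("label must be none/transient/sustained/ambiguous")
  if (object@label == "none" &&
      !(is.na(object@delay) && is.na(object@maxRadius) &&
        is.na(object@initialGrowthRate)))
    return("label 'none' implies all quantitative fields are NA")
  TRUE
})

setMethod("show", "NetworkOutcome", function(object)
  cat(sprintf(
    "NetworkOutcome: %s (delay %.3g s, max radius %.3g um, initial rate %.3g um/s)\n",
    object@label, object@delay, object@maxRadius, object@initialGrowthRate)))

## ---------------------------------------------------------------------------
## Inference containers
## ---------------------------------------------------------------------------

#' Inferred calcium-bound protein stack
#'
#' @slot conc array (ny, nx, nframes) of inferred bound-protein
#'   concentrations (uM), negatives floored at 0.
#' @slot mode estimator used ("linear-slope", "inversion-difference" or
#'   "buffer-corrected").
#' @slot flooredFraction fraction of pixels whose raw estimate was negative.
#' @slot pixelSize,frameInterval,times geometry and clock of the source stacks.
#' @export
setClass("BoundTcb2Stack",
  slots = c(conc = "array", mode = "character", flooredFraction = "numeric",
            pixelSize = "numeric", frameInterval = "numeric", times = "numeric"))

setMethod("show", "BoundTcb2Stack", function(object) {
  d <- dim(object@conc)
  cat(sprintf(
    "BoundTcb2Stack (%s): %d frames of %d x %d px; %.1f%% pixels floored\n",
    object@mode, d[3], d[1], d[2], 100 * object@flooredFraction))
})

#' One (bound protein, assembled?) observation
#'
#' Plain data.frame rows are used for pooled fitting; this constructor
#' documents the expected columns.
#'
#' @param boundTcb2 inferred calcium-bound protein (uM).
#' @param assembled logical assembly status.
#' @param pulseId label of the source pulse.
#' @param time observation time (s).
#' @return data.frame with columns boundTcb2, assembled, pulseId, time.
#' @export
AssemblyObservation <- function(boundTcb2, assembled, pulseId = "pulse", time = NA_real_) {
  stopifnot(all(boundTcb2 >= 0), is.logical(assembled))
  data.frame(boundTcb2 = boundTcb2, assembled = assembled,
             pulseId = pulseId, time = time)
}

#' Fitted ultrasensitive transition
#'
#' @slot model fitted \linkS4class{HillModel}.
#' @slot seN,seK standard errors of the exponent and midpoint.
#' @slot nObs observations used.
#' @slot separated TRUE when the two classes did not overlap, leaving the
#'   exponent effectively unbounded.
#' @export
setClass("HillFitResult",
  slots = c(model = "HillModel", seN = "numeric", seK = "numeric",
            nObs = "integer", separated = "logical"))

setMethod("show", "HillFitResult", function(object)
  cat(sprintf(
    "HillFitResult: nHill = %.4g +/- %.2g, kHalf = %.4g +/- %.2g uM (n = %d)%s\n",
    object@model@nHill, object@seN, object@model@kHalf, object@seK,
    object@nObs, if (object@separated) "  [classes separated: nHill unbounded]" else "")))

#' Stimulus-to-outcome phase portrait
#'
#' @slot entries data.frame (duration, intensity, label, tie) with one row per
#'   unique protocol; 'tie' flags duplicate protocols resolved by majority.
#' @export
setClass("PhasePortrait", slots = c(entries = "data.frame"))

setMethod("show", "PhasePortrait", function(object) {
  cat("PhasePortrait:", nrow(object@entries), "protocol cells\n")
  print(table(object@entries$label))
})

#' Two-group comparison with normality screening
#'
#' @slot nA,nB,meanA,meanB,sdA,sdB group summaries.
#' @slot normalityPA,normalityPB D'Agostino K-squared p-values (NA when the
#'   group was too small for the test).
#' @slot t,df,p two-tailed t-test results.
#' @slot method "pooled" or "welch".
#' @export
setClass("GroupComparison",
  slots = c(nA = "integer", nB = "integer", meanA = "numeric", meanB = "numeric",
            sdA = "numeric", sdB = "numeric", normalityPA = "numeric",
            normalityPB = "numeric", t = "numeric", df = "numeric",
            p = "numeric", method = "character"))

setMethod("show", "GroupComparison", function(object)
  cat(sprintf(
    "GroupComparison (%s): %.4g (sd %.3g, n=%d) vs %.4g (sd %.3g, n=%d): t = %.4g, df = %.4g, p = %.3g\n",
    object@method, object@meanA, object@sdA, object@nA, object@meanB,
    object@sdB, object@nB, object@t, object@df, object@p)))
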
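# Shared fixtures: everything is generated in code at test time.

# small, fast simulation configuration used across tests
smallConfig <- function(n = 32L, pixelSize = 3, seed = 1L, ...) {
  defaultSimulationConfig(gridShape = c(n, n), pixelSize = pixelSize,
                          seed = seed, ...)
}

# the working scale used for pipeline-level checks
midConfig <- function(seed = 1L, ...) {
  defaultSimulationConfig(gridShape = c(64L, 64L), pixelSize = 2,
                          seed = seed, ...)
}

# detection parameters matched to the coarse (2-3 um/px) test grids: the
# 5 px default blur is meant for fine-pixel data; here 1 px ~ 2-3 um
coarseDetection <- function() {
  DetectionParams(blurRadius = 1, thresholdK = 8, minArea = 4)
}

# pulse centred on the field
centerPulse <- function(config, diameter = 50, duration = 5, intensity = 100,
                        start = 0.5) {
  ctr <- (rev(config@gridShape) - 1) / 2 * config@pixelSize
  PulseProtocol(center = ctr, diameter = diameter, duration = duration,
                intensity = intensity, start = start)
}

# exact calibration fit matching a config's camera model
dyeCalibration <- function(config) {
  new("CalibrationFit", curve = config@dyeCurve, residualRms = 0,
      linearRangeMax = config@dyeCurve@b, nPoints = 12L)
}

# paired +/- protein movies with the full correction chain applied;
# returns the experimental movie, corrected stacks and a bound-protein stack
runPairedPulse <- function(config, protocol, nFrames,
                           mode = "buffer-corrected") {
  mvE <- runSimulation(config, protocol, nFrames, withTcb2 = TRUE)
  cfgR <- config
  cfgR@seed <- config@seed + 1000L
  mvR <- runSimulation(cfgR, protocol, nFrames, withTcb2 = FALSE)
  sat <- makeSaturatedReferenceStack(config, nFrames)
  bref <- buildBleachReference(sat, offset = config@cameraOffset)
  refC <- applyBleachCorrection(mvR@fluorescence, bref)
  expC <- applyBleachCorrection(mvE@fluorescence, bref)
  delta <- deltaIntensity(refC, expC)
  bstack <- suppressWarnings(boundTcb2FromDelta(
    delta, dyeCalibration(config), mode = mode, refStack = refC,
    panel = config@panel, offset = config@cameraOffset,
    protocol = protocol, kPhot = config@kPhotolysisMax))
  list(exp = mvE, ref = mvR, refC = refC, expC = expC, delta = delta,
       bstack = bstack)
}

# random reagent panel for property tests
randomPanel <- function(nSpecies, totalCa) {
  sp <- lapply(seq_len(nSpecies), function(i)
    BindingSpecies(paste0("s", i), total = runif(1, 1, 500),
                   kd = 10^runif(1, -2, 3.5)))
  ReagentPanel(sp, totalCalcium = totalCa)
}

# scalar bisection oracle for the equilibrium mass balance (independent of
# the package's Newton-based solver)
bisectFreeCa <- function(total, B, K, tol = 1e-12) {
  if (total <= 0) return(0)
  g <- function(f) f + sum(B * f / (K + f)) - total
  uniroot(g, c(0, total), tol = tol)$root
}
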
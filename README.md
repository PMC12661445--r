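# uncage

Quantitative tools for microscopy assays in which light-triggered uncaging
of a photocaged calcium chelator (DMNP-EDTA) actuates calcium-dependent
self-assembly of an EF-hand protein (Tcb2), read out with the low-affinity
fluorescent calcium indicator Rhod-5N and brightfield imaging. The package
is written for experimentalists running such optical-actuation assays and
for modellers studying ultrasensitive, calcium-gated protein condensation.

It provides two connected halves:

* **A reaction–diffusion forward simulator.** ROI-restricted photolysis
  switches the caged chelator's calcium affinity (5 nM → 3 mM); released
  calcium diffuses and re-equilibrates among competing 1:1 buffers (EGTA,
  indicator, protein) under the rapid-buffering approximation; the
  assembled protein fraction relaxes toward a Hill propensity
  `p = x^N / (K^N + x^N)` of the local calcium-loaded protein `x`
  (defaults N = 23.1, K = 93 µM) with hysteresis and a density cap; both
  camera channels (saturation-law fluorescence with photobleaching and
  read noise; speckle-textured brightfield) are rendered with full ground
  truth retained. The stiff inner loop is compiled (Rcpp).

* **The analysis chain.** Standard-curve fitting of the two-parameter
  saturation-growth law `y = a x / (b + x)` and pixel-level inversion to
  free calcium; spatiotemporal photobleaching correction from a
  saturated-indicator reference; Sobel → blur → threshold → circle-fit
  tracking of the radial network boundary, with delay, growth-rate and
  sustained/transient/none classification; dual-channel competition
  inference of calcium-bound protein from the fluorescence deficit
  `ΔI = I_ref − I_exp`; pooled Hill-transition fitting; phase portraits;
  and group comparisons (D'Agostino K² normality screen plus unpaired
  two-tailed t-tests).

## Worked example

Simulate a delayed-onset pulse, run the dual-channel inference, and read
the bound-protein concentration on the growing network boundary:

```r
library(uncage)

cfg  <- defaultSimulationConfig(gridShape = c(64L, 64L), pixelSize = 2,
                                seed = 17L)
pr   <- PulseProtocol(center = c(63, 63), diameter = 50, duration = 8,
                      intensity = 45, start = 0.5)
exp  <- runSimulation(cfg, pr, nFrames = 90)                 # with protein
cfgR <- cfg; cfgR@seed <- 1017L
ref  <- runSimulation(cfgR, pr, nFrames = 90, withTcb2 = FALSE)

sat   <- makeSaturatedReferenceStack(cfg, 90)
bref  <- buildBleachReference(sat, offset = cfg@cameraOffset)
refC  <- applyBleachCorrection(ref@fluorescence, bref)
expC  <- applyBleachCorrection(exp@fluorescence, bref)
fit   <- new("CalibrationFit", curve = cfg@dyeCurve, residualRms = 0,
             linearRangeMax = 230, nPoints = 12L)
# suppressWarnings: outside the ROI the difference of two noisy frames is
# negative half the time; the estimator floors and flags those pixels
bound <- suppressWarnings(
  boundTcb2FromDelta(deltaIntensity(refC, expC), fit,
                     mode = "buffer-corrected", refStack = refC,
                     panel = cfg@panel, offset = cfg@cameraOffset,
                     protocol = pr, kPhot = cfg@kPhotolysisMax))

dp  <- DetectionParams(blurRadius = 1, thresholdK = 8, minArea = 4)
trc <- trackRadius(exp@brightfield, pr@center, dp, prePulseFrames = 1:4)
extractDelay(trc, pr)
#> [1] 3.7
mean(boundaryConcentration(bound, trc)$boundary)
#> [1] 94.88738
```

The delay is the 3.7 s between pulse onset and the first accepted network
detection (a delayed-onset, mid-intensity pulse), and ~95 µM is the mean
inferred calcium-bound protein on the fitted boundary annulus — the
concentration at which protein is crossing from soluble to assembled,
within a few percent of the 93 µM critical concentration this simulation
plants by default.

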
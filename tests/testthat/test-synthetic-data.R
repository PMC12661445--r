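# Forward model: photolysis, diffusion, equilibration, assembly, rendering.

test_that("photolysis converts caged chelator exponentially inside the ROI only", {
  cfg <- smallConfig(n = 16L)
  # pulse window open from t = 0, ROI covering the left half of the field
  pr <- PulseProtocol(center = c(0, 22.5), diameter = 40, duration = 100,
                      intensity = 100, start = 0)
  st <- initializeFieldState(cfg)
  mask <- roiPixelMask(cfg, pr)
  expect_true(any(mask) && !all(mask))
  kEff <- cfg@kPhotolysisMax
  dt <- 1e-3 / kEff
  st1 <- st
  for (i in 1:400) st1 <- stepPhotolysis(st1, pr, cfg, dt)
  inside <- st1@totals[["DMNP.caged"]][mask]
  outside <- st1@totals[["DMNP.caged"]][!mask]
  expect_equal(unique(round(inside, 9)),
               round(500 * exp(-kEff * 400 * dt), 9), tolerance = 1e-7)
  expect_equal(outside, rep(500, sum(!mask)))
  # chelator mass conserved pixelwise
  tot <- st1@totals[["DMNP.caged"]] + st1@totals[["DMNP.photolyzed"]]
  expect_equal(as.vector(tot), rep(500, 256), tolerance = 1e-12)

  # zero intensity leaves the state untouched
  pr0 <- PulseProtocol(center = c(0, 22.5), diameter = 40, duration = 100,
                       intensity = 0, start = 0)
  st2 <- stepPhotolysis(st, pr0, cfg, 0.01)
  expect_identical(st2@totals, st@totals)
})

test_that("diffusion reproduces the 2-D heat kernel and conserves mass", {
  n <- 61L
  D <- 300
  panel <- ReagentPanel(list(BindingSpecies("s", 0, 1, D = D)), 0)
  cfg <- defaultSimulationConfig(gridShape = c(n, n), pixelSize = 1,
                                 panel = panel)
  st <- initializeFieldState(cfg)
  st@totals[["s"]][31, 31] <- 1000
  dt <- effectiveTimeStep(cfg)
  nSteps <- 150L
  for (i in seq_len(nSteps)) st <- stepDiffusion(st, cfg, dt)
  tt <- nSteps * dt
  r2 <- outer((seq_len(n) - 31)^2, (seq_len(n) - 31)^2, "+")
  kern <- 1000 * exp(-r2 / (4 * D * tt)) / (4 * pi * D * tt)
  num <- st@totals[["s"]]
  expect_lt(sqrt(sum((num - kern)^2) / sum(kern^2)), 0.01)
  expect_equal(sum(num), 1000, tolerance = 1e-9)

  # uniform field is a fixed point
  st2 <- initializeFieldState(cfg)
  st2@totals[["s"]][] <- 7
  st3 <- stepDiffusion(st2, cfg, dt)
  expect_equal(st3@totals[["s"]], st2@totals[["s"]])

  # stability guard
  expect_error(stepDiffusion(st2, cfg, 1), "stability")
})

test_that("per-pixel equilibration delegates to the scalar solver", {
  cfg <- smallConfig(n = 8L)
  st <- initializeFieldState(cfg)
  set.seed(5)
  st@caExchange <- matrix(runif(64, 0, 600), 8)
  st <- stepEquilibrate(st, cfg)
  B <- vapply(cfg@panel@species, function(s) s@total, numeric(1))
  K <- vapply(cfg@panel@species, function(s) s@kd, numeric(1))
  for (i in c(1, 13, 64)) {
    expect_equal(as.vector(st@freeCa)[i],
                 bisectFreeCa(as.vector(st@caExchange)[i], B, K),
                 tolerance = 1e-8)
  }
  # zero calcium: everything empty
  st@caExchange[] <- 0
  st <- stepEquilibrate(st, cfg)
  expect_true(all(st@freeCa == 0))
  expect_true(all(vapply(st@bound, function(m) all(m == 0), logical(1))))
})

test_that("assembly relaxes toward the Hill propensity with first-order kinetics", {
  cfg <- smallConfig(n = 8L)
  st <- initializeFieldState(cfg)

  # zero load: nothing assembles
  st0 <- st
  st0@bound[["Tcb2"]][] <- 0
  for (i in 1:50) st0 <- stepAssembly(st0, cfg, 0.01)
  expect_true(all(st0@assembled == 0))

  # load held exactly at the midpoint: phi(t) = 0.5 (1 - exp(-k t)) -> 0.5
  stH <- st
  stH@bound[["Tcb2"]][] <- cfg@transition@kHalf
  dt <- 0.005
  phiTrace <- numeric(0)
  for (i in 1:1200) {
    stH <- stepAssembly(stH, cfg, dt)
    stH@bound[["Tcb2"]][] <- cfg@transition@kHalf # hold the input
    if (i %% 100 == 0) phiTrace <- c(phiTrace, assembledFraction(stH)[1, 1])
  }
  tGrid <- seq_len(length(phiTrace)) * 100 * dt
  expect_equal(phiTrace, 0.5 * (1 - exp(-cfg@kAssembly * tGrid)),
               tolerance = 1e-2)
  expect_equal(tail(phiTrace, 1), 0.5, tolerance = 5e-3)

  # saturating load: full assembly
  stS <- st
  for (i in 1:1500) {
    stS@bound[["Tcb2"]][] <- 10 * cfg@transition@kHalf
    stS <- stepAssembly(stS, cfg, dt)
  }
  expect_gt(min(assembledFraction(stS)), 0.99)
})

test_that("rendering matches its closed forms", {
  cfg <- smallConfig(n = 8L)
  st <- initializeFieldState(cfg)

  # no dye-bound calcium, no noise: uniform camera offset
  st@bound[["Rhod5N"]][] <- 0
  fr <- renderFluorescence(st, cfg, 0, noise = FALSE)
  expect_equal(fr, matrix(cfg@cameraOffset, 8, 8))

  # affine in bound dye; known map reproduced exactly
  set.seed(9)
  st@bound[["Rhod5N"]] <- matrix(runif(64, 0, 25), 8)
  expo <- 3
  fr <- renderFluorescence(st, cfg, expo, noise = FALSE)
  gain <- cfg@dyeCurve@a / 25
  expect_equal(fr, cfg@cameraOffset +
                 exp(-cfg@bleachRate * expo) * gain * st@bound[["Rhod5N"]])

  # brightfield: pure background without assembly; speckle variance scales
  # with the assembled fraction
  cfgN <- smallConfig(n = 64L)
  stN <- initializeFieldState(cfgN)
  set.seed(1)
  bg <- renderBrightfield(stN, cfgN)
  expect_equal(sd(bg), cfgN@bfNoiseSd, tolerance = 0.1)
  stN@assembled[] <- stN@totals[["Tcb2"]][1, 1]
  stN@totals[["Tcb2"]][] <- 0
  full <- renderBrightfield(stN, cfgN)
  expect_equal(sd(full), sqrt(cfgN@bfNoiseSd^2 + cfgN@textureContrast^2),
               tolerance = 0.1)
})

test_that("compiled loop and R-level operator steps agree", {
  cfg <- smallConfig(n = 16L, seed = 2L)
  pr <- centerPulse(cfg, diameter = 30, duration = 1, intensity = 100,
                    start = 0)
  nFrames <- 2L
  mv <- runSimulation(cfg, pr, nFrames)

  dtEff <- effectiveTimeStep(cfg)
  steps <- as.integer(ceiling(cfg@frameInterval / dtEff))
  dt <- cfg@frameInterval / steps
  st <- initializeFieldState(cfg)
  for (fr in seq_len(nFrames)) {
    for (s in seq_len(steps)) st <- stepOnce(st, pr, cfg, dt)
    snap <- stepEquilibrate(st, cfg)
    expect_equal(snap@freeCa, mv@truthFreeCa[, , fr], tolerance = 1e-7)
    expect_equal(snap@bound[["Tcb2"]], mv@truthBoundTcb2[, , fr],
                 tolerance = 1e-7)
    expect_equal(assembledFraction(snap), mv@truthAssembledFraction[, , fr],
                 tolerance = 1e-7)
  }
})

test_that("simulations are deterministic given a seed and conserve mass", {
  cfg <- smallConfig(n = 16L, seed = 42L)
  pr <- centerPulse(cfg, diameter = 30, duration = 0.5, intensity = 80,
                    start = 0.2)
  m1 <- runSimulation(cfg, pr, 5L)
  m2 <- runSimulation(cfg, pr, 5L)
  expect_identical(m1@fluorescence@frames, m2@fluorescence@frames)
  expect_identical(m1@brightfield@frames, m2@brightfield@frames)
  expect_identical(m1@truthFreeCa, m2@truthFreeCa)

  # grid-total conservation through the R operator chain
  st <- initializeFieldState(cfg)
  dt <- effectiveTimeStep(cfg)
  tot0 <- c(ca = sum(st@caExchange),
            dmnp = sum(st@totals[["DMNP.caged"]] +
                         st@totals[["DMNP.photolyzed"]]),
            tcb2 = sum(st@totals[["Tcb2"]] + st@assembled),
            rhod = sum(st@totals[["Rhod5N"]]))
  for (i in 1:200) st <- stepOnce(st, pr, cfg, dt)
  tot1 <- c(ca = sum(st@caExchange),
            dmnp = sum(st@totals[["DMNP.caged"]] +
                         st@totals[["DMNP.photolyzed"]]),
            tcb2 = sum(st@totals[["Tcb2"]] + st@assembled),
            rhod = sum(st@totals[["Rhod5N"]]))
  expect_equal(tot1, tot0, tolerance = 1e-6)
})

test_that("expanding-disk phantom has the requested geometry", {
  cfg <- midConfig(seed = 8L)
  # 86 um/s at 0.5 um/px and 0.1 s frames advances 17.2 px per frame
  cfgF <- defaultSimulationConfig(gridShape = c(256L, 256L), pixelSize = 0.5,
                                  seed = 8L)
  ph <- makeExpandingDiskPhantom(86, cfgF, nFrames = 6, t0 = 0.1)
  expect_equal(diff(ph$truth$radius) / cfgF@pixelSize,
               rep(17.2, 5), tolerance = 1e-9)
  # zero rate: constant (zero) radius, never clipped
  ph0 <- makeExpandingDiskPhantom(0, cfg, nFrames = 4)
  expect_true(all(ph0$truth$radius == 0))
  # overgrown disk is clipped and flagged
  phC <- makeExpandingDiskPhantom(500, cfg, nFrames = 10, t0 = 0)
  expect_true(any(phC$truth$clipped))
  expect_lte(max(phC$truth$radius), min(ph0$center))
})

test_that("standard-curve frames have the configured means", {
  cv <- SaturationCurve(1000, 230)
  # noise-free: exact levels
  sf <- makeStandardCurveFrames(c(0, 230, 1000), cv, noiseSd = 0,
                                offset = 100)
  mu <- apply(sf$stack@frames, 3, mean)
  expect_equal(mu[1], 100)            # offset only
  expect_equal(mu[2], 100 + 500)      # half saturation
  expect_equal(mu, sf$table$true_mean)
  # noisy: sample mean within the CLT bound 3 sd/sqrt(Npix)
  sfN <- makeStandardCurveFrames(c(500), cv, noiseSd = 20, seed = 4L,
                                 offset = 100, shape = c(64L, 64L))
  expect_lt(abs(mean(sfN$stack@frames) - sfN$table$true_mean),
            3 * 20 / sqrt(64 * 64))
})

test_that("release is biphasic: burst then slow sustained phase", {
  cfg <- defaultSimulationConfig(gridShape = c(48L, 48L), pixelSize = 2.5,
                                 seed = 6L)
  pr <- centerPulse(cfg, duration = 3, intensity = 100, start = 0.5)
  mv <- runSimulation(cfg, pr, 35L, withTcb2 = FALSE)
  tr <- mv@truthTraces
  early <- unname(coef(lm(freeCa ~ time,
                          tr[tr$time >= 0.5 & tr$time <= 1.0, ]))[2])
  late <- unname(coef(lm(freeCa ~ time,
                         tr[tr$time >= 1.5 & tr$time <= 3.5, ]))[2])
  expect_gt(early, 5 * max(late, 1))
})

test_that("final assembled area is nondecreasing in pulse intensity", {
  areas <- vapply(c(30, 60, 100), function(it) {
    cfg <- defaultSimulationConfig(gridShape = c(48L, 48L), pixelSize = 2.5,
                                   seed = 21L)
    pr <- centerPulse(cfg, duration = 2, intensity = it, start = 0.3)
    mv <- runSimulation(cfg, pr, 30L)
    sum(mv@truthAssembledFraction[, , 30] > 0.5)
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_gt(areas[3], 0)
})

test_that("the engaging assembly front sits at the planted threshold", {
  cfg <- midConfig(seed = 23L)
  pr <- centerPulse(cfg, duration = 10, intensity = 40, start = 0.5)
  mv <- runSimulation(cfg, pr, 110L)
  trc <- trackRadius(mv@brightfield, pr@center, coarseDetection(),
                     prePulseFrames = 1:4)
  expect_true(any(trc@detected))
  k <- which(trc@detected)[1]
  phi <- mv@truthAssembledFraction[, , k]
  front <- phi > 0.05 & phi < 0.5 # pixels where assembly is just engaging
  expect_gt(sum(front), 10)
  expect_lt(abs(median(mv@truthBoundTcb2[, , k][front]) - 93) / 93, 0.1)
})
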
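## Forward model: ROI photolysis, buffered calcium diffusion, Hill-gated
## self-assembly, and rendering of the fluorescence and brightfield channels
## the analysis pipeline consumes. The per-substep loop runs in compiled code
## (src/sim_core.cpp); the R-level step functions below implement the same
## operators on a FieldState for unit testing and custom schemes, and are
## cross-checked against the compiled loop in the test suite.

#' Default reagent panel of the actuation assay
#'
#' 500 uM caged Ca.DMNP-EDTA (all calcium initially caged), 100 uM EGTA,
#' 25 uM Rhod-5N, and (optionally) 250 uM of the self-assembling protein,
#' modelled as a single effective 1:1 calcium-binding species whose bound
#' concentration is read as calcium-loaded protein.
#'
#' Dissociation constants: caged DMNP-EDTA 0.005 uM, photolyzed 3000 uM,
#' EGTA 0.15 uM, Rhod-5N 230 uM (in-assay value), protein 200 uM (effective).
#' Diffusion defaults: DMNP species \code{dDmnp}, other small molecules
#' 400 um^2/s, soluble protein \code{dTcb2}.
#'
#' @param tcb2Total total protein concentration (uM); 0 gives the dye-only
#'   reference composition.
#' @param tcb2Kd effective protein dissociation constant for calcium (uM).
#' @param rhodKd indicator dissociation constant (uM); 230 in-assay,
#'   ~320 per manufacturer.
#' @param egtaKd EGTA dissociation constant (uM).
#' @param dDmnp diffusion coefficient of the caged/photolyzed chelator
#'   (um^2/s). The default is the package calibration that reproduces the
#'   diffusion-limited sustained release rate (see the methods vignette).
#' @param dTcb2 diffusion coefficient of the soluble protein (um^2/s);
#'   default from the Stokes-Einstein estimate for a ~25 kDa globular
#'   protein.
#' @param totalCalcium total calcium (uM).
#' @return a \linkS4class{ReagentPanel}.
#' @export
defaultReagentPanel <- function(tcb2Total = 250, tcb2Kd = 200, rhodKd = 230,
                                egtaKd = 0.15, dDmnp = 600, dTcb2 = 400,
                                totalCalcium = 500) {
  ReagentPanel(list(
    BindingSpecies("DMNP.caged", 500, 0.005, D = dDmnp),
    BindingSpecies("DMNP.photolyzed", 0, 3000, D = dDmnp),
    BindingSpecies("EGTA", 100, egtaKd, D = 400),
    BindingSpecies("Rhod5N", 25, rhodKd, D = 400),
    BindingSpecies("Tcb2", tcb2Total, tcb2Kd, D = dTcb2)
  ), totalCalcium = totalCalcium)
}

#' Default simulation configuration
#'
#' @param gridShape (ny, nx) pixels.
#' @param pixelSize um per pixel.
#' @param frameInterval s between rendered frames.
#' @param panel a \linkS4class{ReagentPanel}.
#' @param kPhotolysisMax photolysis rate constant at 100\% intensity (1/s).
#'   The default is the package calibration that reproduces the burst-phase
#'   release rate (see the methods vignette).
#' @param transition assembly-propensity \linkS4class{HillModel}.
#' @param seed RNG seed for rendering.
#' @param ... further \linkS4class{SimulationConfig} slots to override.
#' @return a \linkS4class{SimulationConfig}.
#' @export
defaultSimulationConfig <- function(gridShape = c(96L, 96L), pixelSize = 2,
                                    frameInterval = 0.1,
                                    panel = defaultReagentPanel(),
                                    kPhotolysisMax = 2.11,
                                    transition = HillModel(23.1, 93),
                                    seed = 1L, ...) {
  args <- list(...)
  base <- list(gridShape = as.integer(gridShape), pixelSize = pixelSize,
               frameInterval = frameInterval, timeStep = 0,
               panel = panel, kPhotolysisMax = kPhotolysisMax,
               transition = transition, hysteresis = 0.1,
               kAssembly = 2, kDisassembly = 0.5, immobilizeCutoff = 0.85,
               maxPacking = 1.2, dyeCurve = SaturationCurve(1000, 230), cameraOffset = 100,
               noiseSd = 5, bleachRate = 0.02, bfOffset = 500, bfNoiseSd = 2,
               textureContrast = 30, seed = seed)
  base[names(args)] <- args
  base$seed <- as.integer(base$seed)
  base$gridShape <- as.integer(base$gridShape)
  do.call(new, c(list("SimulationConfig"), base))
}

#' Effective integration substep of a configuration
#'
#' \code{timeStep} if set, otherwise
#' \code{min(frameInterval/20, 0.9 * pixelSize^2 / (4 * Dmax))} where Dmax is
#' the largest diffusion coefficient in play (including free calcium).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return substep in seconds.
#' @export
effectiveTimeStep <- function(config) {
  dmax <- max(c(vapply(config@panel@species, function(s) s@D, numeric(1)),
                .D_FREE_CA))
  bound <- 0.9 * config@pixelSize^2 / (4 * dmax)
  if (config@timeStep > 0) config@timeStep else min(config@frameInterval / 20, bound)
}

.speciesIndex <- function(panel, name) {
  i <- match(name, speciesNames(panel))
  if (is.na(i)) -1L else as.integer(i)
}

#' Pixel mask of the illuminated ROI
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param protocol a \linkS4class{PulseProtocol}.
#' @return logical (ny, nx) matrix; TRUE inside the circular ROI.
#' @export
roiPixelMask <- function(config, protocol) {
  ny <- config@gridShape[1]; nx <- config@gridShape[2]; px <- config@pixelSize
  x <- ((seq_len(nx) - 1) * px)
  y <- ((seq_len(ny) - 1) * px)
  dx2 <- outer(rep(1, ny), (x - protocol@center[1])^2)
  dy2 <- outer((y - protocol@center[2])^2, rep(1, nx))
  (dx2 + dy2) <= (protocol@diameter / 2)^2
}

#' Initial uniform field state for a configuration
#'
#' All species totals uniform at their panel values, no assembled protein,
#' exchangeable calcium at the panel total, equilibrated once.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{FieldState}.
#' @export
initializeFieldState <- function(config) {
  ny <- config@gridShape[1]; nx <- config@gridShape[2]
  nm <- speciesNames(config@panel)
  totals <- lapply(config@panel@species,
                   function(s) matrix(s@total, ny, nx))
  names(totals) <- nm
  st <- new("FieldState", totals = totals,
            assembled = matrix(0, ny, nx),
            caExchange = matrix(config@panel@totalCalcium, ny, nx),
            freeCa = matrix(0, ny, nx),
            bound = setNames(lapply(nm, function(x) matrix(0, ny, nx)), nm),
            elapsed = 0)
  stepEquilibrate(st, config)
}

#' Assembled-fraction map of a field state
#'
#' @param state a \linkS4class{FieldState}.
#' @param proteinName species name of the self-assembling protein.
#' @return matrix in [0, 1].
#' @export
assembledFraction <- function(state, proteinName = "Tcb2") {
  tot <- state@totals[[proteinName]] + state@assembled
  out <- state@assembled
  pos <- tot > 1e-12
  out[pos] <- state@assembled[pos] / tot[pos]
  out[!pos] <- 0
  out
}

#' One photolysis substep
#'
#' Inside the ROI, while the pulse is on (window test at the substep
#' midpoint), the caged chelator decays at rate
#' \code{kPhotolysisMax * intensity / 100}; the lost mass transfers to the
#' photolyzed species so total chelator is conserved pixelwise. Does not
#' advance the clock (see \code{\link{stepOnce}}).
#'
#' @param state a \linkS4class{FieldState}.
#' @param protocol a \linkS4class{PulseProtocol}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param dt substep (s).
#' @return the updated state.
#' @export
stepPhotolysis <- function(state, protocol, config, dt) {
  stopifnot(dt > 0)
  tm <- state@elapsed + dt / 2
  if (protocol@intensity <= 0 || tm < protocol@start ||
      tm >= protocol@start + protocol@duration)
    return(state)
  kEff <- config@kPhotolysisMax * protocol@intensity / 100
  mask <- roiPixelMask(config, protocol)
  frac <- 1 - exp(-kEff * dt)
  dm <- state@totals[["DMNP.caged"]] * frac * mask
  state@totals[["DMNP.caged"]] <- state@totals[["DMNP.caged"]] - dm
  state@totals[["DMNP.photolyzed"]] <- state@totals[["DMNP.photolyzed"]] + dm
  state
}

## zero-flux 5-point Laplacian
.laplacian <- function(m) {
  up <- m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
  dn <- m[c(seq_len(nrow(m) - 1) + 1, nrow(m)), , drop = FALSE]
  lf <- m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
  rt <- m[, c(seq_len(ncol(m) - 1) + 1, ncol(m)), drop = FALSE]
  up + dn + lf + rt - 4 * m
}

#' One explicit diffusion substep
#'
#' Each mobile species' total map advances by a 5-point-Laplacian step with
#' zero-flux boundaries. Exchangeable calcium uses the rapid-buffer flux
#' decomposition (free calcium at \code{600 um^2/s} plus each mobile bound
#' form at its carrier's coefficient, taken from the last equilibration).
#' Assembled protein does not move. Grid-total mass of every species is
#' conserved.
#'
#' @inheritParams stepPhotolysis
#' @return the updated state.
#' @export
stepDiffusion <- function(state, config, dt) {
  px2 <- config@pixelSize^2
  D <- vapply(config@panel@species, function(s) s@D, numeric(1))
  dmax <- max(c(D, .D_FREE_CA))
  if (dt > px2 / (4 * dmax))
    stop("substep violates the diffusion stability bound")
  nm <- speciesNames(config@panel)
  delta <- .D_FREE_CA * .laplacian(state@freeCa)
  for (j in seq_along(nm)) {
    if (D[j] <= 0) next
    state@totals[[nm[j]]] <- state@totals[[nm[j]]] +
      dt * D[j] / px2 * .laplacian(state@totals[[nm[j]]])
    bnd <- state@bound[[nm[j]]]
    if (nm[j] == "Tcb2") {
      tot <- state@totals[[nm[j]]] + state@assembled
      share <- state@totals[[nm[j]]]
      pos <- tot > 1e-12
      share[pos] <- share[pos] / tot[pos]; share[!pos] <- 0
      bnd <- bnd * share # calcium on assembled (immobile) protein stays put
    }
    delta <- delta + D[j] * .laplacian(bnd)
  }
  state@caExchange <- pmax(state@caExchange + dt / px2 * delta, 0)
  state
}

#' Equilibrate every pixel
#'
#' Applies the competitive binding equilibrium
#' (\code{\link{solveCompetitiveEquilibrium}}) to each pixel's exchangeable
#' calcium and species totals, refreshing the free and bound maps.
#'
#' @inheritParams stepPhotolysis
#' @return the updated state.
#' @export
stepEquilibrate <- function(state, config, proteinName = "Tcb2") {
  nm <- speciesNames(config@panel)
  K <- vapply(config@panel@species, function(s) s@kd, numeric(1))
  B <- vapply(nm, function(n) as.vector(state@totals[[n]]),
              numeric(length(state@caExchange)))
  ip <- match(proteinName, nm)
  if (!is.na(ip)) B[, ip] <- B[, ip] + as.vector(state@assembled)
  f <- solveFreeCa(as.vector(state@caExchange), B, K)
  dm <- dim(state@caExchange)
  state@freeCa <- matrix(f, dm[1], dm[2])
  for (j in seq_along(nm))
    state@bound[[nm[j]]] <- matrix(B[, j] * f / (K[j] + f), dm[1], dm[2])
  state
}

#' One assembly-relaxation substep
#'
#' The assembled fraction relaxes toward the Hill propensity of the local
#' calcium-loaded protein concentration (soluble bound plus assembled) at
#' rate \code{kAssembly}; assembling monomers take their calcium with them,
#' sequestering it from the exchange pool. Disassembly (rate
#' \code{kDisassembly}) engages only when the propensity falls below
#' \code{(1 - hysteresis)} times the current fraction, and pixels above
#' \code{immobilizeCutoff} are immobile and protected.
#'
#' @inheritParams stepPhotolysis
#' @param proteinName species name of the self-assembling protein.
#' @return the updated state.
#' @export
stepAssembly <- function(state, config, dt, proteinName = "Tcb2") {
  S <- state@totals[[proteinName]]
  A <- state@assembled
  Bt <- state@bound[[proteinName]] # equilibrium total over soluble + assembled
  tot <- S + A
  pos <- tot > 1e-12
  p <- matrix(0, nrow(S), ncol(S))
  p[pos] <- hillResponse(Bt[pos], config@transition)
  phi <- matrix(0, nrow(S), ncol(S))
  phi[pos] <- A[pos] / tot[pos]

  capA <- config@maxPacking * config@panel@species[[
    max(.speciesIndex(config@panel, proteinName), 1L)]]@total
  up <- pos & (p > phi) & (A < capA)
  dA <- pmin(config@kAssembly * (p - phi) * tot * dt, S, pmax(capA - A, 0))
  dA[!up] <- 0
  down <- pos & (phi < config@immobilizeCutoff) &
    (p < (1 - config@hysteresis) * phi)
  dD <- pmin(config@kDisassembly * (phi - p) * tot * dt, A)
  dD[!down] <- 0

  state@assembled <- A + dA - dD
  state@totals[[proteinName]] <- S - dA + dD
  state
}

#' One full operator-split substep
#'
#' photolysis -> diffusion -> equilibrate -> assembly, then advances the
#' clock by \code{dt}. This is the reference R implementation of the compiled
#' loop used by \code{\link{runSimulation}}.
#'
#' @inheritParams stepPhotolysis
#' @return the updated state.
#' @export
stepOnce <- function(state, protocol, config, dt) {
  state <- stepPhotolysis(state, protocol, config, dt)
  state <- stepDiffusion(state, config, dt)
  state <- stepEquilibrate(state, config)
  state <- stepAssembly(state, config, dt)
  state@elapsed <- state@elapsed + dt
  state
}

#' Render one fluorescence frame
#'
#' \code{I = cameraOffset + exp(-bleachRate * exposure) * gain * [Ca.dye] +
#' noise}, where the gain maps full dye saturation to the saturation level of
#' \code{dyeCurve}. Draws from the current R RNG stream.
#'
#' @param state a \linkS4class{FieldState}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param cumulativeExposure accumulated illumination time (s).
#' @param noise logical; set FALSE for the closed-form noise-free frame.
#' @return intensity matrix.
#' @export
renderFluorescence <- function(state, config, cumulativeExposure = state@elapsed,
                               noise = TRUE) {
  rhodTot <- config@panel@species[[.speciesIndex(config@panel, "Rhod5N")]]@total
  gain <- if (rhodTot > 0) config@dyeCurve@a / rhodTot else 0
  fr <- config@cameraOffset +
    exp(-config@bleachRate * cumulativeExposure) * gain * state@bound[["Rhod5N"]]
  if (noise && config@noiseSd > 0)
    fr <- fr + matrix(rnorm(length(fr), 0, config@noiseSd), nrow(fr))
  fr
}

#' Render one brightfield frame
#'
#' Mid-gray background with low-variance noise; assembled pixels receive
#' additional zero-mean speckle with standard deviation
#' \code{textureContrast * assembledFraction}, so edge-magnitude statistics
#' separate network from background. Draws from the current R RNG stream.
#'
#' @inheritParams renderFluorescence
#' @return intensity matrix.
#' @export
renderBrightfield <- function(state, config, noise = TRUE) {
  phi <- assembledFraction(state)
  fr <- matrix(config@bfOffset, nrow(phi), ncol(phi))
  if (noise && config@bfNoiseSd > 0)
    fr <- fr + matrix(rnorm(length(fr), 0, config@bfNoiseSd), nrow(fr))
  if (config@textureContrast > 0)
    fr <- fr + phi * matrix(rnorm(length(fr), 0, config@textureContrast), nrow(fr))
  fr
}

## internal: mean over a small disc at physical position (x, y)
.discMean <- function(m, centerUm, pixelSize, radiusPx = 2) {
  cj <- round(centerUm[1] / pixelSize) + 1
  ci <- round(centerUm[2] / pixelSize) + 1
  ii <- pmax(1, ci - radiusPx):pmin(nrow(m), ci + radiusPx)
  jj <- pmax(1, cj - radiusPx):pmin(ncol(m), cj + radiusPx)
  sub <- m[ii, jj, drop = FALSE]
  d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
  mean(sub[d2 <= radiusPx^2])
}

#' Run a full stimulation simulation
#'
#' Integrates the operator-split reaction-diffusion model in compiled code
#' and renders both image channels, retaining per-frame ground truth.
#' Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param protocol a \linkS4class{PulseProtocol}.
#' @param nFrames number of rendered frames; frame k is the state at
#'   \code{k * frameInterval}.
#' @param withTcb2 logical; FALSE simulates the dye-only reference
#'   composition (protein total forced to 0) used for the competition
#'   inference, under the same stimulus and seed-derived noise stream.
#' @return a \linkS4class{SyntheticMovie}.
#' @export
runSimulation <- function(config, protocol, nFrames, withTcb2 = TRUE) {
  stopifnot(is(config, "SimulationConfig"), is(protocol, "PulseProtocol"))
  validObject(config); validObject(protocol)
  panel <- config@panel
  if (!withTcb2) {
    i <- .speciesIndex(panel, "Tcb2")
    if (i > 0) panel@species[[i]]@total <- 0
    config@panel <- panel
  }
  state <- initializeFieldState(config)
  dtTarget <- effectiveTimeStep(config)
  stepsPerFrame <- max(1L, as.integer(ceiling(config@frameInterval / dtTarget)))
  dt <- config@frameInterval / stepsPerFrame
  nm <- speciesNames(panel)
  K <- vapply(panel@species, function(s) s@kd, numeric(1))
  D <- vapply(panel@species, function(s) s@D, numeric(1))
  kEff <- config@kPhotolysisMax * protocol@intensity / 100

  res <- sim_core_run(
    totals = state@totals, assembled = state@assembled,
    caEx = state@caExchange, freeInit = state@freeCa,
    Kd = K, D = D, Dca = .D_FREE_CA,
    idxCaged = .speciesIndex(panel, "DMNP.caged") - 1L,
    idxPhot = .speciesIndex(panel, "DMNP.photolyzed") - 1L,
    idxTcb2 = .speciesIndex(panel, "Tcb2") - 1L,
    idxRhod = .speciesIndex(panel, "Rhod5N") - 1L,
    roiMask = as.vector(roiPixelMask(config, protocol)),
    pixelSize = config@pixelSize, dt = dt, stepsPerFrame = stepsPerFrame,
    nFrames = as.integer(nFrames), tStart = 0,
    pulseStart = protocol@start, pulseDur = protocol@duration, kEff = kEff,
    hillN = config@transition@nHill, hillK = config@transition@kHalf,
    hyst = config@hysteresis, kAsm = config@kAssembly,
    kDis = config@kDisassembly, cutoff = config@immobilizeCutoff,
    capA = config@maxPacking *
      panel@species[[max(.speciesIndex(panel, "Tcb2"), 1L)]]@total,
    tol = 1e-12)

  ny <- config@gridShape[1]; nx <- config@gridShape[2]
  rhodTot <- panel@species[[.speciesIndex(panel, "Rhod5N")]]@total
  gain <- if (rhodTot > 0) config@dyeCurve@a / rhodTot else 0
  times <- seq_len(nFrames) * config@frameInterval

  set.seed(config@seed)
  fluor <- array(0, c(ny, nx, nFrames))
  bf <- array(0, c(ny, nx, nFrames))
  for (k in seq_len(nFrames)) {
    base <- config@cameraOffset +
      exp(-config@bleachRate * times[k]) * gain * res$boundRhod[, , k]
    if (config@noiseSd > 0)
      base <- base + matrix(rnorm(ny * nx, 0, config@noiseSd), ny)
    fluor[, , k] <- base
    b <- matrix(config@bfOffset, ny, nx)
    if (config@bfNoiseSd > 0)
      b <- b + matrix(rnorm(ny * nx, 0, config@bfNoiseSd), ny)
    if (config@textureContrast > 0)
      b <- b + res$phi[, , k] * matrix(rnorm(ny * nx, 0, config@textureContrast), ny)
    bf[, , k] <- b
  }

  traces <- data.frame(
    time = times,
    freeCa = vapply(seq_len(nFrames), function(k)
      .discMean(res$free[, , k], protocol@center, config@pixelSize), numeric(1)),
    boundTcb2 = vapply(seq_len(nFrames), function(k)
      .discMean(res$boundTcb2[, , k], protocol@center, config@pixelSize), numeric(1)),
    assembledFraction = vapply(seq_len(nFrames), function(k)
      .discMean(res$phi[, , k], protocol@center, config@pixelSize), numeric(1)))

  new("SyntheticMovie",
      fluorescence = ImageStack(fluor, config@pixelSize, config@frameInterval,
                                "fluorescence", clockOrigin = times[1]),
      brightfield = ImageStack(bf, config@pixelSize, config@frameInterval,
                               "brightfield", clockOrigin = times[1]),
      truthFreeCa = res$free, truthBoundTcb2 = res$boundTcb2,
      truthAssembledFraction = res$phi, truthTraces = traces,
      protocol = protocol, config = config)
}

#' Saturated-indicator reference stack for bleach correction
#'
#' Simulates the bleaching reference acquisition: uniformly saturated dye
#' (no caged chelator) imaged under the same exposure clock, so each frame is
#' \code{cameraOffset + exp(-bleachRate t) * a + noise}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nFrames frames to render.
#' @param seed RNG seed (defaults to \code{config@seed + 1} so the reference
#'   noise stream differs from the experiment's).
#' @return an \linkS4class{ImageStack}.
#' @export
makeSaturatedReferenceStack <- function(config, nFrames,
                                        seed = config@seed + 1L) {
  ny <- config@gridShape[1]; nx <- config@gridShape[2]
  times <- seq_len(nFrames) * config@frameInterval
  set.seed(seed)
  fr <- array(0, c(ny, nx, nFrames))
  for (k in seq_len(nFrames)) {
    b <- config@cameraOffset + exp(-config@bleachRate * times[k]) * config@dyeCurve@a
    m <- matrix(b, ny, nx)
    if (config@noiseSd > 0)
      m <- m + matrix(rnorm(ny * nx, 0, config@noiseSd), ny)
    fr[, , k] <- m
  }
  ImageStack(fr, config@pixelSize, config@frameInterval, "saturated-reference",
             clockOrigin = times[1])
}

#' Expanding-disk brightfield phantom
#'
#' A speckled disk whose true radius grows as \code{rate * (t - t0)} (clipped
#' at 0 and flagged when it outgrows the field), rendered with the
#' brightfield camera model. Fixture for validating the radial tracker
#' against known geometry.
#'
#' @param rate expansion rate (um/s, >= 0).
#' @param config a \linkS4class{SimulationConfig} (grid, camera model, seed).
#' @param nFrames frames to render.
#' @param t0 time at which the disk nucleates (s).
#' @param center disk centre (x, y) um; default field centre.
#' @return list with elements \code{brightfield} (\linkS4class{ImageStack}),
#'   \code{truth} (data.frame time, radius, clipped), and \code{center}.
#' @export
makeExpandingDiskPhantom <- function(rate, config, nFrames, t0 = 0.5,
                                     center = NULL) {
  stopifnot(rate >= 0)
  ny <- config@gridShape[1]; nx <- config@gridShape[2]; px <- config@pixelSize
  if (is.null(center)) center <- c((nx - 1) / 2, (ny - 1) / 2) * px
  x <- (seq_len(nx) - 1) * px
  y <- (seq_len(ny) - 1) * px
  d2 <- outer((y - center[2])^2, (x - center[1])^2, "+")
  maxR <- min(center[1], center[2], max(x) - center[1], max(y) - center[2])
  times <- seq_len(nFrames) * config@frameInterval
  set.seed(config@seed)
  fr <- array(0, c(ny, nx, nFrames))
  radius <- pmax(rate * (times - t0), 0)
  clipped <- radius > maxR
  for (k in seq_len(nFrames)) {
    m <- matrix(config@bfOffset, ny, nx)
    if (config@bfNoiseSd > 0)
      m <- m + matrix(rnorm(ny * nx, 0, config@bfNoiseSd), ny)
    if (radius[k] > 0 && config@textureContrast > 0) {
      inside <- d2 <= radius[k]^2
      m <- m + inside * matrix(rnorm(ny * nx, 0, config@textureContrast), ny)
    }
    fr[, , k] <- m
  }
  list(brightfield = ImageStack(fr, px, config@frameInterval, "brightfield",
                                clockOrigin = times[1]),
       truth = data.frame(time = times, radius = pmin(radius, maxR),
                          clipped = clipped),
       center = center)
}

#' Synthetic indicator standard-curve frames
#'
#' One uniform-plus-noise frame per free-calcium level, at mean intensity
#' \code{offset + saturationResponse(level, curve)}.
#'
#' @param caLevels free-calcium standards (uM, >= 0).
#' @param curve the generating \linkS4class{SaturationCurve}.
#' @param noiseSd Gaussian noise sd (intensity units).
#' @param seed RNG seed.
#' @param offset camera offset added to every frame.
#' @param shape (ny, nx) of each frame.
#' @return list with \code{stack} (\linkS4class{ImageStack}, one frame per
#'   level) and \code{table} (data.frame level_uM, true_mean).
#' @export
makeStandardCurveFrames <- function(caLevels, curve, noiseSd = 0, seed = 1L,
                                    offset = 100, shape = c(64L, 64L)) {
  stopifnot(all(caLevels >= 0))
  ny <- shape[1]; nx <- shape[2]
  set.seed(seed)
  fr <- array(0, c(ny, nx, length(caLevels)))
  mu <- offset + saturationResponse(caLevels, curve)
  for (k in seq_along(caLevels)) {
    m <- matrix(mu[k], ny, nx)
    if (noiseSd > 0) m <- m + matrix(rnorm(ny * nx, 0, noiseSd), ny)
    fr[, , k] <- m
  }
  list(stack = ImageStack(fr, 1, 1, "standards"),
       table = data.frame(level_uM = caLevels, true_mean = mu))
}

## --------------------------------------------------------------------------
## Release-rate calibration of the free knobs
## --------------------------------------------------------------------------

## slope (uM/s) of the ROI-centre ground-truth free-calcium trace over
## [start + window[1], start + window[2]]
.truthSlope <- function(movie, window) {
  tr <- movie@truthTraces
  t0 <- movie@protocol@start
  sel <- tr$time >= t0 + window[1] & tr$time <= t0 + window[2]
  if (sum(sel) < 3) stop("too few frames in the slope window")
  unname(coef(lm(freeCa ~ time, data = tr[sel, ]))[2])
}

#' Calibrate the photolysis rate constant to a target burst slope
#'
#' The quantum yield x photon flux product behind \code{kPhotolysisMax}
#' cannot be measured directly, so it is set by matching the early
#' burst-phase free-calcium release rate at the ROI centre of a
#' 100\%-intensity pulse (dye-only composition, ground truth, no rendering
#' noise involved). Monotone bisection on the rate constant.
#'
#' @param config a \linkS4class{SimulationConfig}; its panel's protein is
#'   removed for the calibration runs.
#' @param targetSlope target early slope (uM/s).
#' @param window c(from, to) seconds after pulse onset over which the slope
#'   is fit.
#' @param protocol stimulation used for calibration (default 100\%, 5 s,
#'   50 um ROI at the field centre).
#' @param range search interval for the rate constant (1/s).
#' @param iters bisection iterations.
#' @return calibrated \code{kPhotolysisMax} (1/s).
#' @export
calibratePhotolysisRate <- function(config, targetSlope = 350,
                                    window = c(0, 0.5), protocol = NULL,
                                    range = c(0.05, 40), iters = 12L) {
  if (is.null(protocol)) protocol <- .centerProtocol(config, duration = 1,
                                                     intensity = 100)
  nFrames <- ceiling((protocol@start + window[2] + 0.05) / config@frameInterval)
  slopeAt <- function(k) {
    cfg <- config
    cfg@kPhotolysisMax <- k
    .truthSlope(runSimulation(cfg, protocol, nFrames, withTcb2 = FALSE), window)
  }
  lo <- range[1]; hi <- range[2]
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (slopeAt(mid) < targetSlope) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Calibrate the chelator diffusion coefficient to a target sustained slope
#'
#' Once the ROI's caged chelator is consumed, release is rate-limited by
#' diffusion of fresh caged chelator into the ROI, so the late sustained
#' release rate calibrates the chelator diffusion coefficient (applied to
#' both caged and photolyzed forms). Monotone bisection.
#'
#' @inheritParams calibratePhotolysisRate
#' @param targetSlope target late slope (uM/s).
#' @param window c(from, to) seconds after pulse onset.
#' @param range search interval for the diffusion coefficient (um^2/s).
#' @return calibrated chelator diffusion coefficient (um^2/s).
#' @export
calibrateDmnpDiffusion <- function(config, targetSlope = 19, window = c(1, 5),
                                   protocol = NULL, range = c(50, 600),
                                   iters = 10L) {
  if (is.null(protocol)) protocol <- .centerProtocol(config, duration = 5.2,
                                                     intensity = 100)
  nFrames <- ceiling((protocol@start + window[2] + 0.05) / config@frameInterval)
  slopeAt <- function(d) {
    cfg <- config
    for (nmi in c("DMNP.caged", "DMNP.photolyzed")) {
      i <- .speciesIndex(cfg@panel, nmi)
      cfg@panel@species[[i]]@D <- d
    }
    .truthSlope(runSimulation(cfg, protocol, nFrames, withTcb2 = FALSE), window)
  }
  lo <- range[1]; hi <- range[2]
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (slopeAt(mid) < targetSlope) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

## protocol centred on the field
.centerProtocol <- function(config, diameter = 50, duration = 5,
                            intensity = 100, start = 0.5) {
  ctr <- (rev(config@gridShape) - 1) / 2 * config@pixelSize
  PulseProtocol(center = ctr, diameter = diameter, duration = duration,
                intensity = intensity, start = start)
}
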
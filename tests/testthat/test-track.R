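# Brightfield segmentation, radius fitting, tracking, outcome classification.

# speckled-disk frame on a flat background (tracker fixture)
speckleDisk <- function(n, radiusPx, contrast = 30, bgSd = 2, seed = 1L) {
  set.seed(seed)
  d2 <- outer((seq_len(n) - (n + 1) / 2)^2, (seq_len(n) - (n + 1) / 2)^2, "+")
  inside <- d2 <= radiusPx^2
  500 + matrix(rnorm(n * n, 0, bgSd), n) +
    inside * matrix(rnorm(n * n, 0, contrast), n)
}

# synthetic trace constructor for the classification rules
makeTrace <- function(radii, dt = 0.1, center = c(0, 0)) {
  new("BoundaryTrace", times = seq_along(radii) * dt, radii = radii,
      detected = !is.na(radii), center = center, pixelSize = 1)
}

test_that("network masks separate speckle from background", {
  dp <- DetectionParams(blurRadius = 2, thresholdMode = "fixed",
                        fixedThreshold = 25, minArea = 10)
  fr <- speckleDisk(101, 30)
  mask <- detectNetworkMask(fr, dp)
  d2 <- outer((1:101 - 51)^2, (1:101 - 51)^2, "+")
  inside <- d2 <= 30^2
  far <- d2 > (30 + 10)^2 # beyond the blur halo
  expect_gt(mean(mask[inside]), 0.9) # covers the disk
  expect_lt(mean(mask[far]), 0.05)   # spares the background

  # uniform frame: nothing detected
  expect_false(any(detectNetworkMask(matrix(500, 64, 64), dp)))

  # background-robust threshold calibrated on pre-pulse frames does the same
  frames <- array(0, c(101, 101, 2))
  frames[, , 1] <- 500 + matrix(rnorm(101^2, 0, 2), 101)
  frames[, , 2] <- fr
  st <- ImageStack(frames, 1, 0.1)
  thr <- detectionThreshold(st, DetectionParams(blurRadius = 2, minArea = 10),
                            frames = 1L)
  mask2 <- detectNetworkMask(fr, DetectionParams(blurRadius = 2, minArea = 10),
                             threshold = thr)
  expect_gt(mean(mask2[inside]), 0.9)

  # zero contrast: the network is invisible
  frInv <- speckleDisk(101, 30, contrast = 0)
  expect_equal(sum(detectNetworkMask(frInv, dp)), 0L)
})

test_that("boundary radius fitting matches disk geometry", {
  d2 <- outer((1:101 - 51)^2, (1:101 - 51)^2, "+")
  mask <- d2 <= 25^2
  r <- fitBoundaryRadius(mask, center = c(50, 50), pixelSize = 1)
  expect_equal(r, 25, tolerance = 0.04)

  # physical units scale with pixel size
  r2 <- fitBoundaryRadius(mask, center = c(100, 100), pixelSize = 2)
  expect_equal(r2, 50, tolerance = 2 * 25 * 0.04)

  # 10% boundary dropout barely moves the estimate
  set.seed(4)
  er <- mask & (d2 > 23.5^2)
  drop <- which(er)[runif(sum(er)) < 0.10]
  maskD <- mask
  maskD[drop] <- FALSE
  rD <- fitBoundaryRadius(maskD, center = c(50, 50), pixelSize = 1)
  expect_lt(abs(rD - 25) / 25, 0.02)

  # empty mask: not detected
  expect_true(is.na(fitBoundaryRadius(matrix(FALSE, 10, 10), c(5, 5), 1)))

  # radius never decreases under mask dilation
  grown <- EBImage::dilate(mask, EBImage::makeBrush(5, "disc")) > 0
  expect_gte(fitBoundaryRadius(grown, c(50, 50), 1), r)
})

test_that("tracking an expanding disk reproduces its radius trace", {
  cfg <- defaultSimulationConfig(gridShape = c(128L, 128L), pixelSize = 2,
                                 seed = 3L)
  ph <- makeExpandingDiskPhantom(10, cfg, nFrames = 60, t0 = 0.5)
  dp <- coarseDetection()
  trc <- trackRadius(ph$brightfield, ph$center, dp, prePulseFrames = 1:4)
  sel <- trc@detected & ph$truth$radius > 8 & !ph$truth$clipped
  expect_gt(sum(sel), 20)
  rmse <- sqrt(mean((trc@radii[sel] - ph$truth$radius[sel])^2))
  expect_lt(rmse / cfg@pixelSize, 1) # < 1 px

  # rotation invariance: a 90-degree rotation leaves radii unchanged (<1%)
  rot <- ph$brightfield
  rot@frames <- aperm(ph$brightfield@frames[, rev(seq_len(128)), ],
                      c(2, 1, 3))
  trcR <- trackRadius(rot, ph$center, dp, prePulseFrames = 1:4)
  both <- sel & trcR@detected
  expect_lt(max(abs(trcR@radii[both] - trc@radii[both]) /
                  trc@radii[both]), 0.01)

  # an all-background movie is never detected
  cfg0 <- defaultSimulationConfig(gridShape = c(64L, 64L), pixelSize = 2,
                                  seed = 4L)
  ph0 <- makeExpandingDiskPhantom(0, cfg0, nFrames = 10)
  trc0 <- trackRadius(ph0$brightfield, ph0$center, dp, prePulseFrames = 1:4)
  expect_false(any(trc0@detected))

  # a static disk yields constant radii
  # (a frozen gel's texture is static, so frames repeat)
  frS <- array(speckleDisk(101, 25, seed = 101L), c(101, 101, 6))
  stS <- ImageStack(frS, 1, 0.1)
  trcS <- trackRadius(stS, c(50, 50),
                      DetectionParams(blurRadius = 1, thresholdMode = "fixed",
                                      fixedThreshold = 15, minArea = 4))
  expect_true(all(trcS@detected))
  expect_equal(sd(trcS@radii), 0)
})

test_that("delay extraction follows the protocol clock", {
  pr <- PulseProtocol(center = c(0, 0), duration = 2, intensity = 50,
                      start = 0.5)
  # detection at the first post-onset frame
  tr <- makeTrace(c(NA, NA, NA, NA, NA, 10, 12, 14)) # detection at t = 0.6
  expect_equal(extractDelay(tr, pr), 0.1, tolerance = 1e-9)
  # never detected
  expect_true(is.na(extractDelay(makeTrace(rep(NA_real_, 8)), pr)))
  # detection before onset warns
  expect_warning(extractDelay(makeTrace(c(5, 6, 7, 8, 9, 10, 11, 12)), pr),
                 "before pulse onset")
})

test_that("initial growth rate is the slope of the first detected points", {
  tr <- makeTrace(c(NA, 2, 4, 6, 8, 10, 10, 10))
  expect_equal(initialGrowthRate(tr), 20, tolerance = 1e-9) # 2 per 0.1 s
  # static disk: zero
  expect_equal(initialGrowthRate(makeTrace(rep(7, 8))), 0)
  # too few detections
  out <- initialGrowthRate(makeTrace(c(NA, NA, NA, NA, NA, NA, 3, 4)))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "detected frames")
  # planted 10 um/s with 1-px quantization noise recovered within 5%
  set.seed(2)
  radii <- round(10 * (1:20) * 0.1)
  expect_lt(abs(initialGrowthRate(makeTrace(radii)) - 10) / 10, 0.05)
})

test_that("outcome classification applies the sustain/decay rules", {
  pr <- PulseProtocol(center = c(0, 0), duration = 1, intensity = 100,
                      start = 0.2)
  n <- 120 # 12 s at 0.1 s
  # never detected -> none, all quantitative fields absent
  ocN <- classifyOutcome(makeTrace(rep(NA_real_, n)), pr)
  expect_equal(ocN@label, "none")
  expect_true(is.na(ocN@delay) && is.na(ocN@maxRadius))

  # monotone growth then plateau -> sustained
  grow <- c(rep(NA, 4), pmin(seq_len(n - 4) * 0.8, 30))
  expect_equal(classifyOutcome(makeTrace(grow), pr)@label, "sustained")

  # rise to R then decay to 0.2 R -> transient
  rise <- c(rep(NA, 4), seq(2, 30, length.out = 16),
            seq(30, 6, length.out = n - 20))
  expect_equal(classifyOutcome(makeTrace(rise), pr)@label, "transient")

  # in-between decay -> ambiguous
  mid <- c(rep(NA, 4), seq(2, 30, length.out = 16),
           seq(30, 20, length.out = n - 20))
  expect_equal(classifyOutcome(makeTrace(mid), pr)@label, "ambiguous")

  # insufficient post-pulse frames is an error
  expect_error(classifyOutcome(makeTrace(grow[1:30]), pr), "need")
})

test_that("phase portrait is monotone on a simulated protocol grid", {
  labelFor <- function(duration, intensity) {
    cfg <- defaultSimulationConfig(gridShape = c(48L, 48L), pixelSize = 2.5,
                                   seed = 19L)
    pr <- centerPulse(cfg, duration = duration, intensity = intensity,
                      start = 0.3)
    nF <- ceiling((0.3 + duration + 6.2) / cfg@frameInterval)
    mv <- runSimulation(cfg, pr, nF)
    trc <- trackRadius(mv@brightfield, pr@center, coarseDetection(),
                       prePulseFrames = 1:2)
    classifyOutcome(trc, pr, postWindow = 6)@label
  }
  grid <- expand.grid(duration = c(0.3, 2), intensity = c(15, 100))
  grid$label <- mapply(labelFor, grid$duration, grid$intensity)
  # if a cell assembles, no cell with >= duration and >= intensity is "none"
  for (i in seq_len(nrow(grid))) {
    if (grid$label[i] == "none") next
    dom <- grid$duration >= grid$duration[i] &
      grid$intensity >= grid$intensity[i]
    expect_true(all(grid$label[dom] != "none"))
  }
  # the strongest cell must assemble
  expect_true(grid$label[grid$duration == 2 & grid$intensity == 100] != "none")
})
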
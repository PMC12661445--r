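# Competition inference, Hill fitting, phase portraits, group statistics.

test_that("intensity differencing is exact and guards alignment", {
  a1 <- array(runif(8 * 8 * 3, 100, 200), c(8, 8, 3))
  s1 <- ImageStack(a1, 1, 0.1)
  # identical stacks: zero everywhere
  expect_true(all(deltaIntensity(s1, s1)@frames == 0))
  # constant offset: recovered exactly
  s2 <- s1; s2@frames <- s1@frames - 7
  expect_equal(deltaIntensity(s1, s2)@frames, array(7, c(8, 8, 3)))
  # misalignment errors
  expect_error(deltaIntensity(s1, ImageStack(a1[, , 1:2], 1, 0.1)), "shapes")
  expect_error(deltaIntensity(s1, ImageStack(a1, 1, 0.2)), "clocks")
  expect_error(deltaIntensity(s1, ImageStack(a1, 2, 0.1)), "pixel sizes")
})

test_that("bound-protein estimators implement their algebra", {
  cv <- SaturationCurve(100, 230)
  fit <- new("CalibrationFit", curve = cv, residualRms = 0,
             linearRangeMax = 230, nPoints = 3L)
  mkStack <- function(v) ImageStack(array(v, c(4, 4, 1)), 1, 0.1)

  # linear-slope: deltaI = a/2 maps to b/2 = 115 uM
  b1 <- boundTcb2FromDelta(mkStack(50), fit, mode = "linear-slope")
  expect_equal(unique(as.vector(b1@conc)), 115)
  expect_equal(boundTcb2FromDelta(mkStack(0), fit,
                                  mode = "linear-slope")@flooredFraction, 0)

  # inversion-difference equals the free-calcium deficit exactly
  fr <- 15; fe <- 5 # uM, well inside the linear range
  iR <- saturationResponse(fr, cv); iE <- saturationResponse(fe, cv)
  b2 <- boundTcb2FromDelta(mkStack(iR - iE), fit,
                           mode = "inversion-difference",
                           refStack = mkStack(iR))
  expect_equal(unique(as.vector(b2@conc)), fr - fe, tolerance = 1e-10)
  # and agrees with linear-slope within 10% in the linear range
  b3 <- boundTcb2FromDelta(mkStack(iR - iE), fit, mode = "linear-slope")
  expect_lt(abs(b3@conc[1] - b2@conc[1]) / b2@conc[1], 0.1)

  # negative differences floored and flagged
  expect_warning(
    bn <- boundTcb2FromDelta(mkStack(-5), fit, mode = "linear-slope"),
    "pairing failure")
  expect_true(all(bn@conc == 0))
  expect_equal(bn@flooredFraction, 1)
})

test_that("maximum-bound traces are robust to single hot pixels", {
  conc <- array(10, c(16, 16, 2))
  conc[8, 8, 1] <- 500 # isolated hot pixel, first frame
  bs <- new("BoundTcb2Stack", conc = conc, mode = "linear-slope",
            flooredFraction = 0, pixelSize = 1, frameInterval = 0.1,
            times = c(0.1, 0.2))
  mt <- maxBoundTrace(bs, center = c(7.5, 7.5), radius = 6)
  expect_equal(mt$maxBound, c(10, 10)) # median filter kills the spike
  expect_error(maxBoundTrace(bs, center = c(100, 100), radius = 2),
               "empty ROI")
  # all-zero stack: zero trace
  bs0 <- bs; bs0@conc[] <- 0
  expect_true(all(maxBoundTrace(bs0, c(7.5, 7.5), 6)$maxBound == 0))
})

test_that("boundary concentration reads the field at the fitted radius", {
  n <- 64
  rmap <- sqrt(outer((0:(n - 1) - 31.5)^2, (0:(n - 1) - 31.5)^2, "+"))
  mk <- function(field) new("BoundTcb2Stack",
                            conc = array(field, c(n, n, 1)),
                            mode = "linear-slope", flooredFraction = 0,
                            pixelSize = 1, frameInterval = 0.1, times = 0.1)
  trc <- new("BoundaryTrace", times = 0.1, radii = 20, detected = TRUE,
             center = c(31.5, 31.5), pixelSize = 1)
  # uniform field: the constant at any radius
  expect_equal(boundaryConcentration(mk(matrix(42, n, n)), trc)$boundary, 42)
  # radially linear field: the value at the fitted radius +/- discretization
  lin <- 5 + 3 * rmap
  expect_equal(boundaryConcentration(mk(lin), trc)$boundary, 5 + 3 * 20,
               tolerance = 0.01)
  # boundary beyond the field flags partial coverage
  trcBig <- trc; trcBig@radii <- 40
  expect_true(boundaryConcentration(mk(lin), trcBig)$partial)
})

test_that("Hill-transition fitting recovers model data and flags degeneracy", {
  # dense noise-free observations drawn from HillModel(4, 50)
  m <- HillModel(4, 50)
  lv <- 10^seq(0.3, 2.6, length.out = 24)
  parts <- lapply(lv, function(l) {
    nUp <- round(hillResponse(l, m) * 2000)
    data.frame(x = l, assembled = rep(c(TRUE, FALSE), c(nUp, 2000 - nUp)))
  })
  parts <- do.call(rbind, parts)
  obs <- AssemblyObservation(parts$x, parts$assembled)
  fit <- fitHillTransition(obs, method = "binary")
  expect_equal(fit@model@nHill, 4, tolerance = 2e-3)
  expect_equal(fit@model@kHalf, 50, tolerance = 2e-3)
  expect_false(fit@separated)
  expect_true(fit@seN >= 0 && fit@seK >= 0)

  # binned method on the same data
  fitB <- fitHillTransition(obs, method = "binned")
  expect_equal(fitB@model@kHalf, 50, tolerance = 0.05)

  # one-class data is an error
  expect_error(fitHillTransition(AssemblyObservation(1:10, rep(TRUE, 10))),
               "both assembled and unassembled")
  # perfectly separated classes: midpoint in the gap, exponent unbounded
  sep <- AssemblyObservation(c(seq(10, 80, 10), seq(110, 180, 10)),
                             rep(c(FALSE, TRUE), each = 8))
  fitS <- fitHillTransition(sep)
  expect_true(fitS@separated)
  expect_true(is.infinite(fitS@model@nHill))
  expect_gt(fitS@model@kHalf, 80)
  expect_lt(fitS@model@kHalf, 110)
})

test_that("phase portraits aggregate outcomes with majority and tie flags", {
  pr <- function(d, i) PulseProtocol(center = c(0, 0), diameter = 50,
                                     duration = d, intensity = i, start = 0.1)
  oc <- function(l) new("NetworkOutcome", label = l,
                        delay = if (l == "none") NA_real_ else 1,
                        maxRadius = if (l == "none") NA_real_ else 10,
                        initialGrowthRate = if (l == "none") NA_real_ else 5)
  # single entry
  pp1 <- buildPhasePortrait(list(pr(1, 50)), list(oc("sustained")))
  expect_equal(nrow(pp1@entries), 1L)
  # majority and tie
  pp2 <- buildPhasePortrait(
    list(pr(1, 50), pr(1, 50), pr(1, 50), pr(2, 80), pr(2, 80)),
    list(oc("sustained"), oc("sustained"), oc("none"), oc("transient"),
         oc("sustained")))
  e <- pp2@entries
  expect_equal(e$label[e$duration == 1], "sustained")
  expect_false(e$tie[e$duration == 1])
  expect_true(e$tie[e$duration == 2])
})

test_that("D'Agostino K-squared matches its reference values", {
  # frozen oracle values computed with an independent implementation
  x1 <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793, 7.395641,
          10.255681, 9.367515, 9.966398, 8.293912, 11.758796, 11.555584,
          10.132061, 12.254482, 10.935019, 8.281415, 10.737502, 8.082235,
          11.756901, 9.900148)
  x2 <- c(1.871079, 0.335365, 2.756955, 1.840629, 0.983694, 0.62563, 0.67998,
          0.115616, 0.269448, 1.027981, 0.58302, 1.89631, 1.062736, 0.356895,
          0.691633, 0.962335, 0.51575, 0.482867, 1.318372, 0.445421, 2.000554,
          2.086296, 1.626124, 0.109543, 1.701101, 2.031507, 1.683059,
          0.420074, 0.481404, 0.248604)
  x3 <- c(0.746346, 1.753422, -0.741434, 2.702211, -2.247433, 0.493591,
          -0.498132, -0.459462, -0.84162, 0.967914, 0.824566, -0.896999,
          -1.099102, 0.011512, 0.790227)
  ref <- list(list(k2 = 1.6864872489, p = 0.4303124852),
              list(k2 = 3.3424166052, p = 0.1880197436),
              list(k2 = 0.3974475699, p = 0.8197762966))
  for (i in 1:3) {
    r <- dagostinoK2(list(x1, x2, x3)[[i]])
    expect_equal(r$statistic, ref[[i]]$k2, tolerance = 1e-8)
    expect_equal(r$p.value, ref[[i]]$p, tolerance = 1e-8)
  }
  expect_error(dagostinoK2(rnorm(5)), "n >= 8")
})

test_that("group comparison reproduces the pooled t-test", {
  # identical samples: t = 0, p = 1
  x <- c(1.2, 1.9, 2.4, 3.1, 0.7, 2.2, 1.4, 2.8, 1.1, 2.0)
  gc0 <- compareGroups(x, x)
  expect_equal(gc0@t, 0)
  expect_equal(gc0@p, 1)

  # summary-statistic formula: 3.9 (0.9) vs 6.1 (0.9), n = 10 each
  ts <- tTestFromSummary(3.9, 0.9, 10, 6.1, 0.9, 10)
  expect_equal(abs(ts$t), 5.466, tolerance = 1e-3)
  expect_equal(ts$df, 18)
  expect_lt(ts$p, 0.001)

  # compareGroups on raw data agrees with the summary formula
  set.seed(10)
  a <- rnorm(12, 5, 1); b <- rnorm(14, 6.2, 1.3)
  gc <- compareGroups(a, b)
  ts2 <- tTestFromSummary(mean(a), sd(a), 12, mean(b), sd(b), 14)
  expect_equal(gc@t, ts2$t, tolerance = 1e-10)
  expect_equal(gc@p, ts2$p, tolerance = 1e-10)
  expect_true(gc@normalityPA > 0.05 && gc@normalityPB > 0.05)

  # small groups skip normality with a warning; welch variant runs
  expect_warning(gcS <- compareGroups(rnorm(4), rnorm(4)), "too small")
  expect_true(is.na(gcS@normalityPA))
  gw <- compareGroups(a, b, method = "welch")
  expect_false(isTRUE(all.equal(gw@df, 24)))
  expect_error(compareGroups(1, 1:5), "n >= 2")
})

test_that("null p-values are uniform across seeded replicates", {
  set.seed(99)
  ps <- vapply(1:800, function(i) {
    a <- rnorm(10); b <- rnorm(10)
    tTestFromSummary(mean(a), sd(a), 10, mean(b), sd(b), 10)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("delay times the loading rate recovers the critical concentration", {
  # near-constant loading: a low-intensity delayed-onset pulse
  cfg <- midConfig(seed = 23L)
  pr <- centerPulse(cfg, duration = 10, intensity = 35, start = 0.5)
  mv <- runSimulation(cfg, pr, 110L)
  trc <- trackRadius(mv@brightfield, pr@center, coarseDetection(),
                     prePulseFrames = 1:4)
  expect_true(any(trc@detected))
  delay <- extractDelay(trc, pr)
  tr <- mv@truthTraces
  pre <- tr$time > 0.6 & tr$time < trc@times[which(trc@detected)[1]]
  rate <- unname(coef(lm(boundTcb2 ~ time, tr[pre, ]))[2])
  expect_lt(abs(rate * delay - 93) / 93, 0.2)
})
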
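test_that("degenerate configurations give the expected uniform scenes", {
  sc <- makeScene(sceneConfig(width_um = 400, height_um = 200,
                              osteonalFraction = 1, osteonAreaFraction = 0,
                              lacunaFraction = 0))
  expect_true(all(sceneLabels(sc) == "interstitial"))
  expect_true(all(is.finite(sc@T)))
})

test_that("the realized osteon area fraction approaches its target", {
  for (s in 1:4) {
    sc <- makeScene(sceneConfig(width_um = 500, height_um = 500,
                                osteonalFraction = 1, lacunaFraction = 0,
                                seed = s))
    expect_lt(abs(sc@meta$realizedOsteonFraction - 0.3), 0.05)
  }
  expect_error(makeScene(sceneConfig(width_um = 500, height_um = 500,
                                     osteonalFraction = 1,
                                     osteonAreaFraction = 0.85,
                                     lacunaFraction = 0)),
               "packing")
})

test_that("scene generation is deterministic under a fixed seed", {
  a <- makeScene(sceneConfig(seed = 7))
  b <- makeScene(sceneConfig(seed = 7))
  expect_identical(a, b)
  sa <- renderScan(a, noise = TRUE, seed = 3)
  sb <- renderScan(b, noise = TRUE, seed = 3)
  expect_identical(sa, sb)
})

test_that("the default scene carries two chord-length modes at the
           configured offset", {
  sc <- makeScene(sceneConfig(width_um = 2000, height_um = 1000))
  dec <- decomposeTwoPopulations(sc@T[is.finite(sc@T)])
  expect_equal(dec@components$TMAX[1], 3.0, tolerance = 0.03)
  expect_equal(dec@components$TMAX[2], 3.4, tolerance = 0.03)
})

test_that("heating leaves the reference untouched at zero duration and
           grows T monotonically", {
  sc <- makeScene(sceneConfig(width_um = 500, height_um = 300))
  h0 <- heatScene(sc, 190, durationH = 0)
  expect_equal(h0@T, sc@T)
  expect_equal(h0@alpha, sc@alpha)
  temps <- c(100, 150, 170, 190, 210, 250)
  means <- vapply(temps, function(tc)
    mean(heatScene(sc, tc)@T, na.rm = TRUE), numeric(1))
  expect_true(all(diff(means) > 0))
  # disorder trends: alpha up (2pi/alpha down), beta down (d up)
  h <- heatScene(sc, 250)
  expect_true(all(h@alpha > sc@alpha, na.rm = TRUE))
  expect_true(all(h@beta < sc@beta, na.rm = TRUE))
  expect_true(mean(h@T * 2 * pi / h@beta, na.rm = TRUE) >
              mean(sc@T * 2 * pi / sc@beta, na.rm = TRUE))
})

test_that("pooled per-temperature histograms of a noiseless heated series
           recover the generation kinetics", {
  sc <- makeScene(sceneConfig(width_um = 1500, height_um = 800))
  temps <- c(100, 150, 170, 190, 210, 250)
  decRef <- decomposeTwoPopulations(sc@T[is.finite(sc@T)])
  rows <- lapply(temps, function(tc) {
    h <- heatScene(sc, tc, Ea = 33.1, n = 1.42)
    dec <- decomposeTwoPopulations(h@T[is.finite(h@T)])
    data.frame(temperature_C = tc, low = dec@components$TMAX[1],
               high = dec@components$TMAX[2])
  })
  tab <- do.call(rbind, rows)
  fitLow <- arrheniusFit(data.frame(temperature_C = tab$temperature_C,
                                    TMAX = tab$low),
                         T0max = decRef@components$TMAX[1])
  expect_lt(abs(fitLow@Ea - 33.1) / 33.1, 0.05)
})

test_that("noise-free rendering equals the forward model exactly", {
  sc <- uniformScene(nx = 2, ny = 2)
  scan <- renderScan(sc, noise = FALSE, fluxScale = 1)
  prof <- scan$profiles[[1]]
  model <- evaluateProfile(qValues(prof),
                           list(T = 3.2, alpha = 2.5, beta = 1.2, P = 1)) /
    qValues(prof)^2
  expect_equal(intensities(prof), model, tolerance = 1e-12)
  expect_error(renderScan(sc, fluxScale = 0), "fluxScale")
})

test_that("Poisson rendering has the right first moment", {
  sc <- uniformScene(nx = 1, ny = 1)
  scan <- renderScan(sc, noise = TRUE, seed = 41)
  prof <- scan$profiles[[1]]
  w <- pixelCounts(prof)
  m <- evaluateProfile(qValues(prof),
                       list(T = 3.2, alpha = 2.5, beta = 1.2, P = 1)) /
    qValues(prof)^2 * w
  z <- (intensities(prof) * w - m) / sqrt(m)   # standardized counts
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(sd(z) - 1), 0.2)
})

test_that("rendered 2D frames integrate back to the 1D profile", {
  g <- smallGeometry()
  truth <- NanostructureParams(3.2, 2.5, 1.2, 1)
  frame <- renderFrame(truth, g, fluxScale = 1e3, noise = FALSE)
  mask <- defaultMask(g, beamstopRadius = 4)
  prof <- azimuthalIntegrate(frame, g, defaultQBins(c(0.1, 3), 80), mask)
  ok <- pixelCounts(prof) > 3
  model <- 1e3 * evaluateProfile(qValues(prof)[ok], truth) /
    qValues(prof)[ok]^2
  expect_lt(median(abs(intensities(prof)[ok] - model) / model), 0.02)
})

test_that("synthetic Raman spectra honor their configuration", {
  cfg <- ramanSimConfig()
  pure <- synthRaman(150, includeBackground = FALSE, noiseSD = 0)
  bf <- fitBands(pure)
  frac <- (150 - 25) / 225
  trueArea <- cfg$bands$area * cfg$bands$areaFactor250^frac
  expect_equal(bf$area, trueArea, tolerance = 1e-4)
  # the configured Amide I shift is recovered at the top temperature
  hot <- synthRaman(250, includeBackground = FALSE, noiseSD = 0)
  bh <- fitBands(hot)
  shift <- bh$center[bh$band == "amideI"] - 1660
  expect_equal(shift, -3.5, tolerance = 0.1)
  # at 250 C the fluorescence dwarfs the strongest band
  peak <- max(cfg$bands$area / (cfg$bands$sigma * sqrt(2 * pi)))
  expect_gt(cfg$bg0 * exp(cfg$bgRate * 225) / peak, cfg$unusableRatio)
})

test_that("synthetic TEM dips are reproducible and well separated", {
  a <- synthTEM(5, thicknessMean = 8, blurSigma = 1, seed = 11)
  b <- synthTEM(5, thicknessMean = 8, blurSigma = 1, seed = 11)
  expect_identical(a@intensity, b@intensity)
  parts <- attr(a, "particles")
  expect_true(all(parts$a[-1] - parts$b[-nrow(parts)] >= 6))
})
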
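test_that("maps assemble from raster fit tables with void exclusion", {
  tab <- expand.grid(x_um = seq(25, 475, by = 50),
                     y_um = seq(10, 190, by = 20))
  tab$T_nm <- 3.1
  tab$valid <- TRUE
  tab$is_bone <- TRUE
  m <- assembleMap(tab, pitch = c(50, 20))
  expect_equal(dim(mapValues(m)), c(10L, 10L))
  expect_true(all(mapValid(m)))
  expect_true(all(mapValues(m) == 3.1))
  # exactly one failed fit -> one invalid cell
  tab2 <- tab; tab2$valid[37] <- FALSE
  m2 <- assembleMap(tab2, pitch = c(50, 20))
  expect_equal(sum(!mapValid(m2)), 1L)
  # non-raster coordinates are rejected with offenders listed
  tab3 <- tab; tab3$x_um[3] <- tab3$x_um[3] + 23
  expect_error(assembleMap(tab3, pitch = c(50, 20)), "raster")
})

test_that("a fitted osteon disk recovers its generating chord length", {
  tissues <- defaultTissueParams()
  tissues$meanT <- c(3.0, 3.5, 3.0, 3.5)
  tissues$sdT <- rep(0.02, 4)
  cfg <- sceneConfig(width_um = 500, height_um = 300, osteonalFraction = 1,
                     osteonAreaFraction = 0.25, canalDiameter = 0,
                     lacunaFraction = 0, tissues = tissues, seed = 3)
  scene <- makeScene(cfg)
  scan <- renderScan(scene, noise = FALSE)
  tab <- fitScan(scan$profiles, scan$coords)
  map <- assembleMap(tab, pitch = scene@pitch)
  inDisk <- sceneLabels(scene) == "osteon" & mapValid(map)
  expect_gt(sum(inDisk), 10)
  expect_lt(abs(mean(mapValues(map)[inDisk]) - 3.5), 0.05)
  matrixPix <- sceneLabels(scene) == "interstitial" & mapValid(map)
  expect_lt(abs(mean(mapValues(map)[matrixPix]) - 3.0), 0.05)
})

test_that("ROI statistics use the population coefficient of variation", {
  m <- ParamMap(matrix(4, 6, 8), pitch = c(50, 20))
  r <- roiStatistics(m, roiWidth = 100)
  expect_true(all(r$cv[!r$empty] == 0))
  # hand-computed example: ROI values {1,1} and {1,3}
  m2 <- ParamMap(matrix(c(1, 1, 1, 3), 2, 2), pitch = c(50, 20))
  r2 <- roiStatistics(m2, roiWidth = 50)
  expect_equal(r2$cv, c(0, 0.5))
  expect_error(roiStatistics(m, roiWidth = 10), "pitch")
  # empty ROI flagged
  vals <- matrix(1, 2, 2); vals[, 2] <- NA
  r3 <- roiStatistics(ParamMap(vals, pitch = c(50, 20)), roiWidth = 50)
  expect_true(r3$empty[2])
})

test_that("histograms are percent of bone area and skewness is adjusted
           Fisher-Pearson", {
  h <- histogramStats(rep(3, 50))
  expect_equal(sum(h$pct), 100)
  expect_equal(sum(h$pct > 0), 1L)
  set.seed(5)
  hs <- histogramStats(rnorm(4000, 3.2, 0.1))
  expect_equal(sum(hs$pct), 100)
  se <- sqrt(6 * 4000 * 3999 / (3998 * 4001 * 4003))
  expect_lt(abs(hs$skewness), 3 * se)
  # the two-tissue mixture with the larger low-T area fraction skews negative
  set.seed(6)
  mix <- c(rnorm(7000, 3.4, 0.15), rnorm(3000, 3.0, 0.12))
  expect_lt(histogramStats(mix)$skewness, 0)
  expect_error(histogramStats(numeric(0)), "valid")
})

test_that("single-Gaussian summary extracts T_MAX and T_FWHM", {
  set.seed(8)
  v <- rnorm(5e4, 3.0, 0.2)
  f <- fitSingleGaussian(v)
  expect_equal(f$TMAX, 3.0, tolerance = 0.01)
  expect_equal(f$TFWHM, 2 * sqrt(2 * log(2)) * 0.2, tolerance = 0.02)
  # translation equivariance
  f2 <- fitSingleGaussian(v + 0.5)
  expect_equal(f2$TMAX - f$TMAX, 0.5, tolerance = 0.01)
  expect_equal(f2$TFWHM, f$TFWHM, tolerance = 0.01)
  expect_error(fitSingleGaussian(rep(3, 100)), "bins")
})

test_that("two-population decomposition recovers a bimodal mixture", {
  set.seed(11)
  v <- c(rnorm(6e4, 3.4, 0.15), rnorm(4e4, 3.0, 0.12))
  dec <- decomposeTwoPopulations(v)
  cmp <- dec@components
  expect_lt(abs(cmp$TMAX[1] - 3.0), 0.02)
  expect_lt(abs(cmp$TMAX[2] - 3.4), 0.02)
  expect_gt(dec@rSquared, 0.995)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-3)
  expect_equal(cmp$weight[1], 0.4, tolerance = 0.05)
  # nested models: the pair fit is never worse than the single fit
  expect_gte(dec@rSquared, dec@single[["rSquared"]] - 1e-9)
  # the same holds on clearly unimodal data, where the fit degenerates but
  # still converges with both means inside one bin width
  set.seed(12)
  u <- rnorm(2e4, 3.2, 0.15)
  du <- decomposeTwoPopulations(u)
  expect_lt(abs(diff(du@components$TMAX)),
            max(du@histogram$binWidth, 0.05) + 1e-9)
  expect_gte(du@rSquared, du@single[["rSquared"]] - 1e-9)
  expect_error(decomposeTwoPopulations(rep(3, 100)), "bins")
})

test_that("population masks split co-registered maps at the equal-density
           crossing", {
  # two tissues generated with interparticle distances 4.0 and 4.4 nm
  tissues <- defaultTissueParams()
  tissues$meanT <- c(3.0, 3.4, 3.0, 3.4)
  tissues$meanBeta <- 2 * pi * tissues$meanT / c(4.0, 4.4, 4.0, 4.4)
  tissues$sdBeta <- rep(0.02, 4)
  cfg <- sceneConfig(width_um = 2000, height_um = 1000,
                     lacunaFraction = 0.005, tissues = tissues, seed = 4)
  scene <- makeScene(cfg)
  maps <- list(T = sceneMap(scene, "T"),
               orderExtent = sceneMap(scene, "orderExtent"),
               d = sceneMap(scene, "d"))
  dec <- decomposeTwoPopulations(maps$T)
  thr <- populationThreshold(dec)
  expect_gt(thr, 3.0); expect_lt(thr, 3.4)
  stats <- populationOrderStats(maps, dec)
  dlow <- stats$median[stats$map == "d" & stats$population == "low"]
  dhigh <- stats$median[stats$map == "d" & stats$population == "high"]
  expect_lt(abs(dlow - 4.0), 0.05)
  expect_lt(abs(dhigh - 4.4), 0.05)
  # identical populations split roughly in half
  set.seed(13)
  u <- rnorm(1e4, 3.2, 0.1)
  mu <- ParamMap(matrix(u, 100, 100), pitch = c(50, 20))
  su <- populationOrderStats(list(T = mu), decomposeTwoPopulations(mu))
  frac <- su$n[su$population == "low"] / sum(su$n)
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
  # threshold outside the data range is an error
  shifted <- ParamMap(matrix(u + 1, 100, 100), pitch = c(50, 20))
  expect_error(populationOrderStats(list(T = shifted), dec), "range")
})

test_that("map statistics ignore raster traversal order", {
  set.seed(14)
  vals <- matrix(runif(200, 3, 4), 10, 20)
  m <- ParamMap(vals, pitch = c(50, 20))
  mt <- ParamMap(vals[10:1, 20:1], pitch = c(50, 20))
  expect_equal(histogramStats(m)$pct, histogramStats(mt)$pct)
  expect_equal(histogramStats(m)$skewness, histogramStats(mt)$skewness)
})
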
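test_that("the wavelet template reproduces smooth inputs and rejects narrow
           spikes", {
  wn <- seq(100, 3200, by = 1)
  # low-order polynomial passes through almost unchanged
  y <- 100 + 0.05 * wn + 1e-5 * (wn - 1500)^2 - 3e-9 * (wn - 400)^3
  tpl <- backgroundTemplate(RamanSpectrum(wn, y))
  expect_lt(max(abs(tpl@intensity - y)) / diff(range(y)), 0.01)
  # constant input gives a constant template
  tc <- backgroundTemplate(RamanSpectrum(wn, rep(5, length(wn))))
  expect_equal(tc@intensity, rep(5, length(wn)), tolerance = 1e-8)
  # narrow spikes stay in the residual (> 90 percent of their energy)
  smooth <- 200 + 50 * sin(wn / 400)
  spikes <- 80 * exp(-(wn - 900)^2 / 18) + 60 * exp(-(wn - 2500)^2 / 14)
  tps <- backgroundTemplate(RamanSpectrum(wn, smooth + spikes))
  resid <- smooth + spikes - tps@intensity
  expect_gt(sum(resid^2) / sum(spikes^2), 0.9)
  expect_error(backgroundTemplate(RamanSpectrum(1:50, rnorm(50))), "short")
})

test_that("perfect reconstruction of the underlying periodized transform", {
  set.seed(31)
  x <- rnorm(1024)
  dec <- qsaxsi:::.dwt(x, 5)
  expect_equal(qsaxsi:::.idwt(dec), x, tolerance = 1e-12)
  # energy is preserved (orthonormal filter bank)
  e <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
  expect_equal(e, sum(x^2), tolerance = 1e-10)
})

test_that("background subtraction finds the generating scale", {
  wn <- seq(100, 3200, by = 1)
  shape <- 300 * qsaxsi:::.bg_shape(wn)
  tpl <- RamanSpectrum(wn, shape)
  sub <- subtractBackground(RamanSpectrum(wn, 2.5 * shape), tpl)
  expect_equal(sub$scale, 2.5, tolerance = 1e-9)
  expect_lt(max(abs(sub$corrected@intensity)), 1e-9)
  # zero spectrum -> zero scale, zero corrected
  sub0 <- subtractBackground(RamanSpectrum(wn, rep(0, length(wn))), tpl)
  expect_equal(sub0$scale, 0)
  expect_equal(sub0$corrected@intensity, rep(0, length(wn)))
  # subtraction is idempotent: re-estimating on the corrected spectrum
  samp <- synthRaman(150, noiseSD = 0.5, seed = 33)
  tpl2 <- backgroundTemplate(synthRaman(250, includeBands = FALSE,
                                        noiseSD = 0.5, seed = 32))
  once <- subtractBackground(samp, tpl2)
  again <- suppressWarnings(subtractBackground(once$corrected, tpl2))
  expect_lt(abs(again$scale), 0.01 * once$scale)
})

test_that("band fitting localizes Gaussian bands to their centers", {
  wn <- seq(100, 3200, by = 1)
  one <- 50 * exp(-(wn - 960)^2 / (2 * 7^2))
  bf <- fitBands(RamanSpectrum(wn, one))
  i <- which(bf$band == "nu1PO4")
  expect_true(bf$present[i])
  expect_equal(bf$center[i], 960, tolerance = 0.01)
  expect_equal(bf$area[i], 50 * 7 * sqrt(2 * pi), tolerance = 0.01)
  # two overlapping CH-region bands at SNR 100
  set.seed(34)
  two <- 100 * exp(-(wn - 2880)^2 / (2 * 20^2)) +
    80 * exp(-(wn - 2940)^2 / (2 * 20^2)) + rnorm(length(wn), 0, 1)
  cfg <- defaultBandConfig()
  cfg <- rbind(cfg, data.frame(name = "nuCH2880", center = 2880, sigma = 20))
  bf2 <- fitBands(RamanSpectrum(wn, two), config = cfg)
  expect_equal(bf2$center[bf2$band == "nuCH2880"], 2880, tolerance = 0.1)
  expect_equal(bf2$center[bf2$band == "nuCH"], 2940, tolerance = 0.5)
  # a flat spectrum has no bands
  bf3 <- fitBands(RamanSpectrum(wn, rnorm(length(wn), 0, 0.5)))
  expect_false(any(bf3$present))
})

test_that("band areas scale linearly and centers resist the background", {
  wn <- seq(100, 3200, by = 1)
  s1 <- synthRaman(150, includeBackground = FALSE, noiseSD = 0)
  b1 <- fitBands(s1)
  bk <- fitBands(RamanSpectrum(wn, 3 * s1@intensity))
  expect_equal(bk$area, 3 * b1$area, tolerance = 1e-6)
  # centers move by < 0.05 cm^-1 when a (subtracted) background was present
  ref <- synthRaman(250, includeBands = FALSE, noiseSD = 0)
  tpl <- backgroundTemplate(ref)
  s2 <- subtractBackground(synthRaman(150, noiseSD = 0), tpl)$corrected
  b2 <- fitBands(s2)
  expect_lt(max(abs(b2$center - b1$center), na.rm = TRUE), 0.05)
})

test_that("band ratios are area ratios with named-denominator errors", {
  fit <- data.frame(band = c("nu1PO4", "nu1CO3", "amideI", "nuCH"),
                    center = c(960, 1070, 1660, 2940), sigma = 10,
                    fwhm = 23.5, area = c(2, 2, 2, 1),
                    present = TRUE)
  r <- bandRatios(fit)
  expect_equal(r[["nu1PO4/amideI"]], 1)
  expect_equal(r[["nu1PO4/nuCH"]], 2)
  expect_equal(r[["nu1CO3/nu1PO4"]], 1)
  fit$present[fit$band == "nuCH"] <- FALSE
  expect_error(bandRatios(fit), "nuCH")
})

test_that("a generated temperature trend in the mineral-to-organic ratio is
           recovered monotonically", {
  temps <- c(25, 100, 150, 190, 210)
  ratios <- vapply(temps, function(tc) {
    bf <- fitBands(synthRaman(tc, includeBackground = FALSE, noiseSD = 0))
    bandRatios(bf)[["nu1PO4/nuCH"]]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_equal(spearmanRho(temps, ratios)$rho, 1)
})
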
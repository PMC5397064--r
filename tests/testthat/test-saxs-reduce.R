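test_that("pixel-to-q mapping follows q = 4*pi*sin(theta)/lambda", {
  g <- ScatteringGeometry()
  expect_equal(pixelToQ(g, g@beamCenter), 0)
  # a pixel at radial distance r = L sits at 2*theta = 45 degrees
  px <- g@beamCenter + c(0, g@distance * 1000 / g@pixelSize[2])
  expect_equal(pixelToQ(g, px), 4 * pi * sin(pi / 8) / g@wavelength,
               tolerance = 1e-12)
  expect_equal(pixelToQ(g, px), 72.1, tolerance = 1e-3)
  # doubling the wavelength halves q (small angles)
  g2 <- ScatteringGeometry(wavelength = 2 * g@wavelength)
  p2 <- g@beamCenter + c(30, 40)
  expect_equal(pixelToQ(g2, p2) / pixelToQ(g, p2), 0.5, tolerance = 1e-3)
  # q is monotone in radial pixel distance
  qs <- pixelToQ(g, cbind(g@beamCenter[1], g@beamCenter[2] + 0:50))
  expect_true(all(diff(qs) > 0))
})

test_that("azimuthal integration averages pixels into half-open q bins", {
  g <- smallGeometry()
  qb <- defaultQBins(c(0.05, 3), 50)
  prof <- azimuthalIntegrate(matrix(7, 96, 96), g, qb)
  ok <- prof@nPixels > 0
  expect_true(any(ok))
  expect_true(all(prof@intensity[ok] == 7))
  expect_true(all(prof@sd[prof@nPixels > 1] == 0))
  expect_true(all(is.na(prof@intensity[!ok])))
  expect_error(azimuthalIntegrate(matrix(1, 96, 96), g, qb,
                                  mask = matrix(FALSE, 96, 96)),
               "usable")
})

test_that("integration is photometrically consistent with the raw frame", {
  g <- smallGeometry()
  set.seed(2)
  fr <- matrix(rpois(96 * 96, 50), 96, 96)
  bins <- c(0, seq(1e-6, 10, length.out = 50))   # cover every pixel q
  prof <- azimuthalIntegrate(fr, g, bins)
  expect_equal(sum(prof@intensity * prof@nPixels, na.rm = TRUE), sum(fr))
})

test_that("an isotropic synthetic frame reproduces its radial function", {
  g <- smallGeometry()
  f <- function(q) 100 / (1 + (q / 0.8)^2)
  q <- qsaxsi:::.q_map(g)
  frame <- f(q)
  prof <- azimuthalIntegrate(frame, g, defaultQBins(c(0.1, 3), 60))
  ok <- prof@nPixels > 3
  relDev <- abs(prof@intensity[ok] - f(prof@q[ok])) / f(prof@q[ok])
  expect_lt(median(relDev), 0.01)
  # finer bins shrink the discretization error
  prof2 <- azimuthalIntegrate(frame, g, defaultQBins(c(0.1, 3), 240))
  ok2 <- prof2@nPixels > 3
  expect_lt(median(abs(prof2@intensity[ok2] - f(prof2@q[ok2])) /
              f(prof2@q[ok2])),
            median(relDev))
})

test_that("the default mask removes the beamstop disk and module gaps", {
  g <- smallGeometry(n = 64L)
  expect_true(all(defaultMask(g, 0)))
  expect_true(!any(defaultMask(g, 200)))
  m <- defaultMask(g, 0, gapRows = 10L)
  expect_equal(sum(!m), 64L)
})

test_that("background profile subtraction needs a shared grid", {
  a <- RadialProfile(1:10, rep(5, 10), sd = rep(1, 10))
  b <- RadialProfile(1:10, rep(2, 10), sd = rep(1, 10))
  d <- subtractProfileBackground(a, b)
  expect_equal(d@intensity, rep(3, 10))
  expect_equal(d@sd, rep(sqrt(2), 10))
  expect_error(subtractProfileBackground(a, RadialProfile(2:11, rep(1, 10))),
               "grid")
})
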
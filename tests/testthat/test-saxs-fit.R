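test_that("Porod estimation is exact for an ideal q^-4 tail", {
  q <- seq(0.5, 4, length.out = 100)
  expect_equal(estimatePorod(RadialProfile(q, 7 / q^4))$P, 7)
  pe <- estimatePorod(RadialProfile(q, 7 / q^4 + 0.1))
  expect_equal(pe$P, 7)
  expect_equal(pe$background, 0.1)
  expect_error(estimatePorod(RadialProfile(q[1:4], 7 / q[1:4]^4)), "bins")
  expect_error(estimatePorod(RadialProfile(q, -7 / q^4 + 1e-6),
                             background = FALSE),
               "Porod")
})

test_that("Porod estimate from a deep stack-model tail is within 2 percent", {
  # window restricted to qT > 20 so the plateau is genuine
  q <- seq(0.1, 10, length.out = 400)
  pars <- list(T = 3.2, alpha = 2.5, beta = 1.2, P = 2)
  prof <- RadialProfile(q, evaluateProfile(q, pars) / q^2)
  pe <- estimatePorod(prof, window = c(20 / 3.2, 10))
  expect_lt(abs(pe$P - 2) / 2, 0.02)
})

test_that("noiseless stack-model fits recover the generating parameters", {
  prof <- noiselessProfile(T = 3.2, alpha = 2.5, beta = 1.2, P = 1)
  fit <- fitStackModel(prof, P = 1, weighted = FALSE)
  expect_true(fit@converged)
  expect_true(fit@valid)
  p <- fitParams(fit)
  expect_equal(Tchord(p), 3.2, tolerance = 1e-3)
  expect_equal(alphaOrder(p), 2.5, tolerance = 1e-3)
  expect_equal(betaPeriod(p), 1.2, tolerance = 1e-3)
  expect_gt(fit@rSquared, 1 - 1e-6)
  # degenerate inputs
  qc <- qValues(prof)
  expect_error(fitStackModel(RadialProfile(qc, rep(0, length(qc))), P = 1),
               "zero")
  expect_error(fitStackModel(RadialProfile(qc[1:10],
                                           intensities(prof)[1:10]), P = 1),
               "20")
})

test_that("free-Porod refit matches the fixed fit on clean data and repairs
           a mis-estimated P", {
  prof <- noiselessProfile(T = 3.2, alpha = 2.5, beta = 1.2, P = 1)
  fit <- fitStackModel(prof, P = 1, weighted = FALSE)
  both <- refitFreePorod(prof, fit, weighted = FALSE)
  expect_equal(Tchord(fitParams(both$free)), Tchord(fitParams(both$fixed)),
               tolerance = 1e-3)
  expect_equal(porodConstant(fitParams(both$free)), 1, tolerance = 1e-3)
  # P mis-estimated by 20 percent: the free refit recovers the truth
  biased <- fitStackModel(prof, P = 1.2, weighted = FALSE)
  repaired <- refitFreePorod(prof, biased, weighted = FALSE)$free
  expect_lt(abs(porodConstant(fitParams(repaired)) - 1), 0.05)
  expect_lt(abs(Tchord(fitParams(repaired)) - 3.2) / 3.2, 0.01)
  bad <- fit
  bad@converged <- FALSE
  expect_error(refitFreePorod(prof, bad), "converge")
})

test_that("the T estimator stays accurate under Poisson counting noise", {
  # 20 replicates at the default flux; the acceptance suite runs 100
  scene <- uniformScene(nx = 5, ny = 4)
  scan <- renderScan(scene, noise = TRUE, seed = 99)
  tab <- fitScan(scan$profiles, scan$coords)
  expect_true(all(tab$converged))
  err <- abs(tab$T_nm - 3.2) / 3.2
  expect_lt(median(err), 0.02)
  # approximate unbiasedness
  expect_lt(abs(median(tab$T_nm) - 3.2) / 3.2, 0.01)
})

test_that("fitScan flags voids from total counts and tabulates derived
           metrics", {
  scene <- uniformScene(nx = 4, ny = 3)
  scan <- renderScan(scene, noise = FALSE)
  # fake one void point by zeroing its profile
  p0 <- scan$profiles[[5]]
  scan$profiles[[5]] <- RadialProfile(qValues(p0),
                                      intensities(p0) * 1e-4,
                                      sd = intensitySD(p0),
                                      nPixels = pixelCounts(p0))
  tab <- fitScan(scan$profiles, scan$coords, freePorod = FALSE)
  expect_false(tab$is_bone[5])
  expect_true(all(tab$is_bone[-5]))
  ok <- tab$is_bone
  expect_equal(tab$order_extent[ok], 2 * pi / tab$alpha[ok])
  expect_equal(tab$d_nm[ok], tab$T_nm[ok] * 2 * pi / tab$beta[ok])
})
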
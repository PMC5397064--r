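test_that("a blurred edge yields a derivative lobe of FWHM 2.3548 sigma", {
  prof <- synthTEM(1, thicknessMean = 20, blurSigma = 2, noiseSD = 0)
  th <- thicknessFromProfile(prof, smoothing = 0)
  expect_length(th, 2L)   # one falling and one rising edge
  expect_equal(th, rep(2 * sqrt(2 * log(2)) * 2, 2), tolerance = 0.01,
               ignore_attr = TRUE)
  # the edge-pair reading returns the geometric dip width instead
  te <- thicknessFromProfile(prof, smoothing = 0, mode = "edgepair")
  expect_equal(te, attr(prof, "particles")$thickness, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("flat profiles produce no thickness estimates", {
  flat <- TEMProfile(seq(0, 31), rep(5, 32))
  expect_length(thicknessFromProfile(flat), 0L)
})

test_that("lobe FWHM tracks the generating blur over many particles", {
  prof <- synthTEM(200, thicknessMean = 20, blurSigma = 2, noiseSD = 0.3,
                   seed = 5)
  th <- thicknessFromProfile(prof)
  expect_gt(length(th), 300)
  expect_lt(abs(median(th) / (2 * sqrt(2 * log(2)) * 2) - 1), 0.05)
})

test_that("thickness estimates are invariant to offset and flip, and scale
           with position", {
  prof <- synthTEM(10, thicknessMean = 20, blurSigma = 2, noiseSD = 0,
                   seed = 3)
  base <- sort(thicknessFromProfile(prof, smoothing = 0))
  shifted <- TEMProfile(prof@position, prof@intensity + 123)
  expect_equal(sort(thicknessFromProfile(shifted, smoothing = 0)), base,
               tolerance = 1e-9)
  flipped <- TEMProfile(prof@position, rev(prof@intensity))
  expect_equal(sort(thicknessFromProfile(flipped, smoothing = 0)), base,
               tolerance = 1e-6)
  stretched <- TEMProfile(prof@position * 2, prof@intensity)
  expect_equal(sort(thicknessFromProfile(stretched, smoothing = 0)),
               2 * base, tolerance = 1e-9)
})

test_that("doubling the particle thickness doubles the dip width", {
  p1 <- synthTEM(20, thicknessMean = 10, blurSigma = 1, noiseSD = 0,
                 seed = 6)
  p2 <- synthTEM(20, thicknessMean = 20, blurSigma = 1, noiseSD = 0,
                 seed = 6)
  w1 <- thicknessFromProfile(p1, smoothing = 0, mode = "edgepair")
  w2 <- thicknessFromProfile(p2, smoothing = 0, mode = "edgepair")
  expect_equal(mean(w2) / mean(w1), 2, tolerance = 0.05)
})

test_that("group summaries exclude tiny groups and flag real shifts", {
  set.seed(9)
  ref <- rnorm(30, 5, 0.5)
  hot <- rnorm(30, 10, 1)
  expect_warning(res <- thicknessDistribution(
    list(ref = ref, hot = hot, bad = 3)), "bad")
  expect_equal(nrow(res$summary), 2L)
  p <- res$tests$p_value[1]
  expect_lt(p, 0.001)
  # identical groups are indistinguishable
  same <- thicknessDistribution(list(a = ref, b = ref))
  expect_gt(same$tests$p_value[1], 0.9)
  expect_error(thicknessDistribution(list(only = ref)), "2 groups")
})

test_that("synthetic TEM packing respects an explicit profile length", {
  expect_error(synthTEM(50, thicknessMean = 20, blurSigma = 2,
                        length_nm = 100), "packing")
  prof <- synthTEM(3, thicknessMean = 10, blurSigma = 1, length_nm = 500)
  expect_equal(max(prof@position), 500)
})
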
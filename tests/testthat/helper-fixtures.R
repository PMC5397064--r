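# Shared fixtures: noiseless profiles, small detector geometries, and the
# brute-force Mann-Whitney enumeration oracle.

# noiseless radial profile from the forward model on the default q grid
noiselessProfile <- function(T = 3.2, alpha = 2.5, beta = 1.2, P = 1,
                             qBins = defaultQBins()) {
  qc <- sqrt(qBins[-1] * qBins[-length(qBins)])
  pars <- list(T = T, alpha = alpha, beta = beta, P = P)
  RadialProfile(qc, evaluateProfile(qc, pars) / qc^2)
}

# compact detector for frame-based tests
smallGeometry <- function(n = 96L, distance = 300) {
  ScatteringGeometry(distance = distance, detectorShape = c(n, n),
                     beamCenter = c((n - 1) / 2, (n - 1) / 2))
}

# exhaustive two-sided Mann-Whitney p-value by enumerating all rank
# assignments under the null (no ties assumed)
enumerateMannWhitneyP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  Ustat <- function(xs, ys) sum(outer(xs, ys, ">"))
  u <- Ustat(x, y)
  uLow <- min(u, n1 * n2 - u)
  combs <- utils::combn(n1 + n2, n1)
  Us <- apply(combs, 2, function(idx) Ustat(pooled[idx], pooled[-idx]))
  min(1, mean(Us <= uLow) + mean(Us >= n1 * n2 - uLow))
}

# uniform one-tissue scene: every pixel carries the same parameters
uniformScene <- function(nx = 10, ny = 10, T = 3.2, alpha = 2.5,
                         beta = 1.2, P = 1) {
  tissues <- defaultTissueParams()
  tissues$meanT <- T; tissues$sdT <- 0
  tissues$meanAlpha <- alpha; tissues$sdAlpha <- 0
  tissues$meanBeta <- beta; tissues$sdBeta <- 0
  tissues$meanP <- P; tissues$sdP <- 0
  makeScene(sceneConfig(width_um = nx * 50, height_um = ny * 20,
                        osteonalFraction = 1, osteonAreaFraction = 0,
                        lacunaFraction = 0, tissues = tissues, seed = 1))
}
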
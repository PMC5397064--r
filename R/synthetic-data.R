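# Synthetic data generation: two-tissue bone scenes, Arrhenius heating,
# scattering profile / frame rendering with Poisson counting noise, Raman
# spectra with a growing fluorescence background, and TEM line profiles.

#' Default per-tissue nanostructure parameter distributions
#'
#' Osteons and fibrous packets (the younger, less mineral-mature tissues)
#' carry a higher mean chord length than interstitial matrix and lamellar
#' packets, with slightly tighter packing (higher beta, lower 2*pi/beta) and
#' more extended ordering decay (higher alpha): the contrast direction seen
#' between osteonal and interstitial bone in reference maps.
#'
#' @return data.frame, one row per tissue class.
#' @export
defaultTissueParams <- function() {
  data.frame(
    label = c("interstitial", "osteon", "lamellar", "fibrous"),
    meanT = c(3.0, 3.4, 3.0, 3.4),       sdT = c(0.07, 0.07, 0.07, 0.07),
    meanAlpha = c(2.1, 2.4, 2.1, 2.4),   sdAlpha = rep(0.12, 4),
    meanBeta = c(0.95, 1.10, 0.95, 1.10), sdBeta = c(0.05, 0.06, 0.05, 0.06),
    meanP = rep(1, 4),                   sdP = rep(0.05, 4))
}

#' Scene generator configuration
#'
#' Geometry defaults follow the scanning setup: 50 x 20 um scan step,
#' ~200 um osteons with central Haversian canals in an interstitial matrix
#' on one side, alternating lamellar/fibrous stripes (fibrolamellar bone) on
#' the other, plus scattered lacunae.
#'
#' @param width_um,height_um scene extent, micrometres.
#' @param pitch scan step (x, y), micrometres.
#' @param osteonalFraction fraction of the width (right side) occupied by
#'   osteonal bone; the rest is fibrolamellar.
#' @param osteonAreaFraction target osteon area fraction within the osteonal
#'   region.
#' @param osteonDiameter,osteonDiameterSD osteon size distribution, um.
#' @param canalDiameter Haversian canal diameter, um.
#' @param lacunaFraction fraction of pixels turned into lacuna voids.
#' @param stripePeriod fibrolamellar stripe period (one lamellar plus one
#'   fibrous stripe), um.
#' @param tissues per-tissue parameter table (see [defaultTissueParams()]).
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return list of class `"sceneConfig"`.
#' @export
sceneConfig <- function(width_um = 1000, height_um = 600, pitch = c(50, 20),
                        osteonalFraction = 0.5, osteonAreaFraction = 0.3,
                        osteonDiameter = 200, osteonDiameterSD = 20,
                        canalDiameter = 40, lacunaFraction = 0.01,
                        stripePeriod = 200,
                        tissues = defaultTissueParams(), seed = 1) {
  structure(list(width_um = width_um, height_um = height_um, pitch = pitch,
                 osteonalFraction = osteonalFraction,
                 osteonAreaFraction = osteonAreaFraction,
                 osteonDiameter = osteonDiameter,
                 osteonDiameterSD = osteonDiameterSD,
                 canalDiameter = canalDiameter,
                 lacunaFraction = lacunaFraction,
                 stripePeriod = stripePeriod, tissues = tissues,
                 seed = seed),
            class = "sceneConfig")
}

.scene_levels <- c("void", "osteon", "interstitial", "lamellar", "fibrous")

.truncnorm <- function(n, mean, sd, lo) pmax(rnorm(n, mean, sd), lo)

#' Generate a synthetic two-tissue bone scene
#'
#' Builds the label map (osteonal region: random non-overlapping osteon
#' disks with central canal voids in interstitial matrix; fibrolamellar
#' region: alternating lamellar/fibrous stripes; scattered lacunae) and
#' draws per-pixel nanostructure parameters from each tissue's
#' distribution.  Disk placement is greedy with a bounded number of
#' rejection attempts; candidates that would move the realized osteon area
#' fraction away from the target are rejected, and generation fails if the
#' target cannot be approached within 0.06.
#'
#' @param config a [sceneConfig()] list.
#' @return A [TissueScene-class] (unheated reference; `temperature = NA`).
#' @examples
#' sc <- makeScene(sceneConfig(width_um = 500, height_um = 400))
#' table(sceneLabels(sc))
#' @export
makeScene <- function(config = sceneConfig()) {
  stopifnot(inherits(config, "sceneConfig"))
  set.seed(config$seed)
  nx <- max(1L, round(config$width_um / config$pitch[1]))
  ny <- max(1L, round(config$height_um / config$pitch[2]))
  xc <- (seq_len(nx) - 0.5) * config$pitch[1]
  yc <- (seq_len(ny) - 0.5) * config$pitch[2]
  X <- matrix(rep(xc, each = ny), ny, nx)
  Y <- matrix(rep(yc, nx), ny, nx)
  lab <- matrix(match("interstitial", .scene_levels), ny, nx)

  # fibrolamellar stripes on the left
  xSplit <- config$width_um * (1 - config$osteonalFraction)
  fibro <- X < xSplit
  if (any(fibro)) {
    stripe <- (floor(Y / (config$stripePeriod / 2)) %% 2) == 0
    lab[fibro & stripe] <- match("lamellar", .scene_levels)
    lab[fibro & !stripe] <- match("fibrous", .scene_levels)
  }

  # osteon disks in the right region
  osteons <- data.frame(x = numeric(0), y = numeric(0), d = numeric(0))
  realized <- 0
  regionPix <- sum(!fibro)
  if (config$osteonAreaFraction > 0 && regionPix > 0) {
    target <- config$osteonAreaFraction
    attempts <- 0L; maxAttempts <- 4000L
    inOsteon <- matrix(FALSE, ny, nx)
    while (realized < target - 1e-9 && attempts < maxAttempts) {
      attempts <- attempts + 1L
      d <- max(.truncnorm(1, config$osteonDiameter,
                          config$osteonDiameterSD,
                          config$osteonDiameter / 2), config$canalDiameter * 2)
      cx <- runif(1, xSplit, config$width_um)
      cy <- runif(1, 0, config$height_um)
      if (nrow(osteons)) {
        dist <- sqrt((osteons$x - cx)^2 + (osteons$y - cy)^2)
        if (any(dist < (osteons$d + d) / 2)) next
      }
      cand <- !fibro & ((X - cx)^2 + (Y - cy)^2 <= (d / 2)^2)
      newFrac <- sum(inOsteon | cand) / regionPix
      if (abs(newFrac - target) > abs(realized - target)) next
      inOsteon <- inOsteon | cand
      osteons <- rbind(osteons, data.frame(x = cx, y = cy, d = d))
      realized <- newFrac
    }
    if (realized < target - 0.06)
      stop("osteon packing infeasible: reached area fraction ",
           signif(realized, 3), " after ", maxAttempts, " attempts")
    lab[inOsteon] <- match("osteon", .scene_levels)
    # central Haversian canals
    for (i in seq_len(nrow(osteons))) {
      canal <- (X - osteons$x[i])^2 + (Y - osteons$y[i])^2 <=
        (config$canalDiameter / 2)^2
      lab[canal] <- 1L
    }
  }

  # scattered osteocyte lacunae
  if (config$lacunaFraction > 0) {
    hit <- runif(ny * nx) < config$lacunaFraction
    lab[matrix(hit, ny, nx)] <- 1L
  }

  Tm <- matrix(NA_real_, ny, nx); Am <- Tm; Bm <- Tm; Pm <- Tm
  tt <- config$tissues
  for (i in seq_len(nrow(tt))) {
    li <- match(tt$label[i], .scene_levels)
    idx <- which(lab == li)
    if (!length(idx)) next
    Tm[idx] <- .truncnorm(length(idx), tt$meanT[i], tt$sdT[i], 0.5)
    Am[idx] <- .truncnorm(length(idx), tt$meanAlpha[i], tt$sdAlpha[i], 1.01)
    Bm[idx] <- .truncnorm(length(idx), tt$meanBeta[i], tt$sdBeta[i], 0.1)
    Pm[idx] <- .truncnorm(length(idx), tt$meanP[i], tt$sdP[i], 0.05)
  }
  new("TissueScene", labels = lab, levels = .scene_levels, T = Tm,
      alpha = Am, beta = Bm, P = Pm, pitch = as.numeric(config$pitch),
      temperature = NA_real_,
      meta = list(config = config, realizedOsteonFraction = realized,
                  osteons = osteons))
}

#' Apply Arrhenius heating to a scene
#'
#' Grows every bone pixel's chord length by the forward growth law
#' ([growT()]), inflates the within-tissue spread (reproducing the
#' broadening of the T distribution with temperature), and applies monotone
#' disorder trends: `alpha` increases (the ordering extent `2*pi/alpha`
#' shrinks) and `beta` decreases (the interparticle distance `T*2*pi/beta`
#' grows), both exponentially in the amount of growth.
#'
#' @param scene a reference [TissueScene-class].
#' @param temperatureC heating temperature, degrees C.
#' @param durationH heating duration in hours (default 1).
#' @param Ea activation energy, kJ/mol (default 33.1).
#' @param n growth exponent (default 1.42).
#' @param fwhmGrowth relative spread inflation per nm of growth.
#' @param alphaRate,betaRate relative disorder-trend rates per nm of growth.
#' @return The heated [TissueScene-class] (`temperature` slot set).
#' @export
heatScene <- function(scene, temperatureC, durationH = 1, Ea = 33.1,
                      n = 1.42, fwhmGrowth = 0.5, alphaRate = 0.15,
                      betaRate = 0.10) {
  stopifnot(is(scene, "TissueScene"))
  if (!is.finite(temperatureC) || temperatureC <= -273.15)
    stop("invalid heating temperature")
  delta <- growT(0, temperatureC, durationH, Ea, n)
  out <- scene
  Tm <- scene@T
  for (li in seq_along(scene@levels)[-1]) {
    idx <- which(scene@labels == li)
    if (!length(idx)) next
    m <- mean(scene@T[idx])
    Tm[idx] <- m + delta + (scene@T[idx] - m) * (1 + fwhmGrowth * delta)
  }
  out@T <- Tm
  out@alpha <- scene@alpha * exp(alphaRate * delta)
  out@beta <- scene@beta * exp(-betaRate * delta)
  out@temperature <- temperatureC
  out@meta$heating <- list(temperatureC = temperatureC,
                           durationH = durationH, Ea = Ea, n = n,
                           fwhmGrowth = fwhmGrowth, alphaRate = alphaRate,
                           betaRate = betaRate, delta = delta)
  out
}

# per-bin photon weights: the number of detector pixels in each q ring
.ring_weights <- function(qBins, geometry) {
  th <- asin(pmin(qBins * geometry@wavelength / (4 * pi), 1))
  r_px <- geometry@distance * tan(2 * th) /
    (mean(geometry@pixelSize) / 1000)
  pmax(1, round(pi * (r_px[-1]^2 - r_px[-length(r_px)]^2)))
}

#' Render scattering profiles for every scan point of a scene
#'
#' For each bone pixel the expected counts per q bin follow the
#' stack-of-cards forward model with that pixel's parameters, scaled by
#' `fluxScale` and by the detector ring occupancy of the bin; voids render
#' 1 percent of a nominal bone signal.  With `noise = TRUE` each bin's total
#' count is replaced by a Poisson draw; reported intensities are counts per
#' pixel with `sd = sqrt(N)/n_pixels`.  With `noise = FALSE` the profile
#' equals the forward model exactly.
#'
#' @param scene a [TissueScene-class].
#' @param qBins q-bin edges, nm^-1 (default [defaultQBins()]).
#' @param geometry detector geometry used for the ring occupancies.
#' @param fluxScale photon flux scale; the default gives peak expected
#'   counts of order 10^4 per bin for nominal tissue.
#' @param noise apply Poisson counting noise.
#' @param seed RNG seed for the noise draws.
#' @return list with `profiles` (list of [RadialProfile-class]) and `coords`
#'   (data.frame `x_um`, `y_um`, `row`, `col`, `label`).
#' @export
renderScan <- function(scene, qBins = defaultQBins(),
                       geometry = ScatteringGeometry(), fluxScale = 1,
                       noise = TRUE, seed = 1) {
  stopifnot(is(scene, "TissueScene"))
  if (!is.finite(fluxScale) || fluxScale <= 0)
    stop("'fluxScale' must be > 0")
  set.seed(seed)
  qc <- sqrt(qBins[-1] * qBins[-length(qBins)])
  w <- .ring_weights(qBins, geometry)
  nomI <- evaluateProfile(qc, list(T = 3, alpha = 2, beta = 1, P = 1)) / qc^2
  ny <- nrow(scene@labels); nx <- ncol(scene@labels)
  profiles <- vector("list", ny * nx)
  coords <- data.frame(x_um = rep(NA_real_, ny * nx), y_um = NA_real_,
                       row = NA_integer_, col = NA_integer_,
                       label = NA_character_)
  k <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    k <- k + 1L
    isVoid <- scene@labels[i, j] == 1L
    I <- if (isVoid) 0.01 * nomI
    else evaluateProfile(qc, list(T = scene@T[i, j],
                                  alpha = scene@alpha[i, j],
                                  beta = scene@beta[i, j],
                                  P = scene@P[i, j])) / qc^2
    m <- fluxScale * I * w
    if (noise) {
      N <- rpois(length(m), m)
      profiles[[k]] <- RadialProfile(qc, N / w, sd = sqrt(pmax(N, 1)) / w,
                                     nPixels = w)
    } else {
      profiles[[k]] <- RadialProfile(qc, fluxScale * I,
                                     sd = sqrt(pmax(m, 1)) / w, nPixels = w)
    }
    coords$x_um[k] <- (j - 0.5) * scene@pitch[1]
    coords$y_um[k] <- (i - 0.5) * scene@pitch[2]
    coords$row[k] <- i; coords$col[k] <- j
    coords$label[k] <- scene@levels[scene@labels[i, j]]
  }
  list(profiles = profiles, coords = coords)
}

#' Render an isotropic 2D detector frame for one parameter set
#'
#' Expected pixel counts follow `fluxScale * I(q(pixel))` with the
#' stack-of-cards model; optional Poisson noise.  Intended for exercising
#' the azimuthal integration on synthetic frames.
#'
#' @param params a [NanostructureParams-class] (or list with T, alpha, beta,
#'   P).
#' @param geometry a [ScatteringGeometry-class].
#' @param fluxScale intensity scale.
#' @param noise apply Poisson noise.
#' @param seed RNG seed.
#' @param qFloor q clamp (nm^-1) applied near the beam center where the
#'   model diverges; mask those pixels in real reductions.
#' @return Numeric counts matrix of the detector shape.
#' @export
renderFrame <- function(params, geometry, fluxScale = 1, noise = FALSE,
                        seed = 1, qFloor = 0.005) {
  q <- pmax(.q_map(geometry), qFloor)
  p <- .as_param_list(params)
  I <- .stack_kratky(q * p$T, p$T, p$alpha, p$beta, p$P) / q^2
  m <- fluxScale * I
  if (noise) {
    set.seed(seed)
    matrix(rpois(length(m), m), nrow(m), ncol(m))
  } else m
}

#' Default configuration for the Raman spectrum generator
#'
#' Band areas and temperature laws: organic bands (Amide I, C-H) shift to
#' lower wavenumbers and lose area with temperature while mineral bands stay
#' put, and a broad fluorescence background grows exponentially until it
#' dominates the spectrum at 250 degrees.
#'
#' @return list with `bands`, `grid`, `bg0`, `bgRate`, `noiseSD`,
#'   `unusableRatio`.
#' @export
ramanSimConfig <- function() {
  bands <- data.frame(
    name = c("nu2PO4", "nu4PO4", "nu1PO4", "nu1CO3", "amideIII",
             "deltaCH2", "amideI", "nuCH"),
    center = c(430, 590, 960, 1070, 1250, 1450, 1660, 2940),
    sigma = c(8, 9, 6, 9, 15, 12, 16, 22),
    area = c(300, 350, 2000, 350, 400, 450, 600, 1500),
    shift250 = c(0, 0, -0.5, -1.0, -1.5, -1.0, -3.5, -2.5),
    areaFactor250 = c(1, 1, 1, 1, 0.7, 0.7, 0.7, 0.7))
  list(bands = bands, grid = seq(100, 3200, by = 1), bg0 = 40,
       bgRate = 0.019, noiseSD = 2, unusableRatio = 10)
}

.bg_shape <- function(wn) {
  0.7 * exp(-((wn - 1300) / 1100)^2) + 0.5 * exp(-((wn - 2900) / 500)^2) + 0.3
}

#' Generate a synthetic Raman spectrum
#'
#' Sum of Gaussian bands whose centers shift and areas scale linearly with
#' temperature per the configuration, on top of a broad fluorescence
#' background growing exponentially with temperature, plus Gaussian noise.
#'
#' @param temperatureC sample temperature, degrees C (25 = reference).
#' @param config see [ramanSimConfig()].
#' @param seed RNG seed for the noise.
#' @param includeBands set `FALSE` for a pure-fluorescence spectrum.
#' @param includeBackground set `FALSE` for bands only.
#' @param noiseSD noise level override (`NULL` uses the config value).
#' @return A [RamanSpectrum-class].
#' @export
synthRaman <- function(temperatureC, config = ramanSimConfig(), seed = 1,
                       includeBands = TRUE, includeBackground = TRUE,
                       noiseSD = NULL) {
  set.seed(seed)
  wn <- config$grid
  frac <- max(0, (temperatureC - 25) / 225)
  y <- numeric(length(wn))
  if (includeBands) {
    b <- config$bands
    for (i in seq_len(nrow(b))) {
      area <- b$area[i] * b$areaFactor250[i]^frac
      cen <- b$center[i] + b$shift250[i] * frac
      y <- y + area / (b$sigma[i] * sqrt(2 * pi)) *
        exp(-(wn - cen)^2 / (2 * b$sigma[i]^2))
    }
  }
  if (includeBackground) {
    amp <- config$bg0 * exp(config$bgRate * (temperatureC - 25))
    y <- y + amp * .bg_shape(wn)
  }
  ns <- if (is.null(noiseSD)) config$noiseSD else noiseSD
  if (ns > 0) y <- y + rnorm(length(wn), 0, ns)
  RamanSpectrum(wn, y, label = sprintf("%g C", temperatureC))
}

#' Generate a synthetic TEM line profile
#'
#' Dark particle dips of drawn widths at non-overlapping positions along the
#' line, with Gaussian edge blur (an ideal edge blurred by sigma gives a
#' derivative lobe of FWHM `2.3548 * sigma`) and additive noise.
#'
#' @param nParticles number of particles along the line.
#' @param thicknessMean mean particle thickness, nm.
#' @param blurSigma Gaussian edge blur, nm.
#' @param seed RNG seed.
#' @param thicknessSD thickness spread (default 15 percent of the mean).
#' @param gapMean mean gap between particles, nm.
#' @param dx sampling step, nm.
#' @param depth dip depth in gray levels.
#' @param noiseSD additive noise sd.
#' @param length_nm optional fixed profile length; an error is raised when
#'   the particles cannot be packed into it.
#' @return A [TEMProfile-class] with the generated particle edges attached
#'   as attribute `"particles"`.
#' @export
synthTEM <- function(nParticles, thicknessMean = 5, blurSigma = 2, seed = 1,
                     thicknessSD = 0.15 * thicknessMean,
                     gapMean = 10 * blurSigma + 2 * thicknessMean, dx = 0.25,
                     depth = 40, noiseSD = 0, length_nm = NULL) {
  stopifnot(nParticles >= 1, thicknessMean > 0, blurSigma > 0, dx > 0)
  set.seed(seed)
  th <- pmax(rnorm(nParticles, thicknessMean, thicknessSD),
             thicknessMean / 4)
  gaps <- pmax(runif(nParticles + 1, 0.7 * gapMean, 1.3 * gapMean),
               6 * blurSigma)
  a <- numeric(nParticles); b <- numeric(nParticles)
  pos <- gaps[1]
  for (i in seq_len(nParticles)) {
    a[i] <- pos
    b[i] <- pos + th[i]
    pos <- b[i] + gaps[i + 1]
  }
  total <- pos
  if (!is.null(length_nm)) {
    if (total > length_nm)
      stop("infeasible packing: ", nParticles, " particles need ",
           signif(total, 4), " nm but only ", length_nm, " nm available")
    total <- length_nm
  }
  x <- seq(0, total, by = dx)
  y <- rep(100, length(x))
  for (i in seq_len(nParticles))
    y <- y - depth * (pnorm((x - a[i]) / blurSigma) -
                      pnorm((x - b[i]) / blurSigma))
  if (noiseSD > 0) y <- y + rnorm(length(y), 0, noiseSD)
  prof <- TEMProfile(x, y)
  attr(prof, "particles") <- data.frame(a = a, b = b, thickness = th)
  prof
}
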
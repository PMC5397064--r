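#' @import methods
#' @importFrom stats lm coef median mad quantile sd rnorm rpois runif
#'   setNames complete.cases optimize uniroot approx wilcox.test cor.test
#'   fivenum dnorm qnorm var
#' @importFrom utils head tail read.delim write.table
NULL

.valid_scalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.finite(x))
    return(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    return(sprintf("'%s' must be > 0", name))
  NULL
}

#' NanostructureParams: one scan point's stack-of-cards parameters
#'
#' Holds the four parameters of the stack-of-cards interference model for the
#' mineral phase of bone: the mean chord length `T` (nm), the dimensionless
#' order-decay parameter `alpha`, the dimensionless stacking-periodicity
#' parameter `beta`, and the Porod constant `P` (arbitrary intensity units
#' times nm^-4).  The derived order metrics -- the relative extent of ordering
#' `2*pi/alpha` and the typical interparticle distance `d = T*2*pi/beta` (nm)
#' -- are always recomputed from the slots, never stored.
#'
#' @slot T numeric(1), mean chord length in nm; must be > 0.
#' @slot alpha numeric(1), order-decay parameter; physical fits require
#'   `alpha >= 1` (forward intensity is non-negative everywhere).
#' @slot beta numeric(1), periodicity parameter; must be > 0.
#' @slot P numeric(1), Porod constant; must be > 0.
#'
#' @seealso [NanostructureParams()], [evaluateProfile()], [derivedOrder()]
#' @name NanostructureParams-class
#' @rdname NanostructureParams-class
#' @exportClass NanostructureParams
setClass("NanostructureParams",
  representation(T = "numeric", alpha = "numeric", beta = "numeric",
                 P = "numeric"),
  prototype(T = 3, alpha = 2, beta = 1, P = 1))

setValidity("NanostructureParams", function(object) {
  msgs <- c(.valid_scalar(object@T, "T"),
            .valid_scalar(object@alpha, "alpha", positive = FALSE),
            .valid_scalar(object@beta, "beta"),
            .valid_scalar(object@P, "P"))
  if (is.null(msgs) && object@alpha < 1)
    msgs <- "'alpha' must be >= 1 for a physical parameter set"
  if (length(msgs)) msgs else TRUE
})

#' Construct a NanostructureParams object
#'
#' @param T mean chord length, nm.
#' @param alpha order-decay parameter (>= 1 for physical parameter sets).
#' @param beta periodicity parameter (> 0).
#' @param P Porod constant (> 0, arbitrary intensity units).
#' @return A [NanostructureParams-class] object.
#' @examples
#' p <- NanostructureParams(T = 3.2, alpha = 2.5, beta = 1.2, P = 1)
#' derivedOrder(p)
#' @export
NanostructureParams <- function(T, alpha, beta, P) {
  new("NanostructureParams", T = as.numeric(T), alpha = as.numeric(alpha),
      beta = as.numeric(beta), P = as.numeric(P))
}

#' ScatteringGeometry: pinhole SAXS camera geometry
#'
#' Flat-detector, small-angle scattering geometry used to map detector pixels
#' to momentum transfer `q = 4*pi*sin(theta)/lambda`.
#'
#' @slot wavelength numeric(1), X-ray wavelength in nm.
#' @slot distance numeric(1), sample-to-detector distance in mm.
#' @slot pixelSize numeric(2), pixel pitch (row, col) in micrometres.
#' @slot beamCenter numeric(2), beam center (row, col), 0-based pixel units.
#' @slot detectorShape integer(2), detector dimensions (rows, cols).
#' @name ScatteringGeometry-class
#' @rdname ScatteringGeometry-class
#' @exportClass ScatteringGeometry
setClass("ScatteringGeometry",
  representation(wavelength = "numeric", distance = "numeric",
                 pixelSize = "numeric", beamCenter = "numeric",
                 detectorShape = "integer"))

setValidity("ScatteringGeometry", function(object) {
  msgs <- c(.valid_scalar(object@wavelength, "wavelength"),
            .valid_scalar(object@distance, "distance"))
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    msgs <- c(msgs, "'pixelSize' must be two positive numbers (row, col)")
  if (length(object@beamCenter) != 2L || any(!is.finite(object@beamCenter)))
    msgs <- c(msgs, "'beamCenter' must be two finite numbers (row, col)")
  if (length(object@detectorShape) != 2L || any(object@detectorShape < 1L))
    msgs <- c(msgs, "'detectorShape' must be two positive integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScatteringGeometry
#'
#' Defaults reproduce a Pilatus-2M-like setup: wavelength 0.0667 nm
#' (18.6 keV), 2100 mm flight path, 172 um square pixels.
#'
#' @param wavelength X-ray wavelength, nm.
#' @param distance sample-to-detector distance, mm.
#' @param pixelSize pixel pitch (row, col), micrometres.
#' @param beamCenter beam center (row, col), 0-based pixels.
#' @param detectorShape detector size (rows, cols).
#' @return A [ScatteringGeometry-class] object.
#' @export
ScatteringGeometry <- function(wavelength = 0.0667, distance = 2100,
                               pixelSize = c(172, 172),
                               beamCenter = (detectorShape - 1) / 2,
                               detectorShape = c(1679L, 1475L)) {
  detectorShape <- as.integer(detectorShape)
  new("ScatteringGeometry", wavelength = as.numeric(wavelength),
      distance = as.numeric(distance), pixelSize = as.numeric(pixelSize),
      beamCenter = as.numeric(beamCenter), detectorShape = detectorShape)
}

#' RadialProfile: azimuthally averaged 1D scattering profile
#'
#' @slot q numeric, bin-center momentum transfer in nm^-1, strictly
#'   increasing.
#' @slot intensity numeric, mean counts per usable pixel per bin; `NA` for
#'   empty bins.
#' @slot sd numeric, standard error of the bin mean; `NA` where undefined.
#' @slot nPixels numeric, usable pixel (or photon-weight) count per bin.
#' @name RadialProfile-class
#' @rdname RadialProfile-class
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(q = "numeric", intensity = "numeric", sd = "numeric",
                 nPixels = "numeric"))

setValidity("RadialProfile", function(object) {
  n <- length(object@q)
  msgs <- NULL
  if (length(object@intensity) != n || length(object@sd) != n ||
      length(object@nPixels) != n)
    msgs <- c(msgs, "q, intensity, sd and nPixels must have equal length")
  if (n > 1 && any(diff(object@q) <= 0))
    msgs <- c(msgs, "q must be strictly increasing")
  if (any(object@nPixels < 0, na.rm = TRUE))
    msgs <- c(msgs, "nPixels must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RadialProfile
#'
#' @param q bin centers, nm^-1 (strictly increasing).
#' @param intensity mean intensity per bin.
#' @param sd standard error per bin (optional).
#' @param nPixels usable pixels per bin (optional).
#' @return A [RadialProfile-class] object.
#' @export
RadialProfile <- function(q, intensity, sd = rep(NA_real_, length(q)),
                          nPixels = rep(1, length(q))) {
  new("RadialProfile", q = as.numeric(q), intensity = as.numeric(intensity),
      sd = as.numeric(sd), nPixels = as.numeric(nPixels))
}

#' StackFit: result of fitting the stack-of-cards model to one profile
#'
#' @slot params fitted [NanostructureParams-class].
#' @slot residualNorm weighted residual sum of squares on `q^2 I(q)`.
#' @slot rSquared coefficient of determination on `q^2 I(q)`.
#' @slot converged logical; optimizer convergence.
#' @slot valid logical; `FALSE` when the fit hit a parameter bound or did not
#'   converge (such points are excluded from maps, mirroring void exclusion).
#' @slot porodWindow numeric(2), q-window (nm^-1) used for the Porod constant.
#' @slot porodBackground flat background fitted together with P.
#' @slot freeP logical; `TRUE` when P was refined together with (T, alpha,
#'   beta) rather than held fixed.
#' @name StackFit-class
#' @rdname StackFit-class
#' @exportClass StackFit
setClass("StackFit",
  representation(params = "NanostructureParams", residualNorm = "numeric",
                 rSquared = "numeric", converged = "logical",
                 valid = "logical", porodWindow = "numeric",
                 porodBackground = "numeric", freeP = "logical"),
  prototype(porodWindow = c(NA_real_, NA_real_), porodBackground = 0,
            freeP = FALSE))

setValidity("StackFit", function(object) {
  if (length(object@rSquared) == 1L && is.finite(object@rSquared) &&
      object@rSquared > 1 + 1e-12)
    return("rSquared must be <= 1")
  TRUE
})

#' ParamMap: quantitative map of one nanostructure parameter
#'
#' A 2D raster of one fitted parameter over the scan grid, together with a
#' validity mask (voids such as Haversian canals and osteocyte lacunae, and
#' failed fits, are invalid) and the scan pixel pitch.
#'
#' @slot values numeric matrix (rows = y, cols = x); `NA` where invalid.
#' @slot valid logical matrix, same shape.
#' @slot pitch numeric(2), scan step (x, y) in micrometres.
#' @slot origin numeric(2), coordinates (x, y) of the first grid cell, um.
#' @slot parameter character(1), name of the mapped parameter.
#' @name ParamMap-class
#' @rdname ParamMap-class
#' @exportClass ParamMap
setClass("ParamMap",
  representation(values = "matrix", valid = "matrix", pitch = "numeric",
                 origin = "numeric", parameter = "character"),
  prototype(origin = c(0, 0), parameter = "T"))

setValidity("ParamMap", function(object) {
  msgs <- NULL
  if (!identical(dim(object@values), dim(object@valid)))
    msgs <- c(msgs, "values and valid must have identical dimensions")
  if (length(object@pitch) != 2L || any(object@pitch <= 0))
    msgs <- c(msgs, "pitch must be two positive numbers (x, y)")
  if (any(object@valid & is.na(object@values)))
    msgs <- c(msgs, "valid cells must carry finite values")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ParamMap
#'
#' @param values numeric matrix of parameter values (`NA` allowed).
#' @param valid logical matrix; defaults to finite cells of `values`.
#' @param pitch scan step (x, y), micrometres.
#' @param origin coordinates of the first cell (x, y), micrometres.
#' @param parameter name of the mapped parameter.
#' @return A [ParamMap-class] object.
#' @export
ParamMap <- function(values, valid = is.finite(values), pitch = c(50, 20),
                     origin = c(0, 0), parameter = "T") {
  values[!valid] <- NA_real_
  new("ParamMap", values = values, valid = valid, pitch = as.numeric(pitch),
      origin = as.numeric(origin), parameter = parameter)
}

#' PopulationDecomposition: Gaussian analysis of a T histogram
#'
#' Stores the single-Gaussian summary (`T_MAX`, `T_FWHM`) and the
#' two-population decomposition of a chord-length histogram, with components
#' in canonical order (lower mean first).
#'
#' @slot single named numeric: `TMAX`, `TFWHM`, `amplitude`, `rSquared` of the
#'   one-Gaussian fit.
#' @slot components data.frame with columns `TMAX`, `TFWHM`, `amplitude`,
#'   `weight` (area fraction), one row per population, ascending `TMAX`.
#' @slot rSquared coefficient of determination of the two-Gaussian fit.
#' @slot skewness adjusted Fisher-Pearson skewness of the raw values.
#' @slot histogram list with `mids`, `pct` (percent of bone area) and
#'   `binWidth` describing the fitted histogram.
#' @name PopulationDecomposition-class
#' @rdname PopulationDecomposition-class
#' @exportClass PopulationDecomposition
setClass("PopulationDecomposition",
  representation(single = "numeric", components = "data.frame",
                 rSquared = "numeric", skewness = "numeric",
                 histogram = "list"))

setValidity("PopulationDecomposition", function(object) {
  msgs <- NULL
  cmp <- object@components
  if (nrow(cmp)) {
    if (any(cmp$TFWHM <= 0)) msgs <- c(msgs, "component TFWHM must be > 0")
    if (any(cmp$weight <= 0)) msgs <- c(msgs, "component weights must be > 0")
    if (is.unsorted(cmp$TMAX))
      msgs <- c(msgs, "components must be ordered by ascending TMAX")
  }
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    msgs <- c(msgs, "rSquared must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' KineticsFit: Arrhenius fit of thermally activated particle growth
#'
#' @slot Ea activation energy, kJ/mol.
#' @slot n dimensionless growth exponent (from the regression intercept).
#' @slot T0max reference mean particle size, nm.
#' @slot slope,intercept coefficients of the regression of
#'   `ln(T_MAX - T0_MAX)` on `10^3 / T_K`.
#' @slot rSquared coefficient of determination of the regression.
#' @slot points data.frame of the fitted `(temperature_C, TMAX)` points.
#' @name KineticsFit-class
#' @rdname KineticsFit-class
#' @exportClass KineticsFit
setClass("KineticsFit",
  representation(Ea = "numeric", n = "numeric", T0max = "numeric",
                 slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", points = "data.frame"))

#' RamanSpectrum: a single Raman spectrum
#'
#' @slot wavenumber numeric, cm^-1, strictly increasing.
#' @slot intensity numeric, arbitrary counts.
#' @slot label character(1), sample / temperature tag.
#' @name RamanSpectrum-class
#' @rdname RamanSpectrum-class
#' @exportClass RamanSpectrum
setClass("RamanSpectrum",
  representation(wavenumber = "numeric", intensity = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("RamanSpectrum", function(object) {
  msgs <- NULL
  if (length(object@wavenumber) != length(object@intensity))
    msgs <- c(msgs, "wavenumber and intensity must have equal length")
  if (length(object@wavenumber) > 1 && any(diff(object@wavenumber) <= 0))
    msgs <- c(msgs, "wavenumber must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RamanSpectrum
#' @param wavenumber cm^-1 grid (strictly increasing).
#' @param intensity counts.
#' @param label sample tag.
#' @return A [RamanSpectrum-class] object.
#' @export
RamanSpectrum <- function(wavenumber, intensity, label = "") {
  new("RamanSpectrum", wavenumber = as.numeric(wavenumber),
      intensity = as.numeric(intensity), label = label)
}

#' TEMProfile: line-intensity profile extracted from a TEM image
#'
#' @slot position numeric, nm along the sampling line, strictly increasing,
#'   at least 16 samples.
#' @slot intensity numeric, arbitrary gray level.
#' @name TEMProfile-class
#' @rdname TEMProfile-class
#' @exportClass TEMProfile
setClass("TEMProfile",
  representation(position = "numeric", intensity = "numeric"))

setValidity("TEMProfile", function(object) {
  msgs <- NULL
  if (length(object@position) != length(object@intensity))
    msgs <- c(msgs, "position and intensity must have equal length")
  if (length(object@position) < 16L)
    msgs <- c(msgs, "a TEM profile needs at least 16 samples")
  if (any(diff(object@position) <= 0))
    msgs <- c(msgs, "position must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TEMProfile
#' @param position nm along the line.
#' @param intensity gray values.
#' @return A [TEMProfile-class] object.
#' @export
TEMProfile <- function(position, intensity) {
  new("TEMProfile", position = as.numeric(position),
      intensity = as.numeric(intensity))
}

#' TissueScene: synthetic two-tissue bone cross-section
#'
#' Label map over the scan grid plus per-pixel nanostructure parameter fields,
#' emulating a bovine cortical cross-section: an osteonal region (disks of
#' osteon tissue with central Haversian canals in interstitial matrix) next to
#' a fibrolamellar region (alternating lamellar/fibrous stripes), with
#' scattered lacunae.
#'
#' @slot labels integer matrix indexing into `levels`.
#' @slot levels character vector of tissue class names; index 1 is `"void"`.
#' @slot T,alpha,beta,P numeric matrices of per-pixel parameters (`NA` in
#'   voids).
#' @slot pitch numeric(2), scan step (x, y) in micrometres.
#' @slot temperature numeric(1), heating temperature in degrees C attached to
#'   the scene (`NA` for the unheated reference).
#' @slot meta list of generation metadata (config, seed, realized fractions).
#' @name TissueScene-class
#' @rdname TissueScene-class
#' @exportClass TissueScene
setClass("TissueScene",
  representation(labels = "matrix", levels = "character", T = "matrix",
                 alpha = "matrix", beta = "matrix", P = "matrix",
                 pitch = "numeric", temperature = "numeric", meta = "list"),
  prototype(temperature = NA_real_, meta = list()))

setValidity("TissueScene", function(object) {
  msgs <- NULL
  dm <- dim(object@labels)
  for (s in c("T", "alpha", "beta", "P"))
    if (!identical(dim(slot(object, s)), dm))
      msgs <- c(msgs, sprintf("'%s' matrix shape differs from labels", s))
  if (length(object@pitch) != 2L || any(object@pitch <= 0))
    msgs <- c(msgs, "pitch must be two positive numbers")
  if (any(object@labels < 1L | object@labels > length(object@levels)))
    msgs <- c(msgs, "labels must index into levels")
  if (length(msgs)) msgs else TRUE
})
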
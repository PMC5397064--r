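# Accessor generics and show methods for the core data classes.

#' @rdname NanostructureParams-class
#' @param object,x a package object.
#' @export
setGeneric("Tchord", function(x) standardGeneric("Tchord"))
#' @rdname NanostructureParams-class
#' @export
setGeneric("alphaOrder", function(x) standardGeneric("alphaOrder"))
#' @rdname NanostructureParams-class
#' @export
setGeneric("betaPeriod", function(x) standardGeneric("betaPeriod"))
#' @rdname NanostructureParams-class
#' @export
setGeneric("porodConstant", function(x) standardGeneric("porodConstant"))

#' @rdname NanostructureParams-class
#' @export
setMethod("Tchord", "NanostructureParams", function(x) x@T)
#' @rdname NanostructureParams-class
#' @export
setMethod("alphaOrder", "NanostructureParams", function(x) x@alpha)
#' @rdname NanostructureParams-class
#' @export
setMethod("betaPeriod", "NanostructureParams", function(x) x@beta)
#' @rdname NanostructureParams-class
#' @export
setMethod("porodConstant", "NanostructureParams", function(x) x@P)

setMethod("show", "NanostructureParams", function(object) {
  d <- derivedOrder(object)
  cat(sprintf(
    "NanostructureParams: T = %.4g nm, alpha = %.4g, beta = %.4g, P = %.4g\n",
    object@T, object@alpha, object@beta, object@P))
  cat(sprintf("  order extent 2pi/alpha = %.4g, d = T*2pi/beta = %.4g nm\n",
              d[["orderExtent"]], d[["d"]]))
})

#' @rdname RadialProfile-class
#' @param x a `RadialProfile`.
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname RadialProfile-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname RadialProfile-class
#' @export
setGeneric("intensitySD", function(x) standardGeneric("intensitySD"))
#' @rdname RadialProfile-class
#' @export
setGeneric("pixelCounts", function(x) standardGeneric("pixelCounts"))

#' @rdname RadialProfile-class
#' @export
setMethod("qValues", "RadialProfile", function(x) x@q)
#' @rdname RadialProfile-class
#' @export
setMethod("intensities", "RadialProfile", function(x) x@intensity)
#' @rdname RadialProfile-class
#' @export
setMethod("intensitySD", "RadialProfile", function(x) x@sd)
#' @rdname RadialProfile-class
#' @export
setMethod("pixelCounts", "RadialProfile", function(x) x@nPixels)

setMethod("show", "RadialProfile", function(object) {
  ok <- is.finite(object@intensity)
  cat(sprintf("RadialProfile: %d bins (%d non-empty), q in [%.4g, %.4g] nm^-1\n",
              length(object@q), sum(ok), min(object@q), max(object@q)))
})

setMethod("show", "ScatteringGeometry", function(object) {
  cat(sprintf(
    "ScatteringGeometry: lambda = %.4g nm, L = %.4g mm, pixels %g x %g um,\n",
    object@wavelength, object@distance, object@pixelSize[1],
    object@pixelSize[2]))
  cat(sprintf("  detector %d x %d, beam center (%.1f, %.1f)\n",
              object@detectorShape[1], object@detectorShape[2],
              object@beamCenter[1], object@beamCenter[2]))
})

#' @rdname StackFit-class
#' @param x,object a `StackFit`.
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname StackFit-class
#' @export
setMethod("fitParams", "StackFit", function(x) x@params)
#' @rdname StackFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname StackFit-class
#' @export
setMethod("isConverged", "StackFit", function(x) x@converged)

setMethod("show", "StackFit", function(object) {
  p <- object@params
  cat(sprintf(
    "StackFit (%s): T = %.4g nm, alpha = %.4g, beta = %.4g, P = %.4g\n",
    if (object@freeP) "free P" else "fixed P",
    p@T, p@alpha, p@beta, p@P))
  cat(sprintf("  r^2 = %.6f, converged = %s, valid = %s\n",
              object@rSquared, object@converged, object@valid))
})

#' @rdname ParamMap-class
#' @param x,object a `ParamMap`.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname ParamMap-class
#' @export
setMethod("mapValues", "ParamMap", function(x) x@values)
#' @rdname ParamMap-class
#' @export
setGeneric("mapValid", function(x) standardGeneric("mapValid"))
#' @rdname ParamMap-class
#' @export
setMethod("mapValid", "ParamMap", function(x) x@valid)
#' @rdname ParamMap-class
#' @export
setGeneric("mapPitch", function(x) standardGeneric("mapPitch"))
#' @rdname ParamMap-class
#' @export
setMethod("mapPitch", "ParamMap", function(x) x@pitch)

setMethod("show", "ParamMap", function(object) {
  cat(sprintf("ParamMap of '%s': %d x %d cells, pitch %g x %g um, %d valid\n",
              object@parameter, nrow(object@values), ncol(object@values),
              object@pitch[1], object@pitch[2], sum(object@valid)))
})

setMethod("show", "PopulationDecomposition", function(object) {
  cat(sprintf("PopulationDecomposition: single T_MAX = %.3f nm, T_FWHM = %.3f nm\n",
              object@single[["TMAX"]], object@single[["TFWHM"]]))
  cmp <- object@components
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  population %d: T_MAX = %.3f nm, T_FWHM = %.3f nm, weight = %.2f\n",
                i, cmp$TMAX[i], cmp$TFWHM[i], cmp$weight[i]))
  cat(sprintf("  pair r^2 = %.4f, histogram skewness = %.3f\n",
              object@rSquared, object@skewness))
})

setMethod("show", "KineticsFit", function(object) {
  cat(sprintf("KineticsFit: Ea = %.3f kJ/mol, n = %.3f (T0_MAX = %.3f nm)\n",
              object@Ea, object@n, object@T0max))
  cat(sprintf("  ln(T_MAX - T0_MAX) = %.4f + %.4f * (10^3/T_K), r^2 = %.6f\n",
              object@intercept, object@slope, object@rSquared))
})

setMethod("show", "RamanSpectrum", function(object) {
  cat(sprintf("RamanSpectrum '%s': %d points, %g-%g cm^-1\n", object@label,
              length(object@wavenumber), min(object@wavenumber),
              max(object@wavenumber)))
})

setMethod("show", "TEMProfile", function(object) {
  cat(sprintf("TEMProfile: %d samples over %g nm\n", length(object@position),
              diff(range(object@position))))
})

#' @rdname TissueScene-class
#' @param x,object a `TissueScene`.
#' @export
setGeneric("sceneLabels", function(x) standardGeneric("sceneLabels"))
#' @rdname TissueScene-class
#' @export
setMethod("sceneLabels", "TissueScene", function(x) {
  structure(x@levels[x@labels], dim = dim(x@labels))
})

#' Extract one per-pixel parameter field of a scene as a ParamMap
#'
#' @param x a [TissueScene-class].
#' @param parameter one of `"T"`, `"alpha"`, `"beta"`, `"P"`,
#'   `"orderExtent"` (2*pi/alpha) or `"d"` (T*2*pi/beta).
#' @return A [ParamMap-class] with voids invalid.
#' @export
setGeneric("sceneMap", function(x, parameter = "T") standardGeneric("sceneMap"))
#' @rdname sceneMap
#' @export
setMethod("sceneMap", "TissueScene", function(x, parameter = "T") {
  vals <- switch(parameter,
    T = x@T, alpha = x@alpha, beta = x@beta, P = x@P,
    orderExtent = 2 * pi / x@alpha,
    d = x@T * 2 * pi / x@beta,
    stop("unknown scene parameter: ", parameter))
  ParamMap(vals, valid = is.finite(vals), pitch = x@pitch,
           parameter = parameter)
})

setMethod("show", "TissueScene", function(object) {
  tab <- table(factor(object@levels[object@labels], levels = object@levels))
  cat(sprintf("TissueScene: %d x %d pixels, pitch %g x %g um, temperature %s\n",
              nrow(object@labels), ncol(object@labels), object@pitch[1],
              object@pitch[2],
              if (is.na(object@temperature)) "reference"
              else paste0(object@temperature, " C")))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})
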
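# Reduction of 2D detector frames to 1D radial profiles: pixel -> q mapping,
# masking and azimuthal averaging.

#' Map a detector pixel to momentum transfer
#'
#' Uses the flat-detector small-angle geometry: the radial distance `r` from
#' the beam center (mm) gives the scattering angle `2*theta = atan(r / L)` and
#' `q = 4*pi*sin(theta)/lambda`.
#'
#' @param geometry a [ScatteringGeometry-class].
#' @param pixel numeric(2) `(row, col)` 0-based pixel, or an n x 2 matrix.
#' @return q in nm^-1 (vectorized over rows of `pixel`).
#' @examples
#' g <- ScatteringGeometry()
#' pixelToQ(g, g@beamCenter)   # 0 at the beam center
#' @export
pixelToQ <- function(geometry, pixel) {
  stopifnot(is(geometry, "ScatteringGeometry"))
  validObject(geometry)
  if (is.null(dim(pixel))) pixel <- matrix(pixel, ncol = 2)
  dr <- (pixel[, 1] - geometry@beamCenter[1]) * geometry@pixelSize[1] / 1000
  dc <- (pixel[, 2] - geometry@beamCenter[2]) * geometry@pixelSize[2] / 1000
  r <- sqrt(dr^2 + dc^2)                       # mm in the detector plane
  theta <- 0.5 * atan(r / geometry@distance)
  4 * pi * sin(theta) / geometry@wavelength
}

# q value of every detector pixel, as a rows x cols matrix
.q_map <- function(geometry) {
  shp <- geometry@detectorShape
  rows <- matrix(seq_len(shp[1]) - 1, shp[1], shp[2])
  cols <- matrix(rep(seq_len(shp[2]) - 1, each = shp[1]), shp[1], shp[2])
  dr <- (rows - geometry@beamCenter[1]) * geometry@pixelSize[1] / 1000
  dc <- (cols - geometry@beamCenter[2]) * geometry@pixelSize[2] / 1000
  r <- sqrt(dr^2 + dc^2)
  4 * pi * sin(0.5 * atan(r / geometry@distance)) / geometry@wavelength
}

#' Default q-bin edges
#'
#' Log-spaced bin edges over the measurable q-range of the setup
#' (0.01-4.1 nm^-1 by default), 300 bins unless requested otherwise.
#'
#' @param qRange numeric(2), lower/upper q in nm^-1.
#' @param n number of bins.
#' @return Numeric vector of `n + 1` edges.
#' @export
defaultQBins <- function(qRange = c(0.01, 4.1), n = 300) {
  stopifnot(length(qRange) == 2, all(qRange > 0), qRange[2] > qRange[1],
            n >= 1)
  exp(seq(log(qRange[1]), log(qRange[2]), length.out = n + 1))
}

#' Beamstop and module-gap mask
#'
#' Marks unusable detector pixels: everything within `beamstopRadius` pixels
#' of the beam center, plus whole rows/columns covered by detector module
#' gaps.
#'
#' @param geometry a [ScatteringGeometry-class].
#' @param beamstopRadius radius in pixels (>= 0).
#' @param gapRows,gapCols integer vectors of 0-based gap rows / columns.
#' @return Logical matrix, `TRUE` = usable.
#' @export
defaultMask <- function(geometry, beamstopRadius = 0, gapRows = integer(),
                        gapCols = integer()) {
  stopifnot(beamstopRadius >= 0)
  shp <- geometry@detectorShape
  mask <- matrix(TRUE, shp[1], shp[2])
  if (beamstopRadius > 0) {
    rows <- matrix(seq_len(shp[1]) - 1, shp[1], shp[2])
    cols <- matrix(rep(seq_len(shp[2]) - 1, each = shp[1]), shp[1], shp[2])
    d2 <- (rows - geometry@beamCenter[1])^2 + (cols - geometry@beamCenter[2])^2
    mask[d2 <= beamstopRadius^2] <- FALSE
  }
  gapRows <- gapRows[gapRows >= 0 & gapRows < shp[1]]
  gapCols <- gapCols[gapCols >= 0 & gapCols < shp[2]]
  mask[gapRows + 1L, ] <- FALSE
  mask[, gapCols + 1L] <- FALSE
  mask
}

#' Azimuthal integration of a detector frame
#'
#' Averages pixel counts into q bins: for each half-open bin
#' `[edge_i, edge_{i+1})` the intensity is the unweighted mean of the usable
#' pixel values whose q falls inside, the uncertainty is the standard error of
#' that mean, and `nPixels` records the bin occupancy.  Empty bins carry
#' `NA` intensity and `nPixels = 0`.  No solid-angle or polarization
#' correction is applied; all downstream fitting uses relative intensities
#' only.
#'
#' @param counts numeric matrix of detector counts (rows x cols), >= 0.
#' @param geometry a [ScatteringGeometry-class] matching `dim(counts)`.
#' @param qBins bin edges in nm^-1 (see [defaultQBins()]).
#' @param mask logical matrix, `TRUE` = usable pixel; default all usable.
#' @return A [RadialProfile-class].
#' @examples
#' g <- ScatteringGeometry(distance = 300, detectorShape = c(64L, 64L),
#'                         beamCenter = c(31.5, 31.5))
#' frame <- matrix(7, 64, 64)
#' prof <- azimuthalIntegrate(frame, g, defaultQBins(c(0.05, 2), 40))
#' @export
azimuthalIntegrate <- function(counts, geometry, qBins = defaultQBins(),
                               mask = NULL) {
  stopifnot(is(geometry, "ScatteringGeometry"))
  if (!identical(dim(counts), as.integer(geometry@detectorShape)) &&
      !identical(dim(counts), geometry@detectorShape))
    stop("frame shape does not match geometry@detectorShape")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(counts), ncol(counts))
  if (!identical(dim(mask), dim(counts)))
    stop("mask shape does not match the frame")
  usable <- mask & is.finite(counts)
  if (!any(usable)) stop("no usable pixels: the frame is fully masked")

  qpix <- .q_map(geometry)[usable]
  vals <- counts[usable]
  # half-open bins [lo, hi): right = FALSE semantics via findInterval
  idx <- findInterval(qpix, qBins, left.open = FALSE, rightmost.closed = FALSE)
  inside <- idx >= 1L & idx <= (length(qBins) - 1L) & qpix < qBins[length(qBins)]
  idx <- idx[inside]; vals <- vals[inside]
  nb <- length(qBins) - 1L
  n <- tabulate(idx, nbins = nb)
  sums <- tapply(vals, factor(idx, levels = seq_len(nb)), sum)
  sums[is.na(sums)] <- 0
  mean_i <- ifelse(n > 0, as.numeric(sums) / n, NA_real_)
  ss <- tapply(vals^2, factor(idx, levels = seq_len(nb)), sum)
  ss[is.na(ss)] <- 0
  var_i <- ifelse(n > 1, (as.numeric(ss) - n * mean_i^2) / (n - 1), NA_real_)
  var_i[n > 1 & var_i < 0] <- 0          # guard tiny negative round-off
  se_i <- ifelse(n > 1, sqrt(var_i / n), ifelse(n == 1, 0, NA_real_))
  centers <- sqrt(qBins[-length(qBins)] * qBins[-1])   # geometric bin centers
  RadialProfile(q = centers, intensity = mean_i, sd = se_i, nPixels = n)
}

#' Subtract a background profile from a sample profile
#'
#' Optional per-scan background (e.g. Kapton/air) subtraction on a shared q
#' grid; uncertainties add in quadrature.
#'
#' @param profile,background [RadialProfile-class] objects on the same grid.
#' @param scale multiplier applied to the background before subtraction.
#' @return A background-subtracted [RadialProfile-class].
#' @export
subtractProfileBackground <- function(profile, background, scale = 1) {
  if (!isTRUE(all.equal(profile@q, background@q)))
    stop("profiles must share the same q grid")
  RadialProfile(q = profile@q,
                intensity = profile@intensity - scale * background@intensity,
                sd = sqrt(profile@sd^2 + (scale * background@sd)^2),
                nPixels = profile@nPixels)
}
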
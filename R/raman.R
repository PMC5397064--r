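# Raman analysis: wavelet fluorescence-baseline template, least-squares
# background subtraction, Gaussian band fitting and band-area ratios.

#' Default Raman fitting windows
#'
#' The four fitting regions used for the mineral and organic bands
#' (370-650, 750-1140, 1140-1550, 2800-3100 cm^-1) plus a fifth window
#' (1550-1750 cm^-1) that covers the Amide I band, which would otherwise
#' fall outside every region.
#'
#' @return list of numeric(2) windows, cm^-1.
#' @export
defaultRamanWindows <- function() {
  list(c(370, 650), c(750, 1140), c(1140, 1550), c(1550, 1750),
       c(2800, 3100))
}

#' Default band configuration
#'
#' Nominal band centers are conventional literature values for bone
#' (phosphate nu1 ~ 960 cm^-1, carbonate nu1 ~ 1070 cm^-1, Amide I ~ 1660
#' cm^-1, C-H stretch ~ 2940 cm^-1, plus the secondary phosphate and organic
#' bands); widths are starting values for the Gaussian fits.
#'
#' @return data.frame with columns `name`, `center`, `sigma`.
#' @export
defaultBandConfig <- function() {
  data.frame(
    name = c("nu2PO4", "nu4PO4", "nu1PO4", "nu1CO3", "amideIII",
             "deltaCH2", "amideI", "nuCH"),
    center = c(430, 590, 960, 1070, 1250, 1450, 1660, 2940),
    sigma = c(10, 10, 7, 10, 16, 14, 18, 24))
}

#' Smooth fluorescence background template from a reference spectrum
#'
#' Decomposes the reference spectrum (in practice the fully fluorescent
#' 250 degree one, which carries no usable bands) with a 7-level
#' Daubechies-11 wavelet transform and reconstructs from the approximation
#' only, discarding all detail coefficients.  The result is a smooth curve
#' that tracks features wider than roughly `2^levels` samples and ignores
#' the narrow vibrational bands.
#'
#' @param reference a [RamanSpectrum-class].
#' @param levels decomposition depth (default 7).
#' @return A [RamanSpectrum-class] holding the smooth template on the same
#'   wavenumber grid.
#' @export
backgroundTemplate <- function(reference, levels = 7) {
  stopifnot(is(reference, "RamanSpectrum"))
  smooth <- .wavelet_smooth(reference@intensity, levels = levels)
  RamanSpectrum(reference@wavenumber, smooth,
                label = paste0(reference@label, " background"))
}

#' Subtract a scaled background template from a spectrum
#'
#' Finds the non-negative scale `s` (and optionally a flat offset)
#' minimizing the squared difference between the spectrum and `s * template`
#' over the anchor regions (the full range by default), and returns
#' `spectrum - s * template`.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param template background template, resampled onto the spectrum grid if
#'   needed.
#' @param anchors optional list of `c(lo, hi)` wavenumber regions used to
#'   estimate the scale (peak-free regions reduce the small bias that bands
#'   induce in full-range fitting).
#' @param offset also fit a flat offset (default `FALSE`).
#' @return list with `corrected` (a [RamanSpectrum-class]), `scale` and
#'   `offset`.
#' @export
subtractBackground <- function(spectrum, template, anchors = NULL,
                               offset = FALSE) {
  stopifnot(is(spectrum, "RamanSpectrum"), is(template, "RamanSpectrum"))
  tv <- if (isTRUE(all.equal(spectrum@wavenumber, template@wavenumber)))
    template@intensity
  else approx(template@wavenumber, template@intensity,
              xout = spectrum@wavenumber, rule = 2)$y
  sel <- rep(TRUE, length(spectrum@wavenumber))
  if (!is.null(anchors)) {
    sel[] <- FALSE
    for (a in anchors)
      sel <- sel | (spectrum@wavenumber >= a[1] & spectrum@wavenumber <= a[2])
    if (!any(sel)) stop("anchor regions select no samples")
  }
  y <- spectrum@intensity[sel]; b <- tv[sel]
  if (offset) {
    fit <- lm(y ~ b)
    s <- unname(coef(fit)[2]); o <- unname(coef(fit)[1])
  } else {
    s <- if (sum(b^2) > 0) sum(y * b) / sum(b^2) else 0
    o <- 0
  }
  if (!is.finite(s) || s < 0) {
    warning("background scale clipped to 0 (template orthogonal to spectrum)")
    s <- 0
  }
  resid <- y - s * b - o
  if (s > 0 && sum(b^2) > 0 &&
      sum(resid^2) > 0.99 * sum((y - mean(y))^2) && sd(y) > 0)
    warning("background template explains almost none of the spectrum")
  RamanCorr <- RamanSpectrum(spectrum@wavenumber,
                             spectrum@intensity - s * tv - o,
                             label = spectrum@label)
  list(corrected = RamanCorr, scale = s, offset = o)
}

#' Gaussian band fitting in spectral windows
#'
#' For each window, jointly fits one Gaussian per configured band (plus a
#' flat per-window baseline that absorbs residual background) and reports
#' the center, width and integrated area of every band.  Windows whose
#' maximum signal does not rise above the noise floor are flagged absent,
#' mirroring spectra that heating has rendered unusable.
#'
#' @param corrected a background-corrected [RamanSpectrum-class].
#' @param windows list of `c(lo, hi)` fitting windows, cm^-1.
#' @param config band table (see [defaultBandConfig()]).
#' @param snr minimum peak signal-to-noise for a window to count as having
#'   signal (default 5).
#' @return data.frame of class `"bandFit"`: `band`, `center`, `sigma`,
#'   `fwhm`, `area`, `present`.
#' @export
fitBands <- function(corrected, windows = defaultRamanWindows(),
                     config = defaultBandConfig(), snr = 5) {
  stopifnot(is(corrected, "RamanSpectrum"))
  wn <- corrected@wavenumber; iv <- corrected@intensity
  out <- data.frame(band = config$name, center = NA_real_, sigma = NA_real_,
                    fwhm = NA_real_, area = NA_real_, present = FALSE)
  for (w in windows) {
    bidx <- which(config$center >= w[1] & config$center <= w[2])
    if (!length(bidx)) next
    sel <- wn >= w[1] & wn <= w[2]
    if (sum(sel) < 3L * length(bidx) + 3L) next
    x <- wn[sel]; y <- iv[sel]
    noise <- mad(diff(y)) / sqrt(2)
    if (max(y) - median(y) < snr * max(noise, 1e-12)) next  # window absent
    nb <- length(bidx)
    start <- c(vapply(bidx, function(i) {
      a0 <- max(approx(x, y, xout = config$center[i], rule = 2)$y, noise)
      c(a0, config$center[i], config$sigma[i])
    }, numeric(3)), median(y))
    lo <- c(rep(c(0, w[1], 1), nb), -Inf)
    hi <- c(rep(c(Inf, w[2], diff(w)), nb), Inf)
    dim(start) <- NULL
    model <- function(p) {
      yh <- rep(p[3 * nb + 1], length(x))
      for (k in seq_len(nb))
        yh <- yh + .gauss(x, p[3 * k - 2], p[3 * k - 1], p[3 * k])
      yh
    }
    res <- try(minpack.lm::nls.lm(
      par = start, fn = function(p) y - model(p), lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
    if (inherits(res, "try-error")) next
    p <- res$par
    # map each named band to the fitted component nearest its nominal center
    cen <- p[3 * seq_len(nb) - 1]
    for (k in seq_len(nb)) {
      i <- bidx[which.min(abs(config$center[bidx] - cen[k]))]
      j <- which(out$band == config$name[i])
      A <- p[3 * k - 2]; mu <- p[3 * k - 1]; sg <- abs(p[3 * k])
      if (A <= snr * noise / 2) next      # component buried in noise
      out$center[j] <- mu
      out$sigma[j] <- sg
      out$fwhm[j] <- 2 * sqrt(2 * log(2)) * sg
      out$area[j] <- A * sg * sqrt(2 * pi)
      out$present[j] <- TRUE
    }
  }
  class(out) <- c("bandFit", "data.frame")
  out
}

#' Band-area ratios
#'
#' The mineral-to-organic and carbonate-to-phosphate indicators:
#' `I(nu1PO4)/I(nuAmideI)`, `I(nu1PO4)/I(nuCH)` and `I(nu1CO3)/I(nu1PO4)`,
#' computed from integrated band areas.
#'
#' @param fit a `"bandFit"` data.frame from [fitBands()].
#' @return Named list of the three ratios.
#' @export
bandRatios <- function(fit) {
  area <- function(nm) {
    i <- which(fit$band == nm)
    if (!length(i) || !fit$present[i] || !is.finite(fit$area[i]))
      return(NA_real_)
    fit$area[i]
  }
  ratio <- function(numName, denName) {
    den <- area(denName)
    if (!is.finite(den) || den <= 0)
      stop("denominator band '", denName, "' is absent or has zero area")
    area(numName) / den
  }
  list("nu1PO4/amideI" = ratio("nu1PO4", "amideI"),
       "nu1PO4/nuCH" = ratio("nu1PO4", "nuCH"),
       "nu1CO3/nu1PO4" = ratio("nu1CO3", "nu1PO4"))
}
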
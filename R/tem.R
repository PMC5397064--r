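# Particle thickness estimation from TEM line-intensity profiles via the
# derivative / Gaussian-FWHM procedure.

.moving_average <- function(x, window) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  n <- length(x)
  pad <- floor(window / 2)
  xe <- c(rep(x[1], pad), x, rep(x[n], window - 1 - pad))
  as.numeric(stats::filter(xe, k, sides = 1))[window:(n + window - 1)]
}

.fit_lobe_gaussian <- function(pos, amp) {
  # moment start, then refine
  w <- amp / sum(amp)
  mu0 <- sum(w * pos)
  s0 <- sqrt(max(sum(w * (pos - mu0)^2), (min(diff(pos)) / 2)^2))
  res <- try(minpack.lm::nls.lm(
    par = c(A = max(amp), mu = mu0, sigma = s0),
    fn = function(p) amp - .gauss(pos, p[1], p[2], p[3]),
    lower = c(1e-12, min(pos) - diff(range(pos)), min(diff(pos)) / 10),
    upper = c(Inf, max(pos) + diff(range(pos)), 10 * diff(range(pos))),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  list(A = res$par[1], mu = res$par[2], sigma = abs(res$par[3]))
}

#' Local particle thickness from a TEM line profile
#'
#' Implements the derivative procedure: the (optionally smoothed) intensity
#' profile is differentiated, each derivative lobe above the noise threshold
#' is fitted with a Gaussian, and the FWHM `2*sqrt(2*ln 2)*sigma` of each
#' lobe is taken as a local thickness estimate.  A particle appearing as a
#' dark dip contributes two lobes (one falling, one rising edge); in the
#' default `"lobe"` mode each lobe yields one estimate (the literal reading
#' of the procedure, measuring the edge-blur width), while `"edgepair"` mode
#' pairs each falling edge with the next rising edge and reports the
#' center-to-center distance (the geometric dip width).
#'
#' @param profile a [TEMProfile-class].
#' @param smoothing moving-average window length in samples (default 5;
#'   0 or 1 disables smoothing).
#' @param mode `"lobe"` (default) or `"edgepair"`.
#' @param threshold lobes whose peak absolute derivative falls below
#'   `threshold * max(|derivative|, noise scale)` are ignored; default keeps
#'   lobes above 4 robust noise sd and above 10 percent of the strongest
#'   lobe.
#' @return Numeric vector of thickness estimates in nm (empty when the
#'   profile is flat); lobe details are attached as attribute `"lobes"`.
#' @export
thicknessFromProfile <- function(profile, smoothing = 5,
                                 mode = c("lobe", "edgepair"),
                                 threshold = 0.1) {
  stopifnot(is(profile, "TEMProfile"))
  mode <- match.arg(mode)
  if (smoothing < 0) stop("'smoothing' must be >= 0")
  x <- profile@position
  y <- .moving_average(profile@intensity, max(1, round(smoothing)))
  d <- diff(y) / diff(x)
  xm <- (x[-1] + x[-length(x)]) / 2
  noise <- mad(d)
  top <- max(abs(d))
  cut <- max(4 * noise, threshold * top)
  if (top == 0 || !any(abs(d) > cut)) {
    out <- numeric(0)
    attr(out, "lobes") <- data.frame(center = numeric(0), sigma = numeric(0),
                                     sign = numeric(0), fwhm = numeric(0))
    return(out)
  }
  # contiguous same-sign runs where |d| exceeds the cut
  above <- abs(d) > cut
  sgn <- sign(d)
  lab <- integer(length(d)); cur <- 0L
  for (i in seq_along(d)) {
    if (!above[i]) { lab[i] <- 0L; next }
    if (i == 1L || !above[i - 1L] || sgn[i] != sgn[i - 1L]) cur <- cur + 1L
    lab[i] <- cur
  }
  lobes <- list()
  for (k in seq_len(max(lab, 0L))) {
    idx <- which(lab == k)
    # extend the lobe down to the surrounding zero crossings for a stable fit
    i0 <- min(idx); i1 <- max(idx)
    while (i0 > 1L && sign(d[i0 - 1L]) == sgn[idx[1]] && abs(d[i0 - 1L]) > 0)
      i0 <- i0 - 1L
    while (i1 < length(d) && sign(d[i1 + 1L]) == sgn[idx[1]] &&
           abs(d[i1 + 1L]) > 0)
      i1 <- i1 + 1L
    seg <- i0:i1
    if (length(seg) < 3L) next
    fit <- .fit_lobe_gaussian(xm[seg], abs(d[seg]))
    if (is.null(fit)) next
    if (fit$sigma < median(diff(x))) next   # sub-sampling-width noise spike
    lobes[[length(lobes) + 1L]] <-
      data.frame(center = unname(fit$mu), sigma = unname(fit$sigma),
                 sign = sgn[idx[1]],
                 fwhm = 2 * sqrt(2 * log(2)) * unname(fit$sigma))
  }
  if (!length(lobes)) {
    out <- numeric(0)
    attr(out, "lobes") <- data.frame(center = numeric(0), sigma = numeric(0),
                                     sign = numeric(0), fwhm = numeric(0))
    return(out)
  }
  lob <- do.call(rbind, lobes)
  lob <- lob[order(lob$center), ]
  rownames(lob) <- NULL
  out <- if (mode == "lobe") lob$fwhm else {
    # pair each falling edge (negative lobe) with the next rising edge
    th <- numeric(0)
    i <- 1L
    while (i <= nrow(lob)) {
      if (lob$sign[i] < 0) {
        j <- which(lob$sign > 0 & seq_len(nrow(lob)) > i)
        if (length(j)) {
          th <- c(th, lob$center[j[1]] - lob$center[i])
          i <- j[1] + 1L
          next
        }
      }
      i <- i + 1L
    }
    th
  }
  attr(out, "lobes") <- lob
  out
}

#' Summarize thickness distributions per temperature group
#'
#' Per-group median and interquartile range plus pairwise Mann-Whitney
#' comparisons (the supplementary-table machinery).  Groups with fewer than
#' 2 estimates are excluded with a warning.
#'
#' @param groups named list of numeric thickness vectors (one per
#'   temperature / sample).
#' @return list with `summary` (data.frame: group, n, median, q25, q75) and
#'   `tests` (data.frame from [pairwiseGroupTests()]).
#' @export
thicknessDistribution <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    warning("excluding group(s) with fewer than 2 estimates: ",
            paste(names(groups)[sizes < 2], collapse = ", "))
    groups <- groups[sizes >= 2]
  }
  if (length(groups) < 2)
    stop("fewer than 2 usable groups after exclusion")
  summ <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = nm, n = length(v), median = qs[2], q25 = qs[1],
               q75 = qs[3])
  }))
  vals <- unlist(groups, use.names = FALSE)
  grp <- rep(names(groups), vapply(groups, length, integer(1)))
  list(summary = summ, tests = pairwiseGroupTests(vals, grp))
}
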
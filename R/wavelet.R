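# Periodized orthogonal discrete wavelet transform with the Daubechies-11
# filter (22 taps, 11 vanishing moments), used to isolate the smooth
# fluorescence baseline of Raman spectra.  The scaling filter is the
# standard orthonormal Daubechies family member; the quadrature-mirror
# highpass is derived from it.

.db11_lo <- c(
  4.49427427723651e-06, -3.4634984186984996e-05, 5.4439074699368475e-05,
  2.491525235528235e-04, -8.930232506662646e-04, -3.085928588151432e-04,
  4.928417656059041e-03, -3.3408588730144454e-03, -1.53648209062016e-02,
  2.0840904360181062e-02, 3.1335090219046076e-02, -6.64387856950252e-02,
  -4.6479955116684187e-02, 1.4981201246637849e-01, 6.60435881966832e-02,
  -2.7423084681794696e-01, -1.6227524502749036e-01, 4.1196436894790744e-01,
  6.856867749162006e-01, 4.4989976435604534e-01, 1.440670211506245e-01,
  1.8694297761471083e-02)

.db11_hi <- local({
  L <- length(.db11_lo)
  (-1)^(0:(L - 1)) * rev(.db11_lo)
})

# one analysis step of the periodized DWT; returns approximation and detail
.dwt_step <- function(x, h = .db11_lo, g = .db11_hi) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(h)
  idx <- (outer(seq(0, n - 2, by = 2), 0:(L - 1), "+") %% n) + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

# one synthesis step (transpose of the analysis operator; exact inverse for
# orthonormal filters on the periodized domain)
.idwt_step <- function(a, d, h = .db11_lo, g = .db11_hi) {
  n <- 2 * length(a)
  L <- length(h)
  y <- numeric(n)
  k2 <- seq(0, n - 2, by = 2)
  for (m in seq_len(L)) {
    pos <- ((k2 + m - 1) %% n) + 1
    y[pos] <- y[pos] + h[m] * a + g[m] * d
  }
  y
}

#' Multilevel periodized DWT (Daubechies-11)
#'
#' @param x numeric vector; length must be divisible by `2^levels`.
#' @param levels decomposition depth.
#' @return list with `approx` (coarsest approximation) and `details` (list of
#'   detail vectors, finest first).
#' @keywords internal
.dwt <- function(x, levels) {
  if (length(x) %% 2^levels != 0)
    stop("signal length must be divisible by 2^levels")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- .dwt_step(a)
    a <- s$a
    details[[j]] <- s$d
  }
  list(approx = a, details = details)
}

.idwt <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details)))
    a <- .idwt_step(a, decomp$details[[j]])
  a
}

# Smooth-baseline extraction.  The signal is detrended with its end-to-end
# line, extended on both sides by point-symmetric (C1) reflection so that
# boundary artifacts of the transform fall into the padding, the two far
# ends are joined with a cubic Hermite bridge to make the extension smoothly
# periodic, and the level-`levels` approximation (all details zeroed) of the
# periodized DWT is cropped back to the original support.
.wavelet_smooth <- function(y, levels = 7) {
  n <- length(y)
  if (n < 2^levels)
    stop("spectrum too short for a ", levels, "-level decomposition")
  k <- min(8L, n)
  i1 <- seq_len(k); i2 <- (n - k + 1L):n
  slope <- (mean(y[i2]) - mean(y[i1])) / (mean(i2) - mean(i1))
  line <- y[1] + slope * (seq_len(n) - 1)
  r <- y - line
  # C1 antisymmetric reflection padding on both sides
  p <- min(n - 1L, max(256L, 2^levels * 4L))
  left <- 2 * r[1] - r[(p + 1L):2L]
  right <- 2 * r[n] - r[(n - 1L):(n - p)]
  ext <- c(left, r, right)
  ne <- length(ext)
  # Hermite bridge joining the far ends into a smooth periodic signal
  block <- 2^levels
  pad <- block * ceiling((ne + max(64L, block / 2)) / block) - ne
  sEnd <- ext[ne] - ext[ne - 1]
  sBeg <- ext[2] - ext[1]
  t <- seq_len(pad) / (pad + 1)
  h00 <- 2 * t^3 - 3 * t^2 + 1; h10 <- t^3 - 2 * t^2 + t
  h01 <- -2 * t^3 + 3 * t^2;    h11 <- t^3 - t^2
  bridge <- h00 * ext[ne] + h10 * sEnd * (pad + 1) +
    h01 * ext[1] + h11 * sBeg * (pad + 1)
  dec <- .dwt(c(ext, bridge), levels)
  dec$details <- lapply(dec$details, function(d) numeric(length(d)))
  smooth <- .idwt(dec)[(p + 1L):(p + n)]
  smooth + line
}
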
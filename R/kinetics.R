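# Arrhenius analysis of thermally activated particle thickening, and the
# forward growth law used by the scene generator.

.GAS_R <- 8.31      # J mol^-1 K^-1

#' Forward Arrhenius growth of the mean particle size
#'
#' Grows the mean chord length according to
#' `T_MAX = T0_MAX + (t - t0)^(1/n) * exp(-Ea / (n * R * T_K))`, with time in
#' seconds and `Ea` in kJ/mol.  Monotone increasing in both temperature and
#' duration; `duration -> 0` returns `T0max`.
#'
#' @param T0max reference mean size, nm.
#' @param temperatureC heating temperature, degrees C (vectorized).
#' @param durationH heating duration, hours (default 1, as in a furnace run).
#' @param Ea activation energy, kJ/mol.
#' @param n dimensionless growth exponent (> 0).
#' @return Grown `T_MAX` in nm.
#' @examples
#' growT(3.0, c(100, 150, 190, 250), Ea = 33.1, n = 1.42)
#' @export
growT <- function(T0max, temperatureC, durationH = 1, Ea, n) {
  if (!is.finite(n) || n <= 0) stop("'n' must be > 0")
  if (any(temperatureC <= -273.15)) stop("temperature below absolute zero")
  if (any(durationH < 0)) stop("duration must be >= 0")
  TK <- temperatureC + 273.15
  tsec <- durationH * 3600
  T0max + tsec^(1 / n) * exp(-Ea * 1000 / (n * .GAS_R * TK))
}

#' Arrhenius fit of a T_MAX vs temperature series
#'
#' Ordinary least squares of `y = ln(T_MAX - T0_MAX)` on `x = 10^3 / T_K`.
#' With the heating time `t - t0` carried in seconds, the intercept equals
#' `ln(t - t0)/n`, which determines the growth exponent
#' `n = ln(duration_s) / intercept`, and the slope yields the activation
#' energy `Ea = -slope * n * R` in kJ/mol (slope taken per `10^3/K`,
#' `R = 8.31 J mol^-1 K^-1`).  Time is kept in seconds because with hours the
#' 1-hour intercept would be identically zero and `n` indeterminate.
#'
#' @param points data.frame (or matrix) with columns `temperature_C` and
#'   `TMAX` (nm); at least 3 points, all with `TMAX > T0max`.
#' @param T0max reference mean size, nm (from the unheated reference map).
#' @param durationH heating duration, hours.
#' @return A [KineticsFit-class].
#' @examples
#' temps <- c(100, 150, 170, 190, 210, 250)
#' pts <- data.frame(temperature_C = temps,
#'                   TMAX = growT(3.0, temps, Ea = 33.1, n = 1.42))
#' arrheniusFit(pts, T0max = 3.0)
#' @export
arrheniusFit <- function(points, T0max, durationH = 1) {
  points <- as.data.frame(points)
  if (!all(c("temperature_C", "TMAX") %in% names(points)))
    stop("'points' needs columns temperature_C and TMAX")
  if (nrow(points) < 3) stop("need at least 3 (temperature, T_MAX) points")
  bad <- which(points$TMAX <= T0max)
  if (length(bad))
    stop("T_MAX <= T0_MAX at temperature(s) ",
         paste(points$temperature_C[bad], collapse = ", "),
         " C; growth is not resolved there")
  if (durationH <= 0) stop("duration must be > 0")
  x <- 1000 / (points$temperature_C + 273.15)
  y <- log(points$TMAX - T0max)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  r2 <- if (var(y) > 0) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
        else 1
  n <- log(durationH * 3600) / intercept
  Ea <- -slope * n * .GAS_R    # kJ/mol (slope is per 10^3/K)
  new("KineticsFit", Ea = Ea, n = n, T0max = T0max, slope = slope,
      intercept = intercept, rSquared = r2,
      points = data.frame(temperature_C = points$temperature_C,
                          TMAX = points$TMAX, x = x, y = y))
}
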
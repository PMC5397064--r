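# End-to-end driver: simulate a heated series, render noisy scans, fit every
# point, map, decompose the T histograms and run the Arrhenius analysis.

#' Run the full heated-series pipeline on a synthetic scene
#'
#' Generates a reference scene, heats copies to each requested temperature,
#' renders Poisson-noised scattering profiles for every scan point, fits the
#' stack-of-cards model per point, assembles chord-length maps, decomposes
#' each map's histogram into the two tissue populations, and fits the
#' Arrhenius growth law per population (the reference decomposition provides
#' `T0_MAX`).
#'
#' @param config scene configuration ([sceneConfig()]).
#' @param temperatures heated temperatures in degrees C (the unheated
#'   reference is always included first).
#' @param durationH heating duration, hours.
#' @param Ea,n generation kinetics (kJ/mol; dimensionless).
#' @param fluxScale,noise passed to [renderScan()].
#' @param freePorod passed to [fitScan()].
#' @param seed base RNG seed; each temperature uses `seed + index`.
#' @param binWidth histogram bin width for the decompositions, nm.
#' @return list with `tmax` (data.frame: temperature_C, population, TMAX,
#'   TFWHM), `decompositions`, `fits` (per-population [KineticsFit-class]),
#'   `maps` and `tables`.
#' @export
runHeatingSeries <- function(config = sceneConfig(),
                             temperatures = c(100, 150, 170, 190, 210, 250),
                             durationH = 1, Ea = 33.1, n = 1.42,
                             fluxScale = 1, noise = TRUE, freePorod = TRUE,
                             seed = 1, binWidth = 0.02) {
  ref <- makeScene(config)
  temps <- c(NA_real_, temperatures)
  decs <- vector("list", length(temps))
  maps <- vector("list", length(temps))
  tables <- vector("list", length(temps))
  rows <- list()
  for (i in seq_along(temps)) {
    scene <- if (is.na(temps[i])) ref
             else heatScene(ref, temps[i], durationH = durationH,
                            Ea = Ea, n = n)
    scan <- renderScan(scene, fluxScale = fluxScale, noise = noise,
                       seed = seed + i)
    tab <- fitScan(scan$profiles, scan$coords, freePorod = freePorod)
    map <- assembleMap(tab, pitch = scene@pitch, parameter = "T")
    dec <- decomposeTwoPopulations(map, binWidth = binWidth)
    decs[[i]] <- dec; maps[[i]] <- map; tables[[i]] <- tab
    cmp <- dec@components
    rows[[length(rows) + 1L]] <- data.frame(
      temperature_C = rep(temps[i], 2), population = c("low", "high"),
      TMAX = cmp$TMAX, TFWHM = cmp$TFWHM, weight = cmp$weight)
  }
  tmax <- do.call(rbind, rows)
  fits <- list()
  for (popn in c("low", "high")) {
    refT <- tmax$TMAX[is.na(tmax$temperature_C) & tmax$population == popn]
    pts <- tmax[!is.na(tmax$temperature_C) & tmax$population == popn, ]
    pts <- data.frame(temperature_C = pts$temperature_C, TMAX = pts$TMAX)
    fits[[popn]] <- try(arrheniusFit(pts, T0max = refT,
                                     durationH = durationH), silent = TRUE)
  }
  list(tmax = tmax, decompositions = decs, fits = fits, maps = maps,
       tables = tables, temperatures = temps)
}
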
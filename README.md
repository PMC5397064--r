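# qsaxsi

Quantitative scanning small-angle X-ray scattering imaging (qsSAXSI) of the
bone mineral nanostructure, with the companion Raman and TEM analysis stages
used to study what early heating (< 300 °C) does to bone tissue.

Bone is a hierarchical composite: platelet-shaped mineral nanocrystals
(~3 nm thick) embedded in collagen, organized into histological units —
osteons in interstitial matrix, lamellar and fibrous packets in
fibrolamellar bone — each ~100–200 µm across. Because nanoscale properties
differ *between* these tissue types, spatially resolved measurements are
needed: a micro-focused X-ray beam is raster-scanned across a bone section,
every 2D scattering pattern is azimuthally averaged, and each 1D profile is
fitted with a nanostructure model, producing quantitative parameter maps at
the histological scale.

The package is aimed at SAXS practitioners and bone researchers who want
the full analysis chain as tested, scriptable R functions, exercised
end-to-end on synthetic two-tissue scenes so that no beamline data are
required.

## The model

The azimuthally averaged intensity `I(q)` of stacked mineral platelets is
fitted in Kratky form with the stack-of-cards interference model

    q²I(q) = P·T²·[q²T² + (α−1)(α²+β²)] / [q⁴T⁴ + 2(α²−β²)q²T² + (α²+β²)²]

with three shape parameters: the mean chord length **T** (nm), which under
a ~50 % mineral volume fraction measures platelet thickness and is related
to the volume fractions by `T = 4Φ(1−Φ)/σ`; the order-decay parameter **α**
(`2π/α` is the relative extent of stacking regularity); and the
periodicity parameter **β** (`d = T·2π/β` is the typical interparticle
distance). The Porod constant **P** = lim q⁴I(q) is estimated
independently from the high-q plateau.

Downstream analyses: per-parameter maps with void exclusion (Haversian
canals, lacunae), map histograms in percent of bone area, single-Gaussian
`T_MAX`/`T_FWHM` summaries, two-Gaussian population decomposition
(osteonal vs interstitial tissue), and the Arrhenius analysis of thermally
activated particle thickening,

    ln(T_MAX − T0_MAX) = (1/n)·ln(t − t₀) − Ea/(nR·T_K)

from which the activation energy `Ea` and growth exponent `n` are fitted.
Raman spectra are baseline-corrected with a 7-level Daubechies-11 wavelet
template and band-fitted with Gaussians; TEM line profiles yield particle
thicknesses from the FWHM of Gaussian fits to derivative lobes.
Nonparametric statistics (Mann-Whitney U, 90 % Hodges-Lehmann intervals,
Spearman ρ) compare tissue populations.

## Worked example

```r
library(qsaxsi)

# a 500 x 300 um synthetic bone scene (osteons + fibrolamellar stripes)
scene <- makeScene(sceneConfig(width_um = 500, height_um = 300, seed = 1))
scan  <- renderScan(scene, noise = TRUE, seed = 2)   # Poisson-noised profiles

# fit one osteon scan point: Porod estimate, fixed-P fit, free-P polish
i   <- which(scan$coords$label == "osteon")[1]
por <- estimatePorod(scan$profiles[[i]])
fit <- refitFreePorod(scan$profiles[[i]],
                      fitStackModel(scan$profiles[[i]], P = por$P))$free
fit
#> StackFit (free P): T = 3.505 nm, alpha = 2.217, beta = 1.05, P = 1.041
#>   r^2 = 0.999659, converged = TRUE, valid = TRUE
```

The generating truth at that pixel was T = 3.527 nm. Mapping and
decomposing the whole scan separates the two tissue populations:

```r
tab <- fitScan(scan$profiles, scan$coords)
map <- assembleMap(tab, pitch = c(50, 20))
decomposeTwoPopulations(map)
#> PopulationDecomposition: single T_MAX = 3.001 nm, T_FWHM = 0.198 nm
#>   population 1: T_MAX = 3.000 nm, T_FWHM = 0.193 nm, weight = 0.68
#>   population 2: T_MAX = 3.417 nm, T_FWHM = 0.243 nm, weight = 0.32
#>   pair r^2 = 0.7269, histogram skewness = 0.698
```

(the scene was generated with tissue means of 3.0 and 3.4 nm). A noiseless
growth series refits its kinetics exactly:

```r
temps <- c(100, 150, 170, 190, 210, 250)
pts <- data.frame(temperature_C = temps,
                  TMAX = growT(3.4, temps, Ea = 33.1, n = 1.42))
arrheniusFit(pts, T0max = 3.4)
#> KineticsFit: Ea = 33.100 kJ/mol, n = 1.420 (T0_MAX = 3.400 nm)
#>   ln(T_MAX - T0_MAX) = 5.7667 + -2.8050 * (10^3/T_K), r^2 = 1.000000
```

`runHeatingSeries()` chains all of the above — scene, heating, rendering,
fitting, mapping, decomposition, kinetics — for a whole temperature series.
See the methods vignette (`vignettes/qsaxsi-methods.Rmd`) for the model
assumptions, parameter choices and limitations.

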
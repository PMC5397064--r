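Package: qsaxsi
Title: Quantitative Scanning Small-Angle X-Ray Scattering Imaging of Bone
    Nanostructure
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multiscale analysis of heat-induced changes in the bone mineral
    nanostructure. Implements the stack-of-cards interference model for
    azimuthally averaged small-angle scattering profiles of mineralized
    collagen (mean chord length T, order-decay alpha, periodicity beta, Porod
    constant P), reduction of 2D detector frames to radial profiles,
    per-scan-point model fitting and assembly into quantitative parameter maps
    with void exclusion, histogram and two-population Gaussian decomposition of
    the T distribution, Arrhenius analysis of thermally activated particle
    thickening, wavelet (Daubechies-11) fluorescence-baseline correction and
    Gaussian band fitting of Raman spectra, derivative-FWHM particle thickness
    estimation from TEM line profiles, the nonparametric statistics used to
    compare tissue populations, and a synthetic two-tissue scene generator that
    emulates osteonal and fibrolamellar bovine cortical bone so that the whole
    pipeline can be exercised without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
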
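---
title: "Methods: quantitative scanning-SAXS imaging of bone nanostructure"
author: "qsaxsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative scanning-SAXS imaging of bone nanostructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsaxsi)
```

# The scattering model and its assumptions

Bone mineral is modelled as stacks of platelet-shaped nanocrystals embedded
in collagen. The azimuthally averaged SAXS intensity of such a system is
fitted in Kratky form,

$$q^2 I(q) = P\,T^2\,
  \frac{q^2T^2 + (\alpha-1)(\alpha^2+\beta^2)}
       {q^4T^4 + 2(\alpha^2-\beta^2)\,q^2T^2 + (\alpha^2+\beta^2)^2},$$

with the mean chord length $T$ (nm), the order-decay parameter $\alpha$ and
the periodicity parameter $\beta$. The denominator rewrites as
$(q^2T^2+\alpha^2-\beta^2)^2 + 4\alpha^2\beta^2$, strictly positive for all
real $q$, and the model obeys $q^4 I \to P$ (the Porod limit) with exact
first-order correction
$[(\alpha-1)(\alpha^2+\beta^2)-2(\alpha^2-\beta^2)]/(qT)^2$. The forward
intensity is non-negative everywhere iff $\alpha \ge 1$, which is why the
physical API enforces $\alpha \ge 1$ while the optimizer is merely bounded
there. Evaluation uses the reduced variable $u = qT$, which is numerically
identical to the $q$ form but better conditioned at large $q$.

Assumptions inherited from the model: isotropic (azimuthally averaged)
scattering; two-phase contrast (mineral/organic); relative intensity units
(no absolute calibration — $P$ carries the arbitrary detector units);
chord length related to volume fractions by $T = 4\Phi(1-\Phi)/\sigma$.
We expose that relation (`chordLength()`) but never substitute it into the
fit: its only analytic use here is the sensitivity statement that a drop of
$\Phi$ from 0.50 to 0.40 changes $T$ by 4 %.

# Reduction of detector frames

`pixelToQ()` uses the flat-detector small-angle geometry
($2\theta = \arctan(r/L)$, $q = 4\pi\sin\theta/\lambda$) with 0-based pixel
indices. `azimuthalIntegrate()` averages usable pixel counts into half-open
log-spaced q bins (300 bins over 0.01–4.1 nm$^{-1}$ by default, matching
the measurable range of the emulated setup; the binning itself is a package
choice) and reports the standard error of each bin mean. The bin statistic
is the unweighted pixel mean: no solid-angle or polarization correction is
applied, because all downstream fitting uses relative intensities only.
Background (air/Kapton) subtraction is off by default and available as
`subtractProfileBackground()`. Frames are accepted as in-memory matrices or
TIFF; profile tables are TSV.

# Fitting strategy

`estimatePorod()` fits $q^4 I = P + Bq^4$ by linear least squares over the
top 15 % of the measured q-range. With $q_{max}T \approx 12$ the plateau is
marginal, so this estimate carries a percent-level bias with the sign and
size given by the correction term above. `fitStackModel()` then fits
$(T, \alpha, \beta)$ on $q^2I$ by bounded Levenberg–Marquardt
(weights $1/\mathrm{sd}^2$ when uncertainties exist; bounds
$T \in (0, 20]$, $\alpha \in [1, 50]$, $\beta \in (0, 50]$), and
`refitFreePorod()` releases $P$ from the fixed-P solution. The batch driver
`fitScan()` applies the free-P polish by default: on noiseless profiles the
two solutions coincide, while under a marginal Porod window the polish
removes the induced ~1 % bias in $T$.

Initialization: $\alpha_0 = 2$, $\beta_0 = 1$; $T_0$ is read off the
interference maximum of $q^2I$ when one exists inside the range, else
$T_0 = 3$ nm (bone-typical). Non-convergence triggers a small deterministic
grid of jittered restarts; the lowest residual wins. Fits ending on a
parameter bound (including $\alpha$ pinned at 1) are flagged invalid and
excluded from maps, mirroring the exclusion of voids. Whether weighting is
used is configurable (`weighted`), defaulting to weighted, since the
original reduction chain does not document its choice.

# Maps, histograms and populations

`assembleMap()` places fits on the scan raster (snap tolerance 25 % of the
pitch) and invalidates failed fits and sub-threshold scan points. The
bone/void criterion — total profile counts above 10 % of the scan median —
is a package choice; the underlying exclusion of canals and lacunae is
standard but its original criterion is not documented. Non-square pixels
(50×20 µm scans) are kept as-is: all areal statistics count pixels, which
equals "percent of bone area" at constant pitch.

Histograms use a 0.02 nm bin width, below the ~0.05 nm practical
resolution of the mapping method, so binning never dominates; ordinates are
percent of bone area and sum to 100 exactly. Skewness is the adjusted
Fisher–Pearson coefficient. `roiStatistics()` partitions maps into vertical
ROIs and reports the population (n-denominator) coefficient of variation.

`fitSingleGaussian()` gives $T_{MAX}$ and
$T_{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. `decomposeTwoPopulations()` fits two
Gaussians with means initialized at the weighted 25th/75th percentiles and
equal amplitudes, plus a start embedding the single-Gaussian solution so
the pair fit can never be worse than the single fit (nested models).
Components are reported in canonical order (lower mean first), which breaks
label switching. Identifiability: on a unimodal histogram the second
component is unconstrained, so a nested-model F test (1 % level) decides
whether the pair fit improves on the single fit beyond noise; if not, the
degenerate solution with both components at the single mode is returned.
The population mask threshold is the equal-density crossing of the two
fitted components — a package choice recorded with the output, since the
original masking rule is not documented.

# Growth kinetics

`arrheniusFit()` regresses $\ln(T_{MAX} - T_{0MAX})$ on $10^3/T_K$;
the slope gives $E_a = -\mathrm{slope}\cdot n R$ (kJ/mol) and the
intercept gives $n = \ln(t-t_0)/\mathrm{intercept}$. Two unit choices
matter and are deliberate:

* **Time in seconds.** With hours, a 1 h heating gives
  $\ln(t-t_0) = 0$, the intercept would be forced through zero and $n$
  would be indeterminate. Seconds ($\ln 3600 \approx 8.19$) make the
  printed $(E_a, n)$ pairs internally consistent.
* **$T_{0MAX}$ from the unheated reference map.** The reference
  measurement defines the baseline; its nominal temperature label is
  metadata only. The heated points alone enter the regression (the
  reference would contribute $\ln 0$).

$n$ is estimated from the intercept rather than fixed at 1, because no
isothermal series exists to measure it directly.

# Raman analysis

The fluorescence baseline is estimated from a peak-free reference spectrum
(in a heating series, the fully fluorescent 250 °C spectrum) by a 7-level
Daubechies-11 discrete wavelet transform, keeping only the approximation.
The transform is implemented here as a periodized orthogonal DWT; boundary
handling is a package choice: the spectrum is detrended by its end-to-end
line, extended by C1 point-symmetric reflection so transform edge artifacts
fall into the padding, and closed into a smooth periodic signal with a
cubic Hermite bridge. A 7-level approximation keeps features wider than
roughly $2^7$ samples (~130 cm$^{-1}$ at 1 cm$^{-1}$ sampling) and rejects
the narrow vibrational bands.

`subtractBackground()` scales the template by least squares over the full
range by default; an anchor-region mode (peak-free intervals) is provided
because full-range fitting is slightly biased by the bands. `fitBands()`
fits one Gaussian per configured band per window plus a flat per-window
baseline that absorbs residual background. Windows follow the four
conventional regions (370–650, 750–1140, 1140–1550, 2800–3100 cm$^{-1}$)
plus a fifth window 1550–1750 cm$^{-1}$ added here so that the Amide I
band (~1660 cm$^{-1}$), required for the mineral-to-organic ratio
I(ν₁PO₄)/I(νAmide I), lies inside a fitted region. Nominal centers
(ν₁PO₄ ≈ 960, ν₁CO₃ ≈ 1070, νAmide I ≈ 1660, νCH ≈ 2940 cm$^{-1}$) are
conventional literature values shipped as an editable table. Windows whose
signal never rises above the noise floor are flagged absent, which is how
spectra rendered unusable by fluorescence behave downstream.

# TEM thickness estimation

Line profiles across well-separated particles are optionally smoothed
(5-point moving average by default — needed for noisy gray levels),
differentiated, and each derivative lobe above the noise threshold is
fitted with a Gaussian. The default (`mode = "lobe"`) reads "FWHM of each
Gaussian" literally: each lobe yields one local thickness estimate, which
for an ideal edge blurred by $\sigma_b$ equals $2.3548\,\sigma_b$. Because
it is physically ambiguous whether that quantity or the falling-to-rising
edge distance is the better particle thickness, both are implemented;
`mode = "edgepair"` pairs each falling edge with the next rising edge and
reports the geometric dip width. Direct gray-level segmentation is
deliberately not attempted (overlapping gray-level populations make it
unreliable). Estimates are invariant to intensity offsets and profile
direction, and scale with position units.

# What the synthetic scenes emulate — and what they do not

`makeScene()` builds a bovine cortical cross-section at the scan
resolution: ~200 µm osteon disks (diameter sd 20 µm, a realistic
biological spread that also smooths the greedy packing) with central
Haversian canals in interstitial matrix, alternating 200 µm-period
lamellar/fibrous stripes, and ~1 % lacuna voids. Per-tissue nanoscale
defaults, chosen once as bone-plausible values in the regime where the
interference maximum lies inside the measured q-range:

| tissue | T (nm) | α | β |
|---|---|---|---|
| interstitial, lamellar | 3.0 ± 0.07 | 2.1 ± 0.12 | 0.95 ± 0.05 |
| osteon, fibrous | 3.4 ± 0.07 | 2.4 ± 0.12 | 1.10 ± 0.06 |

with $P = 1.0 \pm 0.05$ throughout. The 0.4 nm offset between the younger
(osteon/fibrous) and older (interstitial/lamellar) tissue reproduces the
observed contrast direction; no measured per-tissue parameter table exists,
so these are generator choices, documented here and fixed.

`heatScene()` grows every bone pixel's $T$ by the forward Arrhenius law
(defaults $E_a = 33.1$ kJ/mol, $n = 1.42$, 1 h), inflates the within-tissue
spread proportionally to the growth (reproducing the broadening of the T
distribution), increases $\alpha$ and decreases $\beta$ exponentially in
the growth (loss of stacking regularity, larger interparticle distance).
The disorder trends are simple monotone laws: the real functional forms are
unknown, only the trend directions are.

`renderScan()` draws per-bin Poisson counts with expected values
proportional to the forward intensity times the detector ring occupancy of
each q bin (computed analytically from the geometry), so the high-q tail
carries realistic aggregate statistics; the default flux puts peak expected
counts near $10^4$. Voids render 1 % of a nominal bone signal.
`renderFrame()` renders isotropic 2D frames for exercising the reduction.

Not emulated: preferred nanoparticle orientation (anisotropic 2D
patterns), collagen D-banding (the 67 nm periodicity is outside the fitted
model), detector distortions and flat-field structure, physically detailed
fluorescence, or 2D TEM image formation. Passing tests on these scenes
therefore validate the analysis chain, not instrument artifacts or
orientation effects in real data.

# Numerical choices and degenerate inputs

* Optimizer: `minpack.lm` bounded Levenberg–Marquardt throughout; ties
  between restarts broken by lowest residual.
* All generators are fully deterministic given their seed; the test suite
  fixes seeds.
* Degenerate inputs error early with informative messages: empty masks,
  all-zero profiles, histograms with too few bins, growth series with
  $T_{MAX} \le T_{0MAX}$ (the offending temperature is named), constant
  inputs to Spearman.
* Exact Mann-Whitney p-values are used when $n_1 n_2 \le 400$ without
  ties (small enough to verify exhaustively), tie-corrected normal
  approximation otherwise; the Hodges-Lehmann 90 % interval comes from the
  U-distribution order statistics. No multiple-testing correction is
  applied, matching the reporting conventions this machinery mirrors —
  a documented limitation.

Problem sizes in the test suite are deliberate package choices that keep
the suite fast while leaving headroom on the statistics: the end-to-end
heated series runs a 1000×600 µm scene (600 scan points) over seven
temperatures with Poisson noise; the decomposition checks use $10^5$
samples; the replicate study of the $T$ estimator uses 100 noisy profiles.

# Known limitations

* The Porod window is marginal at $q_{max}T \approx 12$; the free-P polish
  compensates, but profiles truncated well below $q = 4$ nm$^{-1}$ will
  bias $P$ and hence $T$.
* The asymptotic Porod correction decays only as $(qT)^{-2}$ with a
  coefficient of order one-to-ten for tissue-like parameters, so $q^4I/P$
  approaches 1 to $10^{-4}$ only around $qT \gtrsim 10^3$.
* Two-population decomposition needs a few hundred valid pixels per
  population for stable $T_{MAX}$; below that, histogram noise dominates
  the component widths first.
* The Raman baseline template assumes the reference spectrum shares the
  background *shape* of the corrected spectra up to scale; a
  temperature-dependent shape change would leave structured residuals.
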
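---
title: "Methods: dual-band filter-array SPR imaging, simulation and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-band filter-array SPR imaging, simulation and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfaspri)
```

## The measurement principle

A surface-plasmon-resonance (SPR) sensor presents a reflectance dip whose
centre wavelength red-shifts linearly with the refractive index *n* of the
medium at the gold surface. Classically one tracks the dip wavelength with
a spectrometer; the sensitivity is the slope $S_\lambda$ in nm/RIU and the
smallest resolvable index change is set by how precisely the dip can be
located.

The dual-band filter-array readout replaces the spectrometer with two
interleaved interference filters in a 10 × 10 µm checkerboard: a narrow
band-pass A (583–598 nm) nested inside a wide band-pass AB (562–598 nm).
A monochrome camera sees a checkerboard image in which A-tiles carry the
band-1 intensity $I_A$ and AB-tiles the combined intensity $I_{AB}$; the
band-2 intensity is $I_B = I_{AB} - I_A$. The per-pixel spectral contrast

$$\gamma = \frac{I_A - I_B}{I_A + I_B} = \frac{2 I_A - I_{AB}}{I_{AB}}$$

is a ratiometric statistic: it is invariant under common intensity scaling
and its change tracks the sign of the resonance shift. Because $\gamma$
can be averaged over the whole field, its noise floor drops with the
number of pixels, which is the mechanism behind the improvement in
refractive-index detection limit over single-spectrum dip tracking.

## Forward optical model

`spectral_core` models everything in the wavelength domain on a uniform
grid (default 555–605 nm at 0.1 nm, well below the 4–5 nm filter edge
scale so that trapezoidal band integrals are accurate to much better than
one part in $10^5$):

* **Filters** (`make_passband()`): rectangular passbands with
  raised-cosine edges. Edge steepness is parameterised the way filter
  data sheets quote it — the wavelength span between the 50 % and
  0.005 %-of-peak transmission points (default 4.5 nm). Cut-on/cut-off
  are the 50 % points, the plateau transmits `peak` (default 0.85, i.e.
  above the 80 % specification of the fabricated filters). The true
  fabricated lineshape is unpublished; a raised cosine reproduces the
  quoted steepness metric without inventing further structure.
* **Resonance** (`dip_model()`, `spr_spectrum()`): a Gaussian dip of
  standard deviation `width_nm` and fractional `depth` on a flat
  `baseline`, whose centre moves as
  $\lambda_{dip}(n) = \lambda_0 + S_\lambda (n - n_0)$ with
  $S_\lambda = 244.7$ nm/RIU, the measured bulk sensitivity of the
  gold-grating chip. Rigorous grating electromagnetics is out of scope by
  design: the Gaussian-plus-linear-shift model is exactly the abstraction
  used for the published theoretical-sensitivity calculation.
* **Band intensities** (`band_intensity()`): trapezoid integral of
  reflectance × filter × illumination. The illumination defaults to flat
  because the broadband source spectrum is unpublished; a measured source
  can be supplied as a two-column CSV.

### Dip alignment: why `lambda0 = 593` nm

The published description aligns the A-filter cut-on and the AB-filter
centre "with the resonance dip", but those two wavelengths differ (583 vs
580 nm) and the numeric dip wavelength in buffer is not printed, so the
alignment is genuinely open. It matters, because the sign of
$d\gamma/dn$ depends on where the dip sits relative to the A band:

* with the dip at the A cut-on (583 nm) or the A-band centre (590.5 nm),
  a red shift moves dip deficit *into* band 1, so $\gamma$ initially
  *falls* with *n* — the opposite of the reported positive
  $\gamma$-sensitivity;
* with the dip in the red half of the A passband, a red shift pushes the
  deficit out past the common 598 nm cut-off, $I_A$ recovers faster than
  $I_B$, and $\gamma$ rises strictly with *n* across the full working
  range 1.333–1.3495.

The package therefore defaults to $\lambda_0 = 593$ nm (with
$\sigma = 8$ nm, depth 0.5, baseline 0.9). This is the one configuration
choice made for internal consistency with the reported behaviour: it gives
a strictly monotone $\gamma(n)$, a negative $\gamma$ change under a blue
shift, and a forward $\gamma$ sensitivity of the same order as the
measured 2.25 a.u./RIU. All four dip parameters are user-configurable.

## Synthetic image generation

`dbsi_simulator` renders checkerboard frames from the forward model. The
defaults encode the reference acquisition conditions: a five-state
staircase of refractive indices from 1.333 to 1.3495 (the sugar-solution
series), ten-minute states, one frame every 20 s (thirty γ values per
state) and one spectrometer acquisition every 60 s (ten spectra per
state) in the companion dip-readout channel.

Choices where the source is silent, fixed once and kept:

* **Mosaic scale.** The real camera pixel (2.4 µm) gives a non-integer
  ≈ 4.17 px per 10 µm filter unit; the simulator uses an integer
  `tile_px = 4` so that pixel-shift demosaicing is exact. Resampling of
  non-integer pitches is deliberately rejected rather than approximated.
  The default field is 16 × 16 tiles (64 × 64 px) — small enough for fast
  tests, large enough for full-field averaging to beat dip tracking.
* **Detector.** 12-bit depth; gain auto-scaled so wide-band tiles sit
  near 2000 counts; Gaussian read noise (σ = 2 counts) plus Poisson shot
  noise. Shot noise at 2000 counts (≈ 45 counts RMS) dominates, a
  realistic regime for a machine-vision camera.
* **Grid artifact.** Diffraction and sidewall effects at filter-unit
  boundaries are emulated as a 1-px boundary band set to the arithmetic
  mean of the adjacent class values. This reproduces the two observed
  consequences — a periodic grid pattern at the tile frequency, and
  boundary pixels whose γ does not respond to the analyte — without
  modelling the underlying optics.
* **Spectrometer channel.** 0.5 nm sampling and 0.1 % additive intensity
  noise. With raw in-band minimum tracking this yields a per-state dip
  scatter of roughly 0.15–0.45 nm, matching the reported wavelength
  stability range.
* **Binding kinetics.** Pseudo-first-order Langmuir segments
  (`ri_langmuir()`, `ri_wash()`) stand in for antibody binding
  transients; no kinetic model is published, so `k_obs`,
  `delta_n_max` and the wash residual are user parameters.

Every frame's noise is drawn under a seed derived from the run seed and
the frame index, so identical configurations reproduce byte-identical
stacks, and each stack carries a ground-truth table (time, *n*, true
$I_A$, $I_{AB}$, γ) for parameter-recovery tests.

## Demosaicing

Shifting a checkerboard frame by one tile pitch along either image axis
always lands on the opposite filter class. `demosaic_frame()` therefore
keeps each pixel's own value for its tile's band and fills the other band
from the shifted neighbours. The published description says "shifted
vertically and horizontally" without a combination rule; the default
averages all in-bounds neighbours at ±`tile_px` along both axes, which is
symmetric and halves the fill noise, and single-direction fills are
available behind a flag. One tile is cropped from each border by default
so that every output pixel has a full neighbour set; a full-size mode
(`border = "none"`) uses whichever neighbours exist. Mirror-reflection
padding is *not* offered: a reflected neighbour at one tile pitch lands
on the same class and would corrupt the fill.

On noiseless, artifact-free frames the reconstruction is exact by
construction (averages of identical values), which the tests assert with
zero tolerance.

## Gamma maps, smoothing and time series

`gamma_map()` applies the contrast equation elementwise and masks pixels
whose $I_{AB}$ falls at or below an intensity floor (default 1 % of full
scale) instead of producing unstable ratios. `smooth_gamma()` suppresses
the grid artifact with a mask-respecting Gaussian (default
σ = `tile_px`/2, matched to the artifact's spatial frequency); the kernel
is normalised by valid-pixel weights and boundaries wrap, so the spatial
mean of a fully valid frame is preserved exactly and a period-4 artifact
is attenuated by $\exp(-2\pi^2\sigma^2 f^2) \approx 0.007$ at the tile
frequency. `roi_timeseries()` reduces each frame to a mean γ over an ROI
(default: full frame minus a one-tile border); `difference_map()` forms
smoothed before/after images of stabilized states.

For *calibration* the analysis driver tightens the ROI to tile-interior
pixels (`interior_pixel_mask()`), excluding the artifact band. Boundary
pixels carry a constant mixture of the two class values, so their γ does
not respond to the analyte and only dilutes the fitted slope — the same
dilution the published analysis attributes to grid artifacts when
comparing the measured 2.25 a.u./RIU with the roughly three-fold higher
theoretical sensitivity. Masking them lets the recovered slope be compared
against the forward model; keeping them (set
`analysis$exclude_artifact = FALSE`) reproduces the diluted regime.

## Calibration and detection limits

`fit_sensitivity()` is unweighted OLS, matching the published "linear
fitting" with no stated weights. `baseline_noise()` is the sample
standard deviation over a stated window. The limit of detection is

$$\mathrm{LOD} = \frac{\text{baseline noise}}{|\text{sensitivity}|},$$

the convention forced by the published numbers (0.46 nm / 244.7 nm/RIU =
1.88 × 10⁻³ RIU; 1.23 × 10⁻⁴ / 2.25 = 5.47 × 10⁻⁵ RIU) even though the
accompanying wording says "ratio of sensitivity to baseline noise". The
noise entering the LOD is the *maximum* of the per-state errors, the
choice consistent with those printed values; mean and pooled statistics
are available.

The spectral channel (`calibrate_dip()`) averages the spectra within each
state and fits a Gaussian to the mean spectrum for the state dip
wavelength — fitting over the full measured span, because windowing to
the AB passband truncates the red flank once the dip approaches the
cut-off and destabilises the centre estimate — while the state noise is
the scatter of the raw per-spectrum minima, which is what a stability
measurement sees. `theoretical_gamma_sensitivity()` implements the
model-based procedure: red-shift the fitted Gaussian by
$S_\lambda \Delta n$, integrate through both filter curves, and take the
OLS slope of γ versus *n*. The published 6.89 a.u./RIU depended on the
measured (unpublished) filter spectra and is not a reproduction target;
the tests instead verify the procedure against an independent chain-rule
oracle, $d\gamma/d\lambda \times S_\lambda$, to 2 %.

`concentration_lod()` extrapolates a concentration detection limit from
post-wash γ responses at the k-sigma level (k = 3 by default, since no
convention is published), with a log₁₀ response model by default and a
through-origin linear model behind a flag; values below the lowest
measured concentration are flagged as extrapolated.

## Numerical choices and degenerate inputs

* Trapezoid integration on the 0.1 nm grid; band integrals against the
  erf closed form agree to < 10⁻⁶ relative.
* `find_dip()` returns the raw in-band minimum by default (the published
  dip-tracking method); three-point quadratic refinement is opt-in.
  Minima on the search-band boundary are flagged, constant spectra are
  errors.
* `fit_gaussian_dip()` uses Levenberg–Marquardt with data-derived starts
  (argmin, half-depth width) and bounded parameters; flat or monotonic
  input raises an error rather than returning a spurious fit.
* Transfer-matrix stacks use non-dispersive SiO₂ = 1.46 and
  Ta₂O₅ = 2.10 (only the materials are published); lossless stacks
  conserve $T + R = 1$ to 10⁻⁹. The feature centre for overlayer scans is
  the transmittance-weighted centroid within a band, which presumes a
  transmission *peak* in the band — use `bandpass_stack()`-style
  structures, not a bare mirror whose in-band feature is a notch.
* Zero-valid-pixel ROI frames yield flagged `NA` gaps, not silent zeros.

## Problem sizes

The test suite and the acceptance script run the full staircase at
16 × 16 tiles × 4 px (64 × 64 px frames), 150 frames and 50 spectra, plus
smaller geometries for unit tests — sizes chosen so the whole suite
completes in well under a minute while leaving full-field averaging
enough pixels to demonstrate the γ-mode noise advantage.

## What passing tests do and do not show

The simulator emulates tile-quantised optics, stationary Gaussian/Poisson
detector noise, an idealised artifact band and instantaneous solution
exchange. It does not emulate non-integer pixel pitch, defocus or
point-spread mixing between tiles, illumination drift, mechanical drift
over hours, temperature dependence of *n*, or depletion-limited binding
kinetics. Parameter recovery within tolerance therefore validates the
*algorithms* — registration, contrast statistics, fitting, LOD
arithmetic — under the stated noise model; it does not certify
instrument-level performance, and the absolute γ-mode LOD scales with
field size and so is not comparable across hardware. Likewise the
γ-versus-dip LOD *ordering* is asserted, not the published two-orders
ratio, which depends on the (much larger) real sensor area.
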
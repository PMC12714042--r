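# dsfaspri

Simulation and analysis of snapshot surface plasmon resonance imaging
(SPRi) read out through a **dual-band spectral filter array**: a
checkerboard of 10 × 10 µm interference-filter units — a narrow band-pass
A (583–598 nm) interleaved with a wide band-pass AB (562–598 nm) — placed
in front of a monochrome camera. The package is for biosensing
methodologists who want a tested, reproducible implementation of the
whole computational chain: forward optics, synthetic image generation,
pixel-shift demosaicing, γ contrast analysis, and sensitivity /
limit-of-detection calibration.

## The statistic at the core

The SPR reflectance dip red-shifts with the refractive index *n* at the
sensor surface, λ_dip(n) = λ₀ + S_λ·(n − n₀) with S_λ = 244.7 nm/RIU.
Each camera pixel sees either the band-1 intensity I_A (through filter A)
or the combined intensity I_AB (through filter AB); with
I_B = I_AB − I_A, the per-pixel spectral contrast is

    γ = (I_A − I_B) / (I_A + I_B) = (2·I_A − I_AB) / I_AB

γ is scale-invariant and its change tracks the sign of the resonance
shift. Averaged over the full field it resolves far smaller index changes
than locating a dip minimum on a coarsely sampled spectrum; both readout
modes share the same detection-limit convention

    LOD = baseline noise / |sensitivity|.

Modules: `spectral_core` (filters, Gaussian dip, band integrals, γ, dip
finding/fitting), `tmm_stack` (transfer-matrix thin-film optics for the
SiO₂/Ta₂O₅ filter stacks), `dbsi_simulator` (checkerboard frame
generation with refractive-index protocols, grid artifacts and detector
noise), `demosaic`, `spri_pipeline` (γ maps, smoothing, ROI series,
difference images) and `calibration`.

## Worked example

Simulate the five-state refractive-index staircase (1.333 → 1.3495,
ten-minute states, thirty frames per state), demosaic every frame, and
calibrate both readout channels:

```r
library(dsfaspri)
res <- run_demo(seed = 1)
res$calib_dip
#> <calibration_result: spectral_shift>
#>   sensitivity  244.684 nm/RIU (R^2 = 1.0000)
#>   noise        0.337 nm
#>   LOD          0.00138 RIU
res$calib_gamma
#> <calibration_result: gamma>
#>   sensitivity  2.76357 a.u./RIU (R^2 = 0.9748)
#>   noise        0.00171 a.u.
#>   LOD          0.00062 RIU
```

Reading the numbers: the spectrometer channel recovers the generating
bulk sensitivity (244.7 nm/RIU) from Gaussian fits to state-averaged
spectra, with a wavelength stability of ≈ 0.34 nm from raw dip-minimum
tracking at 0.5 nm sampling — hence an index detection limit of
1.4 × 10⁻³ RIU. The γ channel fits the full-field contrast statistic
against *n*; its noise floor comes from photon statistics averaged over
the whole mosaic, so its LOD is smaller, and it keeps improving with
sensor area (the 64 × 64 px demo field is deliberately small). The
detection-limit arithmetic itself is exact:

```r
detection_limit(0.46, 244.7)    # 0.00188 RIU   (spectral-shift mode)
detection_limit(1.23e-4, 2.25)  # 5.47e-05 RIU  (gamma mode)
```

Lower-level pieces compose the same way the drivers do:

```r
grid <- wavelength_grid(555, 605, 0.1)
fA   <- make_passband(583, 598, peak = 0.85, edge_width = 4.5, grid = grid)
fAB  <- make_passband(562, 598, peak = 0.85, edge_width = 4.5, grid = grid)
dip  <- dip_model()                       # 593 nm, 244.7 nm/RIU
refl <- spr_spectrum(dip, 1.340, grid)
gamma_value(band_intensity(refl, fA), band_intensity(refl, fAB))
```

A thin command-line wrapper lives in `inst/cli/dsfa-spri.R`
(`simulate`, `analyze`, `demo`, `tmm` subcommands over YAML configs).

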
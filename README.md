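# ventlight

Photon budgets for mineral-mediated visible light at deep-sea
hydrothermal vents.

Deep-sea vents host cyanobacteria — oxygenic phototrophs — far below the
photic zone, and in situ cameras record more blue-green light around
vents than blackbody radiation at vent temperature allows.  `ventlight`
implements, end to end, the quantitative argument that sulfide minerals
resolve this paradox by **second harmonic generation (SHG)**:
non-centrosymmetric sulfides such as chalcopyrite (CuFeS₂) convert two
geothermal infrared photons into one visible photon at half the
wavelength, with intensity ∝ P², efficiency strongly enhanced under
hydrostatic pressure, and output wavelengths that overlap cyanobacterial
pigment absorption.

The core of the package is the multiplicative photon budget

```
Φ_vis = Φ_IR × η × E × Π f_i
```

where Φ_IR is the band-integrated Planck photon radiance of a 400 °C
vent over 800–1100 nm (photons·cm⁻²·s⁻¹·sr⁻¹), η the SHG conversion
efficiency (≤10⁻⁷ at pressure), E the pressure enhancement (66×), and
f_i optional extra multipliers (e.g. microcavity resonance).  Around it
sit five modules:

| module | what it does |
|---|---|
| radiometry | Planck spectral photon radiance, band fluxes, eV and µmol-photon conversions |
| SHG model | λ/2 mapping, log–log quadratic power-law fits, loss-corrected efficiency, pressure enhancement, photon budgets |
| spectra | peak detection, multi-Gaussian fluorescence decomposition, substrate controls, emission–pigment overlap |
| metagenome | photosynthesis-apparatus gene completeness from BLAST/DIAMOND `outfmt 6` tables, FaRLiP probes, Shannon diversity |
| synthetic data | seeded generators for every input above, so the whole pipeline runs without downloads |

## Worked example

```r
library(ventlight)

# 1. SHG power law: synthetic series at 0.45-3.20 mW, 2% noise
fit_power_law(gen_power_series(noise_level = 0.02, seed = 1))
#> <power_law_fit> exponent 2.00935, prefactor 10^-0.00063581, R^2 0.999864 (n=8)

# 2. pressure enhancement recovered from a synthetic diamond-anvil series
pressure_enhancement(gen_pressure_series(seed = 1))
#> [1] 70.65  (66 embedded, 5% noise)

# 3. cyanobacterial fluorescence on chalcopyrite: three components
s <- gen_fluorescence_spectrum("cpy_7002", seed = 1)
decompose_gaussians(s, k = 3, window = c(600, 810), seed = 1)
#> <decomposition> 3 component(s), window 600-810 nm, baseline 0.02004, residual RMS 0.005939
#>   center  sigma   fwhm amplitude
#> 1 656.06 15.013 35.352   0.59939
#> 2 685.41 16.201 38.151   1.01916
#> 3 713.78 17.795 41.903   0.47866

# 4. the headline budget
run_photon_budget()
#> <photon_budget_report> 400 degC vent, 800-1100 nm IR band
#>   IR flux:      1e+12 photons cm^-2 s^-1 sr^-1
#>   visible flux: 6.6e+06 photons cm^-2 s^-1 sr^-1 (400-550 nm)
#>   excess over visible blackbody limit: 3.82 orders of magnitude
```

The exponent ≈2 is the SHG signature; the 656/685/713 nm components are
the phycobilisome → photosystem II → photosystem I fluorescence chain,
showing the up-converted 532 nm light is photosynthetically absorbed;
and the budget's 6.6×10⁶ photons·cm⁻²·s⁻¹·sr⁻¹ of 400–550 nm light
exceeds the visible blackbody ceiling (10³) by more than three orders of
magnitude.  `run_full_demo(seed = 1)` chains every stage — including the
metagenomic completeness scoring on simulated vent datasets — and writes
all artifacts to a directory.

A thin command-line wrapper lives at `inst/scripts/ventlight.R`
(subcommands `budget`, `demo`, `simulate`).

## Documentation

The methods vignette (`vignettes/ventlight-methods.Rmd`) describes the
models, the numerical choices (weighted decomposition objective,
quantile initialization, coverage-breadth threshold), the synthetic
generators' assumptions, and known limitations.
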
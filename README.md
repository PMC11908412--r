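# quenchcal

Calibration tools for using **tetramethylrhodamine (TMR) self-quenching as a
short-range (15–25 Å) distance probe**.

When two TMR dyes come within contact range they form a ground-state H-dimer:
the two transition dipoles couple (exciton splitting), the allowed absorption
band shifts blue from 550 nm to 520 nm, and emission from the lower exciton
level is forbidden — the dimer is dark. The fraction of quenched molecules is
therefore a steep function of inter-dye distance, which can be calibrated on
rigid polyproline-II (PPII) rulers, Cys–(Pro)ₙ–Cys with n = 0, 3, 5, 6, and
then used to read out conformational changes in biomolecules at distances
where FRET between identical-pair alternatives is blind.

The package implements the whole calibration pipeline in R:

* **Ruler geometry** — idealised PPII models from canonical dihedrals
  (φ, ψ, ω) = (−75°, +145°, 180°), dye **accessible volumes** (AV1
  single-sphere dye on a flexible tether, grid-based with obstacle-aware
  reachability), mean dye positions, and the distance-per-residue slope.
* **Spectra** — monomer/dimer basis spectra, non-negative spectral unmixing,
  exciton band-shift (cm⁻¹) and point-dipole coupling
  V = 5.04×10³ κμ²/(n²R³), monomer-likeness of excitation spectra.
* **Distance calibration** — Hill-form response
  F(d) = F_min + (F_max−F_min)·d/(d₅₀+d), midpoint d₅₀ ≈ 18 Å.
* **TCSPC** — IRF-reconvolution multi-exponential fitting (variable
  projection + Poisson maximum likelihood), global fits sharing lifetimes
  across constructs, model-order selection, amplitude → population /
  intensity-fraction conversion.
* **FCS** — 3D diffusion × triplet model, single and global fits,
  multiple-tau autocorrelation, particle numbers, extra-relaxation detection
  with timescale-bound inference (τ ≤ 100 ns or τ_D ≤ τ ≤ 300 ms), and the
  triplet-vs-laser-power diagnostic.
* **Synthetic data** — generators with embedded ground truth for decays,
  correlation curves, blinking traces, spectra and calibration tables.

## Worked example

```r
library(quenchcal)

## 1. build the ruler series and measure mean dye separations
rd <- ruler_distances(c(0, 3, 5, 6))           # ~15 s: eight AV computations
rd
#>   n_pro  distance
#> 1     0  9.715689
#> 2     3 17.814862
#> 3     5 21.447192
#> 4     6 26.194689
distance_per_residue_slope(rd)
#> [1] 2.606913        # A per residue, consistent with the ~3.1 A PPII rise

## 2. simulate the distance calibration and recover the midpoint
g <- generate_distance_series(list(F_min = 0, F_max = 1, d50 = 18, h = 1),
                              distances = rd$distance, noise = 0.05,
                              seed = 2024)
fit_hill_distance_response(g$table, fix = list(F_min = 0, F_max = 1))
#> Hill distance-response fit (h = 1)
#>   d50   = 17.00 A (se 0.98)
#>   F_min = 0, F_max = 1

## 3. lifetime analysis at the study's conditions
dec <- generate_decay(multi_exp_model(c(10000, 1000, 1), c(0.115, 2.2, 16.3)),
                      total_counts = 5e6, seed = 1)
fit <- fit_decay(dec$hist, dec$irf, n_components = 3)
fit$model$lifetimes_ns
#> [1]  0.114986  2.199989 16.587887
fractional_intensities(fit$model$amplitudes, fit$model$lifetimes_ns)
#> [1] 0.3415 0.6538 0.0047   # slowest phase carries ~0.5% of the light

## 4. FCS with timescale-bound logic
cur <- generate_fcs_curve(fcs_model(G0 = 0.1, tauD_ms = 0.24, s = 5,
                                    T = 0.15, tauT_us = 7), seed = 1)
detect_extra_relaxation(cur$curve)
#> no extra relaxation (p = 0.69); process bounded to tau <= 1e-07 s or
#> 0.000239 s <= tau <= 0.3 s
```

The numbers above are what the code prints at those seeds: the fitted
midpoint lands within ~1 Å of the 18 Å ground truth, the three lifetimes are
recovered to well within 10%, and a pure diffusion+triplet curve yields the
"fast or slow window" verdict — quenching dynamics are either ≤ 100 ns or
hidden between the diffusion time and 300 ms.

A command-line interface over the same functions is installed at
`inst/cli/quenchcal.R` (subcommands `simulate`, `build-ruler`, `av`,
`unmix`, `calibrate`, `fit-tcspc`, `fit-fcs`, `bounds`).

## Method details

See the methods vignette (`vignettes/quenchcal-methods.Rmd`) for the models,
their assumptions, parameter defaults and units, the synthetic-data design,
and known limitations.
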
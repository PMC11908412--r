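---
title: "Methods: calibrating TMR self-quenching as a short-range distance probe"
author: "quenchcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrating TMR self-quenching as a short-range distance probe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Two tetramethylrhodamine (TMR) dyes held within roughly 15--25 Å of one
another form a ground-state dimer. In the exciton picture the two transition
dipoles couple; for the cofacial (H-type) arrangement the allowed transition
is the upper exciton level, so absorption shifts blue (550 nm to 520 nm)
while emission from the lower level is forbidden: the dimer is dark, and the
pair self-quenches. Because dimerisation requires contact, the fraction of
quenched molecules is a steep function of how far apart the two labelling
sites hold the dyes. Calibrated on rigid rulers of known length, this turns
a pair of identical dyes into a short-range proximity probe, complementary
to FRET which loses sensitivity below ~30 Å for common pairs.

`quenchcal` implements the full calibration pipeline on polyproline-II
(PPII) rulers — Cys-(Pro)$_n$-Cys peptides with $n$ = 0, 3, 5, 6 — together
with a synthetic-data layer that generates every input with known ground
truth, so the estimators can be validated end to end without the original
measurements.

## Ruler geometry and dye accessible volumes

`build_polyproline()` constructs idealised models from internal coordinates
(natural-extension frame) with canonical PPII dihedrals
$(\phi, \psi, \omega) = (-75^\circ, +145^\circ, 180^\circ)$, ideal bond
lengths and angles, full proline rings, a C-terminal carboxylate, and
cysteine side chains at the most populated gauche$^-$ rotamer. This geometry
reproduces the expected PPII rise of ~3.1 Å per residue (checked in the
tests by projecting the C$\alpha$ trace on the SVD helix axis).

The dye is modelled as a single sphere on a flexible tether (the AV1
accessible-volume model): a grid point is an allowed dye position when

1. the dye sphere (radius 3.5 Å) does not overlap any structure atom's van
   der Waals sphere, and
2. the point is reachable from the attachment S$\gamma$ by a clash-free path
   no longer than the linker (15 Å), where the *path* needs only the linker
   half-width (2.25 Å) of clearance.

Reachability is computed in two stages. Points whose straight segment to the
anchor clears every obstacle get their exact Euclidean distance; occluded
points are resolved by label-correcting relaxation on the 26-connected grid
seeded from the visible set. A pure 6-connected flood fill measures the
Manhattan metric, whose "ball" is an octahedron with volume
$\tfrac{4}{3}L^3$ rather than $\tfrac{4}{3}\pi L^3$ — a 58% error in free
space — so the line-of-sight/26-connected scheme is used instead; it makes
the free-space AV an exact ball up to grid discretisation (the tests check
the analytic sphere volume to 5%). Cells within one linker width of the
anchor are always traversable: the proximal linker segment necessarily hugs
the atoms its anchor is bonded to, and without this exemption every
attachment site would be classified as buried. A genuinely buried site
yields an explicit empty-AV state rather than an error-free zero.

The inter-dye distance is `mean_position_distance()`, the Euclidean distance
between AV centroids ($R_{mp}$). For the default dye parameters the four
rulers give ~9.7, 17.8, 21.4 and 26.2 Å, an ordinary-least-squares slope of
~2.6 Å per residue against $n$ — consistent with the ~3 Å/residue helical
rise once the lateral offsets of the terminal attachment sites are taken
into account (at short lengths the end-to-end distance grows more slowly
than the rise because the termini sit off the helix axis). The published dye
parameters of the original FPS analysis are not available; the defaults
(linker 15 Å, width 4.5 Å, dye radius 3.5 Å, grid 0.9 Å) are typical for a
rhodamine on a thiol-reactive linker and are fully configurable.

`all_trans_probability()` treats prolyl *cis* isomerisation per bond as
independent, $(1-p_{cis})^{n}$; whether terminal prolines count toward $n$
is deliberately left to the caller because the literature convention varies.

## Spectra: exciton mixing and unmixing

The default basis spectra are two-Gaussian models per species: monomer 550 nm
(major) + 520 nm shoulder at 0.55 relative amplitude, FWHM 18 nm; dimer
520 nm (major) + 550 nm at 0.45, FWHM 20 nm. Widths are *full widths at half
maximum*: with standard deviations of that size the two bands merge into a
single maximum near 544 nm and the characteristic "reversal of the two
peaks" disappears. The real band parameters are not published; everything is
configurable.

`unmix_absorption()` solves a two-component non-negative least-squares
problem (exact active-set enumeration — with two columns the active sets can
be enumerated) and normalises the coefficients to fractions. Non-negativity
matters: the coefficients are species populations. `monomer_similarity()`
scores excitation spectra against the monomer basis by cosine similarity —
the experimental signature of the dark dimer is that *excitation* spectra
remain monomer-like even when *absorption* shows the dimer band.
`exciton_splitting()` evaluates the point-dipole coupling
$V = 5.04\times10^{3}\,\kappa\mu^2 / (n^2 R^3)$ cm$^{-1}$ (μ in Debye, R in
Å), classifying $\kappa > 0$ as H-type (blue-shifted allowed band).

## The distance calibration

Emission at 575 nm against $R_{mp}$ follows the saturation (Hill, $h = 1$)
form
$$F(d) = F_{min} + (F_{max}-F_{min})\frac{d^h}{d_{50}^h + d^h},$$
with midpoint $d_{50} \approx 18$ Å. `fit_hill_distance_response()` floats
all three parameters by default. With only the four ruler points, however,
the three-parameter fit is not identifiable under realistic noise: the four
$F$ values span a nearly linear stretch of the curve, and $F_{max}$ trades
off against $d_{50}$ almost freely (simulations give median midpoint errors
of several Å at 5% noise). The recovery tests therefore use the normalised
readout convention — emission scaled so the fully quenched baseline is 0 and
the unquenched monomer signal is 1, i.e. `fix = list(F_min = 0, F_max = 1)` —
under which the midpoint is recovered to ~1.3 Å median error at 5% noise.
This mirrors practice: the quenched floor and the free-dye plateau are
measured separately with far better precision than four construct points can
provide.

## TCSPC: reconvolution with globally shared lifetimes

The expected decay is the discrete convolution of
$\sum_i a_i e^{-t/\tau_i}$ (sampled at channel centres) with the unit-area
IRF, plus a constant background; sub-channel IRF shifts are applied as a
Fourier phase ramp on the zero-padded FFT grid. Fitting uses variable
projection: the nonlinear search runs only over $\log\tau_i$ and the shift,
while amplitudes and background — in which the model is linear — are solved
by non-negative least squares at every step. Multi-starts are deterministic
(log-spaced lifetime sets at fixed scale factors), so fits are exactly
reproducible.

The estimator default is Poisson maximum likelihood: the Neyman chi-square
(weights $1/\max(y,1)$) solution is used as the starting point and then
refined by minimising the Poisson deviance. The Neyman weighting is kept as
an option and for model-order selection (where the nested F-test on
chi-square applies), but it is not the default because on the study's own
conditions — a 16.3 ns component carrying <0.5% of the intensity, living in
tail channels with single-digit counts — it underestimates that lifetime by
~17%, an instance of the well-known low-count bias of $1/y$ weights.
Noiseless data are recovered exactly by both estimators.

`global_fit()` shares the lifetime vector across histograms while
amplitudes, shifts and backgrounds stay free per curve, which is how a
construct series with common species but different populations is analysed.
`select_component_count()` picks the smallest order whose successor brings
no significant F-test improvement (α = 0.01) *and* whose weighted residuals
have lag-1 autocorrelation below 0.1. Two caveats are worth knowing. The
unit weight floor deflates the Neyman chi-square in empty tail channels
(reduced chi-square < 1), which would make the F denominator too small, so
the denominator scale is floored at 1 — the improvement an extra component
can deliver lives in well-populated channels whose weighted residuals have
unit variance. And tests for the number of exponential components have
nonstandard null distributions (the extra component's lifetime is
unidentified under the null), so the F-test is mildly anticonservative: on
50 simulated replicates of the preset three-component decay the selection
returns 3 in 45 and overfits to 4 in 5, rather than the nominal ~1%. `fractional_populations()` uses
$p_i \propto a_i$ (equal radiative rates): this convention reproduces both
the ~10000:1000:1 population ratio and the <0.5% slow-phase intensity share
self-consistently.

Preset acquisition settings (the real ones are unpublished): 4096 channels ×
25 ps (102.4 ns window, >6× the longest lifetime), Gaussian IRF of 120 ps
FWHM, 5×10⁶ total counts.

## FCS: diffusion + triplet, and what non-detection means

The model is the single-species 3D Gaussian-volume form
$$G(\tau) = G_0\left(1+\frac{\tau}{\tau_D}\right)^{-1}
\left(1+\frac{\tau}{s^2\tau_D}\right)^{-1/2}
\left(1+\frac{T}{1-T}e^{-\tau/\tau_T}\right),$$
with the structure parameter fixed at $s = 5$ by default (not published;
poorly determined by a single curve). Fits run in transformed parameters
(log for positive quantities, logit for $T$). The particle-number
convention is $N = (1-T)/G_0$ (with the uncorrected $1/G_0$ also reported).

`detect_extra_relaxation()` augments a fitted model with one factor
$(1 + A e^{-\tau/\tau_R})$ and decides by F-test at α = 0.01. Two numerical
choices matter. First, the augmented triplet lifetime is constrained to the
canonical microsecond dark-state window (0.5–20 µs): with both exponentials
free the triplet and the extra relaxation can swap roles, and a free
"triplet" absorbs, say, a 50 µs process. Second, the extra term is
multi-started over six log-spaced initial timescales because the augmented
objective is multimodal. When nothing is detected, the physically honest
statement is a *disjunction*: the dimerisation process is either faster than
the shortest reliable lags (τ ≤ 100 ns) or hidden above the diffusion time,
bounded by the slowest literature self-quenching timescale
($\tau_D$ ≤ τ ≤ 300 ms). These two constants are stored as named arguments
with their provenance documented.

`multiple_tau_autocorrelate()` is the standard multiple-tau scheme: 2*m*
lags at native resolution, then *m* per octave with bin-doubling, symmetric
normalisation at every lag. It is validated against an exact $O(N^2)$
brute-force correlator: identical at native-resolution lags, within a
binning tolerance (~10–15% of $G_0$) at rebinned octaves.

## Synthetic data: what it does and does not emulate

Noise models follow the estimators' statistical structure at the lowest
adequate fidelity: independent Poisson counts per TCSPC channel (physical),
multiplicative Gaussian noise on FCS curves with a scale rising
log-linearly from 0.5× at the shortest lag to 2× at the longest (a pragmatic
stand-in for correlator statistics — real FCS noise is correlated across
lags), and additive Gaussian noise on spectra. The blinking-trace generator
sums independent two-state telegraph emitters with Poisson shot noise; its
analytic relaxation rate $k_{on}+k_{off}$ and stationary brightness validate
the correlator end to end. Every generator embeds its ground truth and seed
in the returned object, and per-purpose seed streams are derived from one
master seed so adding a generator never shifts another's stream.

The preset scenario ties the constructs together: one dark-dimer fraction
per construct (0.95/0.55/0.15/0.05 for 0P/3P/5P/6P) drives both the
spectral mixtures and the apparent FCS particle number, decreasing toward
shorter rulers as dimers go dark.

What passing the recovery tests shows is that the estimators are correct and
well-conditioned under these noise models at the study's problem sizes; it
does not show robustness to the artefacts real instruments add (afterpulsing,
dead time, IRF drift, correlated correlator noise, scattering backgrounds),
none of which are modelled.

## Problem sizes and numerical choices

The validation suite uses the preset sizes throughout: 50 Poisson replicates
at 5×10⁶ counts for lifetime recovery and model-order selection, 100 noisy
curves (2% noise) for FCS recovery and relaxation detection, 200 replicates
for the calibration midpoint, 10⁴-bin traces for the correlator oracle.
Tie-breaks and degeneracies: lifetimes are reported ascending with ties
broken by amplitude; empty accessible volumes are a distinct state; constant
emission tables, all-zero spectra and zero-mean traces are rejected with
specific errors; a fitted triplet fraction at its bound is flagged rather
than silently returned.

## Known limitations

* Rigid, idealised ruler models: no *cis*-proline conformers, rotamer
  ensembles or chain flexing; the AV1 single-sphere dye, not the
  three-radius AV3 variant.
* The absorption basis is synthetic; unmixed fractions are only as good as
  the basis supplied.
* Point-dipole exciton coupling only; no vibronic structure and no dimer
  geometry beyond κ.
* FCS assumes one diffusing species and uncorrelated per-point noise.
* The amplitude-to-population conversion assumes equal radiative rates
  across decay environments.
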
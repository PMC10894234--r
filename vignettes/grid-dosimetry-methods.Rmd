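---
title: "Methods: Monte Carlo dosimetry of grid-collimated 6 MV fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo dosimetry of grid-collimated 6 MV fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the physics model, the estimators, the tunable
parameters and the known limitations of `gridrt`. It is the place where
every genuinely open design choice is recorded.

## The problem

Spatially fractionated radiotherapy (grid therapy) delivers a 6 MV beam
through a brass or cerrobend block with 127 focused holes (1.0 cm
diameter, 2.0 cm center-to-center pitch projected to the isocenter,
hexagonal lattice, maximum 25 × 25 cm² coverage). The quantities a
physicist needs for commissioning — PDD and d_max, output factors,
TPR20/10, lateral valley-to-peak ratios (the *spatial fraction*), axial
photon/electron spectra, and the primary/scatter decomposition of the
axial dose — all hinge on how the block reshapes the photon fluence.
`gridrt` simulates the whole chain with enough fidelity to reproduce the
established reference values for these quantities (see
`reference_values()`) at desk scale.

## Source model

The linac head is not modeled. Photons are emitted from:

* a Gaussian focal spot, FWHM 1.2 mm (the tuned spatial width of the
  electron beam the source emulates; its energy FWHM, 1.2 MeV, is carried
  as metadata);
* an optional broad "extra-focal" Gaussian (default FWHM 3 cm, 10% of the
  fluence) standing in for flattening-filter and collimator scatter. Head
  scatter of this order is a standard feature of clinical 6 MV beams and
  matters here: extra-focal photons are blocked by the grid at nearly the
  full septal fraction, which is what drives the observed ~13% reduction
  of *primary* fluence under the central hole — a pure point source would
  predict only the tray attenuation (~5%).

Directions are drawn toward a uniform target point in the collimated
field (plus a 2 mm penumbral margin) at the isocenter plane, which
enforces the collimation contract and the inverse-square law by
construction. Energies follow the two-parameter family

\[ \Phi(E) \propto E^{\alpha} e^{-\beta E}, \qquad 0.01 < E \le 6.02\ \mathrm{MeV}. \]

**Tuning.** `tune_beam()` implements the commissioning loop: simulate a
candidate, compare PDD (and optionally profile) against reference curves
with the 1D gamma index at 3%/3 mm, pick the candidate with the highest
pass rate (ties by RMS). The shipped defaults `alpha = 0.44`,
`beta = 0.75` were fixed once by requiring the open-field TPR20/10
(0.678 ± 0.009 reference window) and the axial average energy at 1.5 cm
depth (~1.47 MeV) to be reproduced simultaneously; the resulting d_max is
~15 mm. The mapping from the quoted electron-beam widths onto
\((\alpha, \beta)\) is a calibration choice, not a physical derivation.

## Cross sections and stopping powers

Per-element photon partial cross sections (photoelectric, incoherent,
coherent, pair) and electron collision stopping powers are shipped as
plain-text tables (`inst/extdata/`), regenerated by
`tools/make-physics-tables.R`. They are an *approximate analytic
compilation*, not a copy of a published library:

* incoherent scattering is the exact free-electron Klein–Nishina cross
  section (no binding/Doppler corrections — adequate above ~50 keV, and
  photons below the 10 keV cutoff are absorbed anyway);
* collision stopping powers use the Bethe formula with standard mean
  excitation energies and **no density-effect correction**. This keeps
  mass stopping powers exactly element-additive and ranges exactly
  density-scaling at the cost of ≲4% overestimated stopping at 6 MeV;
* photoelectric, pair and coherent cross sections are smooth
  parameterizations least-squares calibrated against embedded handbook
  attenuation anchors (water, copper, lead). Resulting total attenuation
  coefficients are accurate to a few percent over 0.05–6 MeV; absorption
  edges are not modeled, so high-Z materials below ~100 keV are the least
  accurate region.

Materials are weight-fraction mixtures (`material()`,
`gr_material()`), and every lookup applies the mixture rule exactly —
a blend of materials is the convex combination of its components at every
energy. Registry densities (water 1.000, PMMA 1.19, air 0.0012, brass
8.49, cerrobend 9.38 g/cm³) are handbook values and configurable.

## Photon transport

Analog transport with sampled free paths; Compton (Klein–Nishina
composition–rejection sampling with the kinematically exact electron
angle), photoelectric absorption, pair production (uniform energy split;
two 0.511 MeV annihilation photons emitted back-to-back at the positron
track end) and a forward-restricted Thomson-type Rayleigh deflection.
Cutoffs: photons 0.01 MeV, electrons 0.5 MeV; sub-cutoff particles deposit
locally. Russian roulette below weight 1e-4 with survival factor 10. Air
between source and phantom is treated as vacuum (<0.5% attenuation over
1 m). Every interaction in grid, tray or water flips the photon tag from
`primary` to `scattered`; tags partition the fluence exactly at every
scoring surface.

The grid block and tray are tracked with Woodcock (delta) tracking; the
focused-hole test projects the collision point through the source onto
the isocenter plane and checks membership in the 127-disk hexagonal
lattice, so hole cones follow the beam divergence exactly. The block and
tray are finite disks (default radius: projected maximum field + 2 cm);
side-escaping scatter is not artificially absorbed.
`transmit_through_grid()` exposes both the analog mode and a
deterministic `attenuate_only` mode whose hole-cone chord lengths are
solved in closed form (a quadratic in 1/z per hole).

## Electron transport

Secondary electrons use continuous slowing down (CSDA) in 1 mm sub-steps
with **Gaussian multiple-scattering deflection applied at a random hinge
inside each step** (Highland angle, PENELOPE-style random hinge). A pure
straight-ahead CSDA scheme was implemented first and rejected by
measurement: without angular diffusion the build-up keeps rising until the
range of the spectrum's high-energy tail is exhausted and the open-field
d_max lands near 29–30 mm, twice the reference value; with the random
hinge the build-up saturates realistically (d_max ≈ 15 mm). Remaining
electron-model simplifications: no energy straggling, no bremsstrahlung
(radiative yield is deposited along the track), no large-angle single
scattering. Electron fluence spectra are scored by track length in the
axial voxels (92 bins of 60 keV).

## Tallies and estimators

* **Cylindrical CAX mesh** (r = 4 mm, 2 mm bins, 0–30 cm): three parallel
  dose estimators —
  * `track` (default): forced-collision track-length estimator. Every
    photon flight chord through a wider sampling cylinder (r = 2.4 cm)
    spawns interaction points stratified at ≤1 cm spacing with weight
    \(w\,\ell\,\mu\); their CSDA electrons are transported and scored only
    inside the 4 mm column. The wide sampling cylinder is essential:
    sampling only chords inside the scoring column would miss electron
    in-scatter and biases the equilibrium dose low by ~25%.
  * `kerma`: track-length collision kerma (\(w\,\ell\,\mu_{tr}E/V\)) —
    lowest variance, but no build-up region;
  * `deposit`: fully analog electron deposits — unbiased but noisy at
    desk-scale histories; retained for cross-checks and attribution
    studies.
* **Rectangular profile mesh** (0.5 × 0.5 × 0.1 cm³ at 10 cm depth):
  kerma and deposit estimators.
* **Fluence spectra** (photon: 100 bins over 0.01–6.02 MeV; electron: 92
  bins over 0.5–6.02 MeV) by track length in 4 mm × 2 mm axial voxels at
  1.5, 5 and 10 cm.
* **In-air plane**: 50 × 50 × 0.1 cm³ slab just below the block position,
  scored with and without the grid from the same seed (correlated pair).

Uncertainties come from 10 statistical batches; every history owns its
own counter-seeded PCG32 stream keyed by a stable history id, so identical
configuration and seed give bit-identical tallies, results do not depend
on execution order, and paired runs that share a seed (open vs grid,
brass vs cerrobend, the in-air attenuation pair) are common-random-number
correlated — the surviving shared histories replay identically, which
substantially cancels the statistical error of paired differences and
ratios. Per-batch energy bookkeeping (in = deposited +
escaped ± roulette) closes to better than 1e-6 relative and is asserted in
the tests.

**Dose-tag attribution.** Two conventions are exposed because collision
tallies in general-purpose MC codes are ambiguous about the moment the
tag is read. `"parent"` attributes a deposit to the tag the photon
carried when it set the electron in motion (first-collision attribution;
under it, primary photons dominate the axial dose at d_max).
`"post_interaction"` reads the tag after the collision, so any photon
that has interacted contributes scattered-tagged dose and the scattered
component dominates at every depth — this matches the published
decomposition's qualitative picture and is the default in
`dose_components()`.

## Analysis conventions

* `pdd_and_dmax()` uses the classic 3-point parabolic fit around the
  maximum voxel, widening to contiguous points within 98% of the maximum
  only when the peak is flatter than that. An earlier candidate (all
  points within 95% of the maximum) was rejected at high statistics: the
  6 MV depth dose is asymmetric around its peak, and a parabola fitted
  across the whole plateau drags the vertex ~1.5–2 mm deep. The d_max
  estimate is meaningful only once per-voxel noise is well below the
  plateau flatness, which is why the reference open-field run uses
  2 × 10⁷ histories.
* `spatial_fraction()` uses pitch-guided windows (±pitch/4 around the
  expected peak positions, valleys as minima between accepted peaks).
  Median pre-smoothing is **off** by default: on the standard 0.5 cm
  profile mesh the beamlet peaks are one to two voxels wide and a 3-point
  median clips them (measured inflation of the ratio from ~0.16 to
  ~0.36); pass `smooth = TRUE` only for profiles sampled much finer than
  the pitch. The pitch argument should be the isocenter pitch scaled by
  the divergence factor (2.2 cm at 10 cm depth for SSD 100).
* `gamma_index_1d()` searches ±3 DTA around each evaluated point at
  DTA/10 steps with local refinement to DTA/1000, global (percent of
  reference maximum) normalization, and a 10% low-dose threshold;
  evaluated points whose search window is truncated by the reference
  support are flagged `edge`. The threshold and interpolation step are
  documented choices, configurable per call.
* Per-MU normalization defines 1 MU as 1 cGy at d_max of the open
  10 × 10 cm² field at SSD 100 (`mu_calibration()`), after which doses are
  cGy/MU and fluences 1/cm²/MU.

## Problem sizes

The package targets desk-scale reproduction: 2 × 10⁶ histories per
phantom geometry, 5 × 10⁶ per TPR geometry, 10⁶ for in-air runs, and
1.2 × 10⁷ for the reference open 10 × 10 field — the flat build-up
plateau needs sub-percent per-voxel noise before a ±2 mm d_max estimate
is meaningful. This is still roughly 10³–10⁴ times fewer histories than a
production cluster study. At these sizes the axial track-estimator dose
carries ~0.5–2% batch standard errors, TPR20/10 ~0.006, and spectral
average energies <1%. The acceptance script and the test suite use
exactly these sizes; the unit tests run reduced versions (2 × 10⁴ –
4 × 10⁵) of the same pipelines.

## Assumed geometry and known limitations

The block thickness and mounting distance are not part of the published
grid description. The defaults — a 7.6 cm thick block with its bottom
face 65 cm from the source under a 0.6 cm PMMA tray — are stated
assumptions, configurable in `grid_spec()`. Two reference quantities are
sensitive to them and are the package's known misses under the default
geometry: the simulated in-air fluence reduction is ~59% against the
reference "nearly 50%", and the simulated spatial fractions are ~0.16/0.19
(10×10 / 20×20 brass) against 0.23/0.26. Both discrepancies move together
with a single parameter — the block's effective transmission
(\(e^{-\mu t}\) ≈ 0.05 of the open fluence at 7.6 cm) — and both would be
reconciled by an effectively thinner (~6.5 cm) or more transmissive
block. The default is deliberately left at the stated assumption rather
than calibrated against those observables; users with vendor drawings
should set `block_thickness_cm` accordingly.

Other limitations to keep in mind when extrapolating to real beams: no
electron contamination in the source (surface doses below ~5 mm read
low, and that region is excluded from gamma scoring in `tune_beam()`),
no absorption edges or fluorescence in high-Z materials, free-electron
Compton, Gaussian-only multiple scattering, and valley doses that rely on
photon scatter plus ~mm-scale electron blur — effects finer than the
0.5 cm profile mesh are not resolved. Passing tests demonstrate internal
consistency and agreement with the reference values at the stated
windows; they do not validate the code against measured clinical beam
data.
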
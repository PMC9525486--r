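---
title: "Voxel-scale dosimetry of CAF-targeted radiopharmaceutical therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-scale dosimetry of CAF-targeted radiopharmaceutical therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdosim)
```

## The problem

Fibroblast activation protein (FAP) is overexpressed on cancer-associated
fibroblasts (CAFs) in many carcinomas, making the stroma a target for
radiopharmaceutical therapy (RPT). Whether a short-range alpha emitter
(Ac-225, chain alpha ranges 40-90 um in tissue) or a longer-range beta
emitter (Lu-177, maximal beta range ~1.8 mm) kills more of the tumor depends
on where the dose lands at the scale of single cells: alphas deposit
essentially all of their energy inside or immediately next to the labelled
cell, while betas spread dose over hundreds of micrometres of neighboring
tissue ("crossfire"). `voxdosim` quantifies this trade-off on voxelized
spherical tumor models in which tumor cells and CAFs are interspersed at
controlled degrees of clustering.

## The spherical-mass model

A 3 mm diameter sphere is sampled at 20 um isotropic voxels (one voxel ~ one
cell). The voxel-inclusion convention is locked: voxel centers on a grid whose
central voxel coincides with the sphere center, with a non-strict comparison
`r^2 <= R^2`. Of the four candidate conventions (center- vs corner-anchored
grid, strict vs non-strict), only this one yields 1,767,063 inside voxels
(the continuum value is 1,767,146); the others give 1,766,313 or 1,768,496.
`build_spherical_mask()` implements it and the alternatives.

Inside voxels are partitioned into 75% tumor and 25% CAF by ranking a
morphology-specific scalar field and thresholding at the exact 75th
percentile, so the global fraction is honoured to a single voxel at every
clustering scale. Four generator families cover the clustering range:

* **interspersed-cubes** — a periodic lattice of tumor cubes separated by CAF
  septa; the period is the scale parameter. Fine interspersion.
* **blob-field** — a Gaussian-smoothed random field thresholded at the
  fraction quantile; the correlation length is the scale. Irregular mid-scale
  clusters.
* **few-large-blobs** — k seeded regions grown to the tumor fraction; k is
  derived from the intended blob diameter. Coarse, discrete clusters. Because
  k is an integer, the achievable cluster sizes jump discretely; this family
  is therefore not used for calibrated reference models.
* **shell** — an *eccentric shell*: the tumor is a ball whose center is
  displaced from the sphere center by a continuous offset along a fixed
  grid-diagonal axis, and the CAF compartment is the complement. At zero
  offset this is a concentric peripheral CAF shell; as the offset grows the
  CAF collects into a crescent on the far side and the mean tumor-to-CAF
  distance rises smoothly toward the sphere-diameter scale. The offset axis is
  deterministic because orientation is irrelevant to isotropic-emission
  dosimetry, and a fixed axis keeps the calibrated geometry stable across
  label seeds.

### Nearest-CAF distances and L_mean

For every tumor voxel, rays are cast along the cartesian directions (6 in 3D,
4 for 2D sections) and L is the **minimum** over directions of the number of
steps to the first CAF voxel, times the spacing. A tumor voxel face-adjacent
to a CAF is one step (20 um) away — never zero, since a tumor cell is never
at distance 0 from a CAF. A ray that reaches an outside voxel or the array
edge without meeting a CAF contributes no candidate; voxels with no candidate
in any direction are flagged *undefined* and excluded from the mean
(zero-filling them would bias L_mean downward). L_mean is the arithmetic mean
over defined distances.

Two consequences of this definition are worth stating explicitly:

1. With 25% CAF arranged as septa around tumor clusters, L_mean and septum
   thickness are tightly coupled: a cube lattice with L_mean = 92 um forces
   septa ~3 voxels (60-70 um) thick, because the volume fraction pins the
   septum-to-cluster ratio. Dose ratios for emissions whose range is
   comparable to the septum thickness are therefore *very* sensitive to the
   distance convention used to report clustering.
2. The alternative convention in which the per-voxel statistic is the *mean*
   over the defined directional distances (`compute_nearest_caf_distances(...,
   combine = "mean")`) is nearly independent of septum thickness (for an
   interior cube of side s it is exactly (s+1)/2 steps per axis) and can
   report values 2-4x larger on identical label maps. When comparing against
   clustering lengths reported by other image-analysis pipelines, the
   convention must be checked first; this is the dominant reconstruction
   uncertainty for models built to match a published L_mean, and it is why
   self-absorption-sensitive endpoints on reconstructed geometries should be
   read with generous tolerances.

The five reference models span L_mean 92-1030 um
(`reference_models()`): levels 1-2 use interspersed-cubes (92, 180 um),
level 3 blob-field (350 um), levels 4-5 the eccentric shell (650, 1030 um).
Intermediate targets are an approximately geometric ladder between the
anchored end points. `calibrate_scale_to_lmean()` bisects the scale parameter
(geometric midpoints, since scales span decades) until the generated model's
L_mean is within a relative tolerance (default 2%) of the target; L_mean is
monotone in scale for every family, up to sub-voxel discretization jitter.
The coarsest model concentrates CAF toward one side of the sphere — the only
way 25% CAF can be, on average, a millimetre away from the tumor bulk inside
a 1.5 mm-radius sphere — so 2-5% of its tumor voxels have all rays exiting
the sphere before meeting a CAF; they are excluded from L_mean as undefined.
Fine and mid-scale models have essentially none.

## Radiation physics

### Nuclear data

Decay schemes ship as plain-text tables with provenance headers
(`inst/extdata/decay_*.tsv`), compiled as grouped approximations of public
evaluations (ICRP-107-class). Lu-177: four beta-minus branches (endpoint
497.8 keV at 79.3% dominating) plus grouped conversion-electron and Auger
lines (~10 keV per decay). Ac-225: the alpha chain Ac-225 -> Fr-221 ->
At-217 -> Bi-213, with the Bi-213 branch resolved per decay by a Bernoulli
draw (2.2% alpha branch via Tl-209, 97.8% beta branch via the 8.376 MeV
Po-213 alpha), terminated at Pb-209 whose beta is included with the chain
electrons. Every decay emits exactly four alphas; branch-weighted alpha
yields sum to 4.0. Alpha recoil nuclei (E_alpha * 4 / A_daughter, ~0.45 MeV
per decay) are deposited in the decay voxel. Photons (gammas, X-rays) are
excluded throughout: their mean free paths far exceed the 3 mm model, so
their local dose contribution is negligible and all energy bookkeeping is on
*electron/alpha emitted energy*. Bremsstrahlung is likewise not scored
(about 1% of electron energy at these energies).

### Stopping powers and ranges

Electron collision stopping power for the liver-like medium (rho = 1.05
g/cm^3, water-equivalent composition) is generated from the standard
Berger-Seltzer formula (I = 75 eV, Z/A = 0.555; density effect neglected
below 2.5 MeV) and reproduces the common compilation values to better than
1% at 10-1000 keV. Alpha electronic stopping power is an anchor table
interpolated from standard range-energy tabulations for liquid water, with
velocity-proportional extrapolation below the ~0.8 MeV Bragg-peak maximum.
Both ship as documented text tables. Ranges follow from the CSDA integral
`R(E) = int dE'/S(E')` on a fine log grid, density-scaled by rho_ref/rho;
the inverse curve E(R) is precomputed on a uniform range grid for O(1)
residual-energy lookup. The chain alpha ranges come out at 44-85 um at
1.05 g/cm^3, and the Lu-177 endpoint electron at ~1.68 mm.

### Straight-track CSDA Monte Carlo

Transport is deliberately simple: straight tracks with deterministic
continuous slowing-down, no angular scattering, no energy straggling, no
delta rays. For alphas this is an excellent approximation (tracks are nearly
straight and straggling is a few percent of range). For electrons it
overestimates penetration depth — real electrons scatter and their mean
projected range is roughly half the CSDA path length — which is
*conservative* for energy-containment claims and smooths cross-dose
estimates; this is the core fidelity trade-off versus a condensed-history
code, and it is stated rather than hidden. Each track deposits
`E(s_k) - E(s_{k+1})` into the voxel containing the segment midpoint, with a
2 um step (1/10 voxel); halving or doubling the step changes kernel totals
by well under 1%. Decay positions are uniform within the source voxel;
directions are isotropic. Energy conservation is exact by construction
(deposited + escaped = emitted through the same lookup table, to double
precision), and the grid is convex, so a ray that leaves never re-enters.
All sampling happens in R under the R RNG (a single `set.seed()` makes runs
bitwise reproducible); the segment loop is compiled C++.

### The Lu-177 dose voxel kernel

`generate_beta_kernel()` simulates decays uniformly distributed inside the
central voxel of a 201^3 cube (4 mm edge, spacing 20 um), samples the
mixture beta spectrum by inverse transform — *stratified* per batch
(permuted midpoint quantiles), a standard variance-reduction choice that
suppresses the spectrum-sampling component of the estimator variance at no
cost — adds the discrete
electron lines by Bernoulli thinning, transports straight tracks, and
converts the tally to Gy per decay by voxel mass. The cube half-width
(2 mm) exceeds the maximal straight-track electron range, so containment of
emitted electron energy is complete by construction (>99% is the documented
requirement). The run is split into >= 20 batches; the batch-means standard
error of the central-voxel dose, divided by its mean, is the reported
relative standard deviation (0.03% at 1e7 primaries). Because the
expectation kernel is isotropic, the kernel is optionally averaged over the
48 cube symmetries (default on), which suppresses Monte Carlo noise without
bias. The beta spectrum itself is the allowed shape
`p E_tot (E0 - E)^2 F(Z, E)` with the non-relativistic Fermi function
`F = 2 pi eta / (1 - exp(-2 pi eta))`, `eta = Z alpha / beta`; forbidden
shape factors are ignored (their kernel-level effect is small).

## Dose computation

Lu-177 uses the MIRD-style voxel S-value superposition
`D(v) = sum_s A(v_s) S(v - v_s)`: a uniform time-integrated activity map
(total decays divided equally over source voxels; 1e9 decays means ~755 per
tumor-source voxel or ~2264 per CAF-source voxel) convolved with the kernel
by zero-padded FFT. The padded size is the next highly composite size that
prevents wrap-around, so the spectral result equals the direct triple sum to
float round-off (asserted at 1e-6 in the test suite at every run); tiny
negative round-off values are clamped to zero. Convolution requires a
non-stochastic decays-per-voxel distribution, which is why it is reserved
for the high-budget beta emitter.

Ac-225 uses the Monte Carlo route directly on the label volume with 1e6
decays (~2.3 per CAF source voxel), preserving the per-cell stochasticity
that dominates alpha dosimetry at realistic activities. A kernel-MC
cross-check path for Lu-177 on small grids exists for testing
(`simulate_mc_dose()` with the Lu-177 scheme) but is not the reference
route.

Doses are reported only on the spherical-mass voxels; energy escaping the
sphere is intentionally ignored downstream (escape is accounted in the
transport bookkeeping but not redistributed).

## Analysis statistics

* **Cumulative DVH** (`cumulative_dvh()`): the fraction of target voxels
  receiving at least each dose level, on 512 uniform bins from 0 to the
  target maximum; starts at 100% and is monotone non-increasing.
* **Efficacy ratio** (`efficacy_ratio()`): mean dose over the target voxels
  divided by mean dose over the whole mass, for a given source. ER = 1 means
  the target received exactly the mass-average dose. Because tumor and CAF
  partition the mass and voxels have equal mass, the volume-weighted
  identity `f_CAF ER_CAF + f_tumor ER_tumor = 1` holds exactly per source —
  a useful end-to-end invariant, asserted in the tests. In the zero-range
  limit with CAF sources, ER(CAF) = 1/0.25 = 4 and ER(tumor) = 0; with a
  kernel whose range far exceeds the sphere all ERs tend to 1.
* **Threshold fraction** (`fraction_above_relative_threshold()`): the
  percentage of target voxels at or above 10% of the *whole-mass* maximum
  dose. The maximum of a low-count alpha map is a single-voxel statistic, so
  an optional winsorized maximum (99.99th percentile, default off) is
  provided for reproduction runs.
* **Negligible-dose fraction**: reported as the fraction of target voxels
  below 1% of the mass-mean dose — an explicit, documented proxy for the
  "cold" shoulder of a cross-irradiation DVH (extrapolating a DVH shoulder
  intercept is not a well-defined operation, so the package does not attempt
  it).

`analyze_pairings()` emits the six standard reports per nuclide and model:
S(tumor <- tumor), S(CAF <- tumor), S(tumor <- CAF), S(CAF <- CAF), and the
whole-mass targets for both sources.

## Synthetic data and what the tests show

All fixtures are generated in code. Toy label maps (checkerboard, stripes,
shell, blob) carry hand-derivable L_means and exact fractions; analytic
kernels (delta, flat, Gaussian) drive the ER limit checks; synthetic
immunohistochemistry-style sections render blue tumor nests and red
FAP-positive CAF regions on a white background from a known label map, so
the 2D chain (block-mean downsampling to 20 um, redness segmentation
`r - max(g, b) > 0.15`, tissue-only ratios, 4-direction L) can be checked
against ground truth: exactly at native 20 um resolution, and within 2
percentage points of tumor ratio / 10% of L_mean for subsampled noisy
images. These synthetic sections emulate structure, not stain chemistry:
there is no chromogen co-localization, uneven illumination, or nuclear
texture, so passing them bounds segmentation-pipeline correctness, not
performance on real slides.

The always-on suite runs on scaled-down problems: a 600 um sphere for
geometry properties, a 1 mm five-level clustering ladder with 3e4 alpha
decays and a 61^3 kernel at 3e4 primaries for the trend properties
(self-irradiation ER rising with clustering, cross-irradiation falling,
alpha more sensitive than beta, mean mass dose insensitive for contained
emissions). The acceptance suite additionally builds the full 3 mm models,
the 201^3 kernel at 1e7 primaries, and full-budget dose maps; it completes
in a few minutes on one core. On the 1 mm test sphere the surface-to-volume
ratio is three times that of the full model, so surface-escape-sensitive
properties (CAF-source mean dose for coarse models) are asserted at full
size instead.

## Numerical choices and degenerate inputs

* Tie-breaks in the fraction-exact threshold use a seeded 1e-9 jitter, so
  label maps are reproducible and the fraction is exact to one voxel.
* `tumor_fraction` of 0 or 1 is rejected: with no CAF (or no tumor) the
  nearest-CAF distance is undefined everywhere.
* Cube-lattice periods below ~3 voxels alias against the grid and are
  excluded from the calibration bracket.
* Calibration refuses unreachable targets with the maximum reachable L_mean
  in the error message, and refuses targets below one voxel spacing.
* Stopping-power lookups refuse energies above the table domain (no
  extrapolation); below the lowest tabulated energy a linear slowdown is
  used (sub-micrometre residual ranges).
* Convolution refuses mismatched voxel spacings and even-sized kernels.
* 64-bit accumulation everywhere; tallies are doubles end to end.

## Known limitations

* Straight-track electron transport overestimates penetration; condensed-
  history codes with multiple scattering would pull the beta kernel inward
  by tens of micrometres at the spectrum mean. Endpoints dominated by
  self-absorption within ~100 um structures inherit this bias.
* Reported clustering lengths are convention-sensitive (min-ray versus
  directional-mean; see above). Models reconstructed to match a published
  L_mean under one convention can differ substantially in septum thickness,
  and hence in self-dose, from the structures that produced the published
  value. This is the main caveat when comparing efficacy ratios against
  published figures on geometries that are not deposited.
* No biology: uptake is uniform over source voxels, no clearance kinetics,
  no daughter redistribution, no bystander effects, no radiobiological
  weighting (the decay budgets are fixed totals, not activity-time curves).
* Vasculature, immune cells and acellular stroma are not modelled; the
  sphere is tumor and CAF only.
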
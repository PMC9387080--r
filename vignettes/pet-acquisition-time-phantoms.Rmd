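---
title: "Digital phantoms for PET acquisition-time and reconstruction-parameter optimisation"
author: "petiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phantoms for PET acquisition-time and reconstruction-parameter optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petiq)
```

## The question this package addresses

Modern silicon-photomultiplier PET/CT systems are sensitive enough that a
whole-body FDG scan acquired for 3 minutes per bed position contains far more
counts than are strictly needed for diagnostic image quality. How short can a
frame be before small lesions stop being detectable and quantitative readings
(the maximum and peak activity concentrations that clinicians interpret as
SUV~max~ and SUV~peak~) drift outside an acceptable band?

On a physical scanner this question is answered by acquiring a long list-mode
measurement of a lesion phantom and rebinning the event stream into shorter
frames. `petiq` reproduces that whole analysis chain on *digital* phantoms,
so the statistical machinery — visibility criteria, quantification-stability
bands, resolution estimation, paired agreement statistics — can be exercised,
tested, and taught without scanner data.

## Phantoms

Three torso phantoms are shipped as declarative YAML presets
(`phantom_preset()`), all based on an elliptical-cylinder body of
300 × 200 × 180 mm:

* **soft_tissue** — six hot spheres of 6.5, 9.7, 12.6, 15.1, 22.2 and
  28.0 mm diameter at 15 kBq/mL on a 57.2-mm ring in a 3 kBq/mL warm
  background (signal-to-background ratio 5:1). These conditions represent
  clinically realistic nodal lesions; the 9.7-mm sphere marks the typical
  threshold size for a conspicuous lymph node.
* **bone_lung** — three cold cylindrical tubes labelled with CT densities of
  −800 HU (lung surrogate) and 500/1000 HU (bone surrogates), each holding an
  8.5-mm and a 19.4-mm hot sphere at 15 kBq/mL. The densities carry labels
  and an optional per-region noise multiplier only; no attenuation or scatter
  physics is modelled.
* **resolution** — two 0.5-mm line sources at 10 mm and 100 mm transaxial
  offset, filled at 7.1 MBq/mL, in a non-radioactive body.

The torso dimensions and the in-plane background-ROI template are package
conventions (the physical phantom's exact fill geometry is not part of the
published description); both are configurable.

## The acquisition-noise model

The generator works post-reconstruction:

1. `voxelize_phantom()` renders the analytic geometry onto the reconstruction
   grid by supersampled sub-voxel classification (priority: spheres > lines >
   tubes > background), giving partial-volume-correct noise-free activity.
2. `apply_psf()` convolves with an isotropic Gaussian whose FWHM is the
   measured *system* resolution of the reconstruction being emulated
   (presets: 3.6 mm for OSEM-TOF, 2.9 mm for OSEM-TOF+PSF).
3. `generate_reference_frame()` draws independent voxelwise Poisson counts
   for the 600-s reference frame with mean
   `lambda = C · V_voxel · kappa · t`, where `kappa` (counts per kBq·s) is
   the single calibration constant of the model.
4. `thin_to_time()` produces every shorter frame (30–300 s in 30-s steps) by
   binomial thinning of the *same* reference counts with `p = t / t_ref`.
   Thinning a Poisson count is exactly Poisson with the reduced mean, and the
   frames are nested — precisely the correlation structure of list-mode
   truncation, and the reason the reference-frame activity-concentration
   ratio is exactly 1 by construction.
5. The post-reconstruction Gaussian filter (2 or 4 mm) is applied to the
   *noisy* frames. This ordering matters: a post filter smooths reconstructed
   noise, so a 4-mm filter yields lower background SD (higher CNR, tighter
   ACR spread) than a 2-mm filter, while the pre-noise system PSF sets the
   resolution floor. The effective resolution of the filtered image follows
   the quadrature rule used by `clinical_resolution()`.

What this model deliberately omits: tomographic reconstruction itself
(OSEM/TOF/PSF iterations, sinogram statistics, spatially correlated noise),
attenuation, scatter, randoms, and Gibbs artefacts. Iteration count is
carried as metadata with an optional noise multiplier
(`iteration_noise_scale`), not simulated mechanistically. Passing tests
therefore demonstrate the correctness of the *analysis* pipeline under a
well-specified count-statistics model, not fidelity to any particular
scanner's noise texture.

### Calibration of `kappa`

`kappa` fixes the absolute noise level. It was calibrated once (and frozen in
`inst/extdata/presets/acquisition.yaml`, `kappa = 0.32`) so that under the
default study conditions — soft-tissue phantom, 3.30 × 3.30 × 3.00-mm grid,
TOF system PSF, 4-mm filter — the 9.7-mm sphere's CNR at 60 s sits near the
Rose visibility threshold of 5. This anchors the simulation in the clinically
interesting regime: the smallest clinically relevant sphere becomes visible
at about one minute, larger spheres are visible at every frame length, and
the 6.5-mm sphere requires substantially longer frames. The calibration is a
property of the preset configuration, never hard-coded into formula tests.

## Image-quality metrics

For every sphere and frame, `measure_time_series()` records

* `c_avg`: mean in a sphere-matched VOI (voxel-center membership, like
  clinical tools — no partial-volume weighting on the measurement side),
* `c_max`: maximum within the sphere boundary,
* `c_peak`: mean in a 1-mL sphere (12.407 mm diameter) anchored at the
  geometric insert center. Anchoring at the center, rather than on the
  hottest voxel, follows the phantom-analysis convention; a max-centered
  mode is available for patient-style data.

Background noise uses the NEMA-style layout built by
`nema_background_layout()`: 60 two-dimensional 37-mm circular ROIs, 12 per
plane on the central sphere plane and two planes each side. The in-plane
positions are a shipped, constraint-checked template (≥ 15 mm clearance from
the body edge beyond the ROI radius; at least ROI radius + largest sphere
radius from every insert). The background SD is the voxelwise SD over the
union of all ROI voxels (the layout is treated as one background VOI); the
SD-of-ROI-means alternative is available via `method = "roi_means"`.

Detectability is `CNR = (C_avg − C_bgr) / SD_bgr` with the Rose criterion
`CNR ≥ 5`; quantification stability is `ACR = C / C_ref` against the 600-s
reference with a ±20% acceptance band. Both boundaries are inclusive, as the
defining inequalities state. `minimal_acceptable_time()` reports the
earliest grid time from which the criterion holds *through the end of the
grid* ("sustained" rule), guarding against non-monotone noise flapping; a
"first-pass" rule is available behind a flag.

Clinical-condition helpers: `compute_suv()` (1 g/mL density convention, no
decay correction — frames are coeval surrogates),
`normalize_concentration_to_reference_patient()` (SUV-preserving rescaling to
a 3 MBq/kg injection), and `cbm_speed_equivalent()` (per-bed time to
continuous-bed-motion speed, assuming a 263-mm axial field of view and 50%
bed overlap — the overlap is an explicit package assumption).

## Spatial resolution

`extract_profiles()` samples radial and tangential profiles through each
line source at three axial stations (center and ± one fourth of the axial
extent), giving 12 profiles. Profiles are sampled on the native voxel
centers along the profile axis (avoiding along-axis interpolation, which
would broaden the apparent width) with trilinear interpolation across the
other axes. `fit_gaussian_fwhm()` fits `baseline + A·exp(−(x−mu)²/2sigma²)`
by Levenberg–Marquardt with an analytic Jacobian (tolerances 1e-14; the
baseline term absorbs scattered background), and `system_resolution()`
averages all fits (population SD).

A numerical subtlety: a 0.5-mm line inside 0.83-mm voxels is quantized into
one or two voxel columns depending on its alignment with the grid. This adds
between 0 and `dx²/4` to the profile variance (plus `R²/4` for the line
disc), so recovered FWHM values legitimately sit up to ~4% above the
injected PSF. The parameter-recovery tests bound the estimate between the
nominal FWHM and the quadrature upper bound rather than pretending the
broadening does not exist.

`clinical_resolution()` combines the fitted system resolution with a filter
level as `sqrt(FWHM_sys² + FWHM_filter²)`; rounding to one decimal happens
only at presentation.

## Agreement statistics

`agreement_report()` bundles the paired-measurement battery used to compare
full- against reduced-acquisition-time quantification on a lesion table
(CSV: `lesion_id, value_full, value_reduced`):

* Pearson correlation with a Fisher-z confidence interval
  (via `stats::cor.test`);
* two-way mixed-model ICC. The single-measure *consistency* form ICC(3,1)
  with Shrout–Fleiss F-distribution bounds is the default — the standard
  test–retest choice when a constant offset between arms should not count as
  disagreement; the absolute-agreement form is available via
  `type = "agreement"`;
* Krippendorff's alpha from the coincidence-matrix definition, with the
  squared-difference (interval) metric by default — appropriate for SUVs on
  an absolute scale — and a normalised-ratio metric as an option;
* Bland–Altman analysis with differences defined as `reduced − full` (a
  negative bias means the short frame reads lower), t-based bias CI and
  1.96-SD limits of agreement;
* the maximum percentage deviation across lesions.

Because the underlying 20-patient dataset is not public,
`generate_synthetic_cohort()` stands in for it: lognormal full-time SUVs
(defaults `meanlog = 2.1`, `sdlog = 0.65`, i.e. median ≈ 8 and a central 95%
range of ≈ 2.3–30, spanning more than an order of magnitude as real lesion
cohorts do), a constant additive bias (default −0.5 SUV, the magnitude
reported for reduced-time imaging) and proportional Gaussian noise (default
CV 3%). The synthetic-cohort tests are parameter-recovery and CI-coverage
checks — they validate the statistics, not any patient-level value.

## Problem sizes and numerical choices

The shipped analyses and the test suite run on one CPU with the following
sizes, chosen so a full run completes in a few minutes: the soft-tissue
study simulates 11 frames of a 96 × 64 × 64 grid (3.30-mm preset); Monte
Carlo properties (CNR ∝ sqrt(t) scaling, thinning unbiasedness) use 50
seeds; resolution recovery uses the full 380 × 250 × 96 0.83-mm grid with
supersample 8; CI coverage uses 500 simulated cohorts of 30 lesions.
Voxelization uses supersample 4 by default (32 for oracle cross-checks).
Gaussian kernels are truncated at 4 sigma and renormalised; convolution uses
zero padding, so total activity is conserved away from the grid edge (the
presets keep the body several sigma inside the grid). Degenerate cases are
defined explicitly: a zero-variance background is an error for CNR; an
all-identical paired table yields Krippendorff alpha 1 with a `degenerate`
flag; `thin_to_time(t = 0)` is rejected because concentration is undefined
for an empty frame.

## Known limitations

* Voxelwise-independent Poisson noise underestimates the spatial correlation
  of iterative reconstruction; absolute CNR values are therefore
  calibration-dependent, while *trends* in time, filter and voxel size are
  model-robust.
* The bone-lung densities do not modulate the signal model (no attenuation
  or scatter); they exist so the analysis surface (per-density lesion
  tables) matches the physical study design.
* The horseshoe background VOI is a parameterized shell-with-wedge; the
  clinical drawing style it emulates is not standardised.
* ICC and alpha variants beyond the documented defaults (e.g. average-score
  ICCs) are out of scope.
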
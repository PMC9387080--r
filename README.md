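# petiq

Digital-phantom image-quality and quantification analysis for PET
acquisition-time optimisation.

## What it does and for whom

Silicon-photomultiplier PET/CT systems collect enough counts that whole-body
FDG acquisition times can be shortened substantially — but how short is too
short? Physicists answering that question acquire a long list-mode phantom
scan, rebin it into shorter frames, and track two things as the frame
shrinks: whether small lesions remain *visible* and whether their
quantitative readings remain *stable*. `petiq` implements that entire
analysis for fully synthetic digital phantoms, so the method can be run,
inspected and unit-tested end to end without scanner data. It is aimed at
PET physicists, protocol developers, and anyone teaching or validating
image-quality methodology.

The core quantities, per sphere insert and acquisition time `t`:

* **Detectability** — contrast-to-noise ratio against the Rose criterion:

  `CNR = (C_avg − C_bgr) / SD_bgr`, visible iff `CNR ≥ 5`,

  with `C_bgr`, `SD_bgr` taken over a NEMA-style background VOI
  (60 two-dimensional 37-mm circular ROIs: 12 per plane on the central
  sphere plane ± 2 adjacent planes).

* **Quantification stability** — maximum and peak activity-concentration
  ratios against a 600-s reference frame:

  `ACR_max = C_max / C_max,ref`, `ACR_peak = C_peak / C_peak,ref`,

  acceptable iff within ±20% of 1. `C_peak` is the mean of a 1-mL sphere
  (12.407 mm) at the insert center.

* **Spatial resolution** — Gaussian fits to radial/tangential line-source
  profiles give `FWHM_sys`; a post-reconstruction filter combines in
  quadrature: `FWHM_clin = sqrt(FWHM_sys² + FWHM_Gauss²)`.

* **Agreement battery** for paired full/reduced-time lesion tables: Pearson
  correlation (Fisher-z CI), two-way mixed ICC(3,1) with Shrout–Fleiss
  bounds, Krippendorff's alpha, Bland–Altman bias and limits of agreement,
  maximum percentage deviation.

The simulator emulates list-mode rebinning faithfully at the count level:
one Poisson reference realisation per run, shorter frames obtained by
binomial thinning of the *same* counts (`p = t/t_ref`), so frames are
nested and the reference ACR is exactly 1. The system PSF (3.6 mm OSEM-TOF
/ 2.9 mm OSEM-TOF+PSF surrogates) blurs the noise-free phantom before
Poisson sampling; the 2/4-mm Gaussian filter smooths the noisy frames.
See the vignette (`vignettes/pet-acquisition-time-phantoms.Rmd`) for the
model, its assumptions and its limits.

## Worked example

```r
library(petiq)

report <- run_iq_study(run_config(phantom = "soft_tissue", grid = "3.30",
                                  recon = "tof", seed = 1))
subset(report$table, sphere_label == "9.7mm" & !is_reference,
       select = c(t_s, c_avg, c_max, c_peak, cnr, acr_max, visible))
```

```
 t_s c_avg c_max c_peak   cnr acr_max visible
  30  8.77  14.1   7.32  4.13   1.279   FALSE
  60  8.31  12.3   6.78  5.49   1.113    TRUE
  90  8.88  12.1   7.18  7.15   1.097    TRUE
 ...
 300  8.51  10.8   6.82 12.55   0.983    TRUE
```

The 9.7-mm sphere — the typical threshold size for a conspicuous lymph
node — fails the Rose criterion at 30 s (CNR 4.13 < 5) and passes from 60 s
onward; its maximum-concentration ratio is noisy upward at very short frames
(ACR 1.28 at 30 s) and settles inside the ±20% band. The per-sphere minimal
acceptable times are in `report$minimal_times`; with this seed the spheres
≥ 12.6 mm are visible from 30–60 s and the 6.5-mm sphere only from 90 s.

```r
run_resolution_study("tof", seed = 1)
#> <resolution_result> FWHM_sys = 3.70 +/- 0.14 mm (12 fits)
#>   FWHM_clin: 2-mm filter -> 4.2 mm, 4-mm filter -> 5.5 mm
```

Twelve line-source profile fits recover the injected 3.6-mm system PSF
(slightly broadened by sub-voxel line quantization, as documented in the
vignette); the quadrature rule then gives the clinical resolution per
filter level.

```r
agreement_report(generate_synthetic_cohort(seed = 1))
#> <agreement_report> SUV_max, n = 30 lesions
#>   PCC   0.999 (0.998 to 1.000)
#>   ICC   0.999 (0.998 to 1.000) [consistency]
#>   alpha 0.995
#>   Bland-Altman bias -0.464 (-0.547 to -0.381), LoA (-0.900, -0.028)
#>   max % deviation 25.7%
```

A synthetic 30-lesion cohort (lognormal SUVs spanning more than an order of
magnitude, −0.5 additive bias, 3% proportional noise) recovers its
generating parameters: near-perfect correlation/agreement and a bias CI
covering −0.5. The same battery runs on a real paired table via
`read_paired_csv("lesions.csv")`.

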
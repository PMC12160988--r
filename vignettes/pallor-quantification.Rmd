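---
title: "Quantifying optic disc pallor: model, geometry and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optic disc pallor: model, geometry and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pallorkit)
```

## The measurement

Optic disc pallor — abnormal paleness of the neuro-retinal rim — is widely
read by clinicians from fundus photographs, but qualitatively. pallorkit
quantifies it as a dimensionless reflectance ratio. For a zone $Z$ of the rim
and a peripapillary control region $C$,

$$
\mathrm{pallor}(Z) \;=\;
\frac{\overline{G}_Z / \overline{R}_Z}{\overline{G}_C / \overline{R}_C},
$$

where $\overline{G}$ and $\overline{R}$ are mean green- and red-channel
reflectances over the (vessel-excluded) pixels of the region. Healthy rim
tissue is red-dominated because blood attenuates green light strongly; loss
of nerve fiber tissue exposes paler, more scattering tissue, raising the
green/red ratio. Under this convention **higher values mean a paler rim**.
The inverse orientation is available (`inverse = TRUE` in `zone_pallor()` /
`compute_pallor()`) because "ratio of red/green reflectance" is directionally
ambiguous in prose; we fixed the orientation so that observed population
values sit above 1 and paler discs score higher.

Two numerical choices matter here:

* **Ratio of means, not mean of per-pixel ratios.** The two agree to first
  order on smooth regions, but the ratio of means is robust to single dark
  or saturated pixels and makes results reproducible bit for bit.
* **Channels are taken from the stored RGB without color-space conversion**;
  8-bit inputs are promoted to float before averaging.

### Geometry

All geometry hangs off a parametric disc ellipse (center, semi-axes, tilt;
pixel units, x rightward, y downward) and the fovea landmark:

1. *(Left eyes only)* the image is mirrored horizontally, so that one
   angular convention serves both eyes. A proper rotation cannot map a left
   eye onto the right-eye layout — it would swap superior and inferior
   sectors — hence the reflection, recorded in provenance.
2. The image is rotated about the disc center so the fovea lies on the
   horizontal ray toward the temporal side (`rotate_to_disc_fovea_axis()`,
   bilinear resampling, invertible transform returned).
3. The disc is cropped with a margin (default 60 px: the 50-px control frame
   plus a 10-px guard; the margin is not dictated by the measurement
   definition, so it is configurable and logged).
4. `build_regions()` constructs the **measurement region** (pixels inside
   the ellipse within 30 px of the boundary), the **control region** (pixels
   within 50 px of the crop border, disc interior excluded), a per-pixel
   angle map and sector labels.

"30 pixels inwards" is ambiguous on an anisotropic ellipse; we erode on the
normalized ellipse metric (each semi-axis shrunk by the depth), which keeps
the annulus width visually uniform. The 30/50-px defaults are tied to
~512-px optic-disc crops from 45°-field photographs at the resolution of the
cohort the method was built for; both depths are parameters. The
measurement depth must stay below the semi-minor axis or the annulus would
close (this is an error).

Angles are measured from the disc center, 0° at the intersection of the
disc-fovea axis with the measurement band on the temporal side, negative
toward superior. The six sectors follow the standard peripapillary OCT
layout: temporal $[-45°, +45°]$, temporal-superior $[-90°, -45°)$,
nasal-superior $[-135°, -90°)$, nasal (the 90° sector through 180°),
nasal-inferior $[+90°, +135°)$, temporal-inferior $(+45°, +90°)$. Sector
boundaries are half-open (with the closed temporal interval winning its
endpoints) so that zone assignment is a function; the layout itself does not
define ties. The papillomacular bundle (PMB) is the $[-15°, +15°]$
sub-sector of the temporal zone. Nine outcomes are reported: global pallor
(whole annulus), six sector pallors, PMB pallor, and the nasal/temporal
(NT) ratio, plus a 360-bin angular pallor profile (bins scored only with
≥ 20 valid pixels).

Vessels crossing the rim are much darker in green than in red, so they bias
the ratio downward; `exclude_vessels()` removes a 2-px dilation of the
vessel mask from every region. A zone left with fewer than 50 valid pixels
is flagged invalid and reported as missing, never silently zeroed.

## The synthetic image generator

`fundus_scene()` / `generate_fundus()` render a fundus-like image in which
the estimand is known exactly: background chromaticity $g/r$ is constant,
and the rim in zone $Z$ has chromaticity $g/r \times c_Z$, where $c_Z$ is
the scene's zone contrast. On a vessel-free, noise-free, flat-illumination
scene the measured pallor of every zone equals $c_Z$ in closed form, which
is the package's primary oracle. Key renderer choices:

* the disc-edge blend (2 px) is placed strictly *outside* the ellipse
  boundary, so measurement pixels are uncontaminated and the oracle is
  exact;
* vessels radiate from the disc center as curved strokes with green
  attenuated much more than red (factors 0.20 vs 0.55), mimicking the bias
  vessel exclusion exists to remove;
* illumination is a low-order polynomial gain field; because it multiplies
  both channels, a smooth gain cancels in the ratio — its QC relevance is
  exposure, not chromaticity. The original processing chain may well apply
  an illumination correction before the ratio; nothing quantitative is
  published about it, so the generator exposes illumination strength as a
  parameter instead of assuming a correction;
* default geometry: disc semi-axes 55–75 px in a 512-px frame, fovea 2.5
  disc diameters temporal at up to ±15° elevation — the proportions of a
  45° fundus photograph;
* output is 8-bit by default (camera-like); float output keeps the oracles
  exact to machine precision.

The generator does **not** model cataract media opacity, peripapillary
atrophy, pathology textures or photoreceptor mosaics. Passing tests
therefore demonstrate correctness of the geometry and photometry of the
measurement, not robustness to real-world image artefacts beyond the
modelled ones (exposure, gradients, noise, vessels).

`generate_batch()` degrades a stated fraction of images (under-exposure
×0.02, over-exposure ×1.8, or a strong illumination gradient), cycling the
three defect types; which images are degraded is part of the truth table.

## Quality control

The original rejection rules were a single human annotator's judgement; the
package provides explicit quantitative proxies with configurable thresholds
(`qc_thresholds()`): under/over-exposure when more than 20% of
measurement-plus-control pixels are near-black (< 5/255 in all channels) or
near-saturated (> 250/255 in any channel); uneven illumination when a
quadratic gain field fitted to the crop background has max/min > 1.5;
unclear border when the median luminance step across the ellipse boundary
falls below 0.02; missing fovea; and abnormal retina as a robust z-score
(> 4, median/MAD) on background chromaticity against the batch — a plain
SD-based z cannot exceed $(n-1)/\sqrt{n}$ and would let a gross outlier
mask itself in small batches. Group-wise rejection *rates* reported for the
original cohort are properties of the annotator and are not reproduced;
the summary instead recovers the generator's configured degraded fraction.

## The synthetic cohort and the statistical arm

`generate_cohort()` emulates a matched case-control study: a control arm, a
prevalent-PD arm (diagnosed before imaging) and an incident-PD arm
(diagnosed after). Covariates (age, sex, four-level ethnicity with a
White/non-White binary, hypertension, diabetes, cataract, eye surgery, disc
area) are drawn per arm from the published demographic table of the cohort
this package emulates; the nine pallor measures are generated from a latent
standardized multivariate normal with a common correlation of 0.8 (the
zones share one annulus; no correlation matrix is published, and the NT
ratio is treated as a ninth jointly-normal measure rather than derived).

Case status is tied to pallor through a multinomial-logit superpopulation
whose pallor coefficients are the configured log-odds per SD; the two
intercepts are solved numerically so the expected arm fractions match the
requested arm sizes. Conditioning a multinomial logit on {one case arm,
control} leaves a binary logistic model with exactly the configured
coefficient, so refitting recovers known truth even under
fixed-arm-size (retrospective) sampling. Covariates are independent of the
latent pallor, so the configured coefficient is also the *adjusted* truth.
Diabetes prevalence in the prevalent arm defaults to 2/89, reproducing the
situation in which diabetes cannot be adjusted for in that arm.

### The duration-effect scale

The published duration analysis reports "β per SD increase" values around
1.4 alongside prose reading them as *SD of pallor per year*. Taken
literally, 1.4 SD/year over a 25-year duration range implies rim-color
changes of tens of standard deviations — irreconcilable with the published
pallor distributions; read as *years of duration per SD of pallor* the same
numbers are unremarkable. Rather than guessing, both parameterisations are
first-class:

* `duration_model = "sd_per_year"`: durations are drawn from their own
  distribution — exponential with mean 5 y truncated at the 15-y outlier
  threshold, plus a configurable point mass (default 5/89) uniform on
  15–25 y — and pallor receives a `slope × years` increment in control-SD
  units. `fit_linear(response = "pallor")` recovers the slope on that scale.
  This is the scale of the published point estimates, and the recovery
  simulations use it.
* `duration_model = "years_per_sd"` (default): duration is the modelled
  outcome, `slope` is years per SD of pallor, and pallor itself stays at
  the published control/case distributions. Default cohorts therefore look
  like the published demographic table in every column.

The long-duration point mass exists to reproduce the outlier-sensitivity
phenomenon: `duration_effect_min_years = 15` builds cohorts whose entire
duration effect is carried by the >15-y tail, and the sensitivity scenario
removing that tail then attenuates the slope to null — mirroring the
published finding that removing five long-duration participants rendered
the duration associations non-significant.

### Models and matching

`fit_logistic()` and `fit_linear()` wrap maximum-likelihood logistic
regression (IRLS, tolerance 1e-8, ≤ 50 iterations) and OLS behind a single
reporting object: estimate per SD, SE, Wald 95% CI (the published intervals
are symmetric on the log scale, i.e. Wald), two-sided p, sample sizes, the
SD that defines the unit, and a convergence flag. Standardization uses the
population convention (divisor $n$) on the analysis sample — the reference
sample and divisor are not published, so the convention is fixed and
stated. A binary covariate whose minority level holds fewer than five
members of the case group is dropped rather than adjusted for (its
coefficient cannot be estimated); at the published arm sizes this rule
bites exactly for diabetes in the prevalent arm. Separation is flagged
(`converged = FALSE`) when it destabilises the pallor coefficient itself;
no silent estimate is returned. No multiple-testing correction is applied,
matching the original analysis (significance at p < 0.05 per test) — worth
remembering when reading the sensitivity tables.

`match_controls()` performs 1:1 matching without replacement: exact on sex,
greedy nearest-neighbour on age with the case order randomized under a
seed. The original study matched with a propensity-based package default;
both are age/sex 1:1 matching in effect, and the greedy scheme is fully
deterministic given the seed. Balance is reported as standardized mean
differences before/after.

`run_sensitivity()` refits a base model after each exclusion scenario
(cataract, eye surgery, diabetes, non-White ethnicity, duration > 15 y are
the canonical ones) and tabulates estimate shifts and significance changes.
When comparing a base fit against scenario refits on different subsamples,
pass a fixed `sd_reference` so the slopes share a unit; per-sample
standardization makes them incommensurable when the excluded rows dominate
the variance.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data
generated at run time. Parameter-recovery checks use the study's arm sizes
(89 prevalent / 381 controls; prevalent-only n = 89 for duration models)
with 200 replicates in the tests and 500 in the acceptance script —
the Monte-Carlo standard error of the recovered odds ratio at 500
replicates is below 0.01, an order of magnitude inside the comparison
bands. Confidence-interval calibration uses 500 replicates at 1000/1000.
Generator-moment checks use 30k–100k controls. The end-to-end pipeline
check runs 200 images (512 px) through generation, QC, measurement,
cohort simulation, matching and model fitting. Every random operation
takes an explicit seed; identical seeds give bit-identical images, truth
tables and result CSVs.

## Known limitations

* The pallor measure is relative to the control region by design; changes
  in the peripapillary background (atrophy, pigmentation) move the measure
  without any rim change. No absolute colorimetric calibration is
  attempted.
* Disc segmentation is assumed given (fitted from a supplied mask); the
  package deliberately does not localize the disc or fovea in raw
  photographs.
* QC proxies are calibrated on the synthetic degradations; their thresholds
  are starting points, not reproductions of a human annotator.
* The cohort generator draws covariates independently of pallor; real
  confounding structure (pallor declining with age, varying by ethnicity)
  is not emulated, which is precisely what makes the configured effects
  exact truths for recovery testing — and what a realism-focused user must
  add before using it for power analysis.
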
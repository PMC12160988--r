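# pallorkit

Quantification of optic disc pallor from color fundus photographs, with a
fully synthetic test bed and the matched case-control statistics used to
study pallor as a biomarker of Parkinson's disease (PD).

Pallor of the neuro-retinal rim — the visible correlate of peripapillary
nerve-fiber-layer loss — is quantified as a dimensionless reflectance ratio.
For a rim zone *Z* and a peripapillary control region *C*:

```
pallor(Z) = [ mean(G)_Z / mean(R)_Z ] / [ mean(G)_C / mean(R)_C ]
```

with G and R the green/red channels and vessels excluded from both regions;
higher = paler. The measurement band extends 30 px inward from the disc
boundary (an ellipse fitted to the disc mask), rotated so 0° points along
the disc-fovea axis, and is sectored into the standard peripapillary zones:
temporal (±45°), temporal/nasal superior and inferior obliques (45° each),
nasal (90°), and the papillomacular bundle (±15°). Nine outcomes result:
global pallor, six sector pallors, PMB pallor and the nasal/temporal ratio.

The package contains:

* **synthetic fundus generator** (`fundus_scene()`, `generate_fundus()`,
  `generate_batch()`) — fundus-like images with exact ground truth (disc
  ellipse, fovea, vessel mask, per-zone contrast), so the measurement has a
  closed-form oracle;
* **geometry** (`fit_ellipse()`, `rotate_to_disc_fovea_axis()`,
  `crop_disc()`, `build_regions()`);
* **pallor metrics** (`exclude_vessels()`, `zone_pallor()`,
  `compute_pallor()`, `measure_pallor()`);
* **quality control** (`assess_quality()`, `qc_batch()`, `qc_summary()`) —
  quantitative proxies for exposure, uneven illumination, unclear border,
  abnormal retina and missing fovea;
* **synthetic cohort** (`cohort_params()`, `generate_cohort()`,
  `apply_exclusions()`) — case-control tables with known effect sizes;
* **statistics** (`match_controls()`, `standardize()`, `fit_logistic()`,
  `fit_linear()`, `compare_groups()`, `run_sensitivity()`) — age/sex
  matching and the adjusted models reporting odds ratios / slopes per SD;
* **pipeline** (`run_config()`, `run_pipeline()`) plus a thin CLI at
  `inst/scripts/pallorkit`.

## Worked example

Render a synthetic eye whose temporal rim is markedly pale, then measure it:

```r
library(pallorkit)

scene <- fundus_scene(zone_contrast = c(T = 1.45, TS = 1.25, NS = 1.15,
                                        N = 1.18, NI = 1.10, TI = 1.28),
                      seed = 42)
img <- generate_fundus(scene)
measure_pallor(img$image, img$truth$disc, img$truth$fovea,
               vessel_mask = img$truth$vessel_mask)
#> optic disc pallor (zone G/R relative to control):
#>            global          temporal temporal_inferior    nasal_inferior
#>             1.259             1.450             1.280             1.100
#>             nasal    nasal_superior temporal_superior               pmb
#>             1.180             1.150             1.250             1.450
#>          nt_ratio
#>             0.814
```

Every zone recovers its ground-truth contrast exactly (temporal 1.45, nasal
1.18, ...); global pallor is the annulus-wide ratio and the NT ratio
(nasal/temporal = 0.814) is below 1 because the temporal rim is palest.

Fit the adjusted case-control model on a simulated cohort (here with the
default generator, prevalent-PD arm vs controls, global pallor per SD):

```r
tab <- generate_cohort(cohort_params(), seed = 1)
tab$case <- tab$group == "prevalent_pd"
fit_logistic(tab[tab$group != "incident_pd", ], "case", "global")
#> logistic model, measure 'global': OR per SD = 1.077 (95% CI 0.843-1.375), p = 0.5526
#>   n = 89 cases / 381 controls; 1 SD of global = 0.227
#>   covariates dropped (sparse exposure): diabetes, cataract
```

A single cohort at these arm sizes is noisy (the CI spans 1); the
parameter-recovery simulations below average hundreds of replicates.

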
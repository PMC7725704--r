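# petscoresim

Simulation study of how MR-based attenuation-correction (MRAC) error in
brain FDG-PET propagates into an automated Alzheimer's-disease
discrimination statistic — a PALZ-style PET score — built entirely on
synthetic phantoms so that no patient or ADNI data is needed.

PET/MR derives its attenuation map from MR (atlas registration or
zero-echo-time bone segmentation) instead of CT, leaving spatially
structured, skull-concentrated multiplicative error in the reconstructed
image. This package lets you ask, on reproducible synthetic cohorts,
how much of that error survives an automated scoring pipeline and moves
the final score, and whether a low-variance "ZTE-like" error regime is
more benign than a high-variance "Atlas-like" one.

## The statistic

Given a subject volume in template space, the pipeline: smooths with a
12 × 12 × 12 mm FWHM Gaussian; normalizes intensities by the mean over a
preserved-uptake mask; compares each voxel to a voxelwise age regression
fitted on normal controls,

```
t_v = ((a_v + b_v·age) − x_v) / (s_v · sqrt(1 + 1/n + (age − ā)² / S_xx))
```

sums t over the AD-pattern mask (the AD t-sum), and maps it to

```
PET score = log2(AD t-sum / 11089 + 1)
```

so a t-sum at the 95% prediction limit 11089 gives a score of exactly 1.
Attenuation error is injected as a multiplicative voxelwise field
(MRAC-PET ÷ CTAC-PET, smoothed and brain-masked), crossed with a cohort:
107 subjects × 27 maps = 2889 scored images per method.

## Worked example

```r
library(petscoresim)

pet_score(c(0, 11089, 3 * 11089))
#> [1] 0 1 2

cfg <- study_config(grid_shape = c(16, 16, 16), n_controls = 8,
                    n_nc = 6, n_ad = 6, n_maps_per_regime = 2,
                    boot_reps = 100, seed = 1)
res <- run_end_to_end(cfg)
res$diff_stats[, c("method", "n", "mean_diff", "mean_abs_diff")]
#>       method  n   mean_diff mean_abs_diff
#> 1 Atlas_like 24 -0.04528720    0.04528720
#> 2   ZTE_like 24  0.01481841    0.01481841
```

The table reads: across all (subject × error map) combinations, the
Atlas-like error regime perturbs PET scores about three times as much as
the ZTE-like regime (mean absolute score difference 0.045 vs 0.015), with
a net negative bias — underestimation near the skull drags the score
down slightly. `res$diagnostics` holds, per series, classification at the
fixed cutoff (score ≥ 1), the empirical ROC with trapezoidal AUC and a
bootstrap CI, and the Youden-index cutoff.

## The full analysis

Numbered drivers under `analysis/` run the study at the original cohort
structure (48 database controls, 48 NC + 59 AD test subjects, 27 error
maps per regime → 2889 scored images per method, 5778 total) and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_and_score.R   # cohort × error-map scoring
Rscript analysis/02_agreement.R            # regression + Bland–Altman, paired t
Rscript analysis/03_diagnostics.R          # cutoff metrics, ROC/AUC/Youden
```

On a 32³ grid stage 1 takes ~15 s and reports, per regime, mean absolute
score error 0.032 (ZTE-like) vs 0.129 (Atlas-like), per-subject agreement
R² > 0.999 for both, and AUC 1.000 vs 0.998 — error variance shifts
individual scores but leaves group discrimination essentially intact.
Note that on a desk-scale grid the AD t-sums sit far below the constant
11089 (calibrated on the full-resolution template), so the fixed cutoff 1
is not informative here; use the reported Youden cutoffs and AUC.

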
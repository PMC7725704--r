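---
title: "Simulating attenuation-correction error propagation into an automated AD PET score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating attenuation-correction error propagation into an automated AD PET score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petscoresim)
```

## The problem

PET/MR scanners cannot measure photon attenuation directly the way PET/CT
does: the attenuation map must be derived from MR images (MRAC), either by
registering a population CT atlas (Atlas-AC) or by segmenting bone from a
zero-echo-time sequence (ZTE-AC). Both introduce spatially structured,
mostly bone-driven error into the reconstructed FDG-PET image relative to
the CT-based reference (CTAC). Clinically, brain FDG-PET is often read
through automated statistics; a widely used one summarizes
Alzheimer-pattern hypometabolism as a single PET score. The question this
package addresses is: how much of the MRAC error survives the scoring
pipeline and moves the PET score, and does the lower-variance ZTE-style
error matter less than the atlas-style error?

Because patient PET/MR data and reference cohorts cannot be redistributed,
the package answers this on fully synthetic brain phantoms: every input
the analysis assumes is generated by code, so the whole study is
reproducible from a seed.

## The scoring statistic

Scoring follows the standard automated AD-discrimination pipeline:

1. **Smoothing.** A separable Gaussian filter, default FWHM 12 × 12 × 12 mm
   (`smooth_gaussian()`), with σ = FWHM / (2√(2 ln 2)) per axis. The
   convolution is zero-padded; every downstream statistic is restricted to
   the brain mask, so the edge treatment cannot bias results.
2. **Intensity normalization.** Division by the mean over a mask of voxels
   whose uptake is typically preserved in AD (`intensity_normalize()`).
   The output mean over that mask is exactly 1, which makes the score
   invariant to any global rescaling of the input — the mechanism by which
   a spatially *uniform* multiplicative attenuation error cancels exactly.
3. **Normal database.** Per voxel, ordinary least squares of normalized
   control uptake on age (`fit_age_regression()`): intercept $a_v$, slope
   $b_v$, residual SD $s_v$ (denominator $n-2$), plus $n$, $\bar a$ and
   $S_{xx}$.
4. **t-map.** For a subject of age $a$,
   $$t_v = \frac{(a_v + b_v a) - x_v}{s_v\sqrt{1 + 1/n + (a-\bar a)^2/S_{xx}}}$$
   (`compute_tmap()`). The numerator is *expected − observed*, so
   hypometabolism gives positive t.
5. **AD t-sum and PET score.** The t-values are summed over the AD-pattern
   mask (`ad_tsum()`) and mapped to
   $\mathrm{PET\ score} = \log_2(\text{AD t-sum}/11089 + 1)$
   (`pet_score()`), where 11089 is the published 95% prediction limit of
   the AD t-sum; a t-sum of 11089 maps to a score of exactly 1.

Three choices here were genuinely open and are our own conventions:

* the t-statistic uses the single-new-observation prediction standard
  error $\sqrt{1 + 1/n + (a-\bar a)^2/S_{xx}}$, the standard form for
  comparing one subject against a regression-modelled reference
  population;
* the AD t-sum is a plain sum with **no thresholding**: negative t-values
  are included, so the PET score can be negative for markedly
  hypermetabolic subjects;
* normalization is applied **after** smoothing.

`s_v` is floored at `s_floor` (default 10⁻⁶ × mean normalized brain
uptake) so that noise-free synthetic databases, whose residuals vanish,
still produce finite t-values.

## The synthetic data

`make_template_masks()` builds a deterministic geometric head model on an
RAS grid (2 mm isotropic; 91 × 109 × 91 mimics the usual template
bounding box, 32³ keeps experiments fast): the brain is a filled
ellipsoid, the AD pattern its posterior-superior sector (a proxy for the
temporoparietal/posterior-cingulate hypometabolism pattern) and the
preserved-uptake mask the disjoint anterior-inferior sector. These are
geometric proxies, not anatomy; there is no gray/white parcellation.

`simulate_scan()` builds uptake as
`base × (1 + slope·(age − 70)) × (1 − severity·AD) × lognormal noise`:

* `base_uptake = 1` — arbitrary units; scoring is scale-invariant, so the
  plateau value is immaterial.
* `age_slope_per_year = −0.005` — a 0.5%/year decline, the order of
  magnitude reported for adult cortical FDG metabolism. It applies to the
  brain **minus the preserved mask**, so normalization does not absorb the
  age trend (the preserved region is, by construction, age-stable).
* `subject_noise_sd = 0.10` — 10% voxelwise lognormal inter-subject
  variability. Lognormal (not additive Gaussian) guarantees nonnegative
  uptake; the unit-mean parameterization keeps the expected image equal to
  the noise-free one. The noise is voxelwise independent, which is
  unrealistically white compared with real PET; it is the variance scale,
  not the correlation structure, that the downstream statistics exercise.
* `ad_severity = 0.15` — a 15% multiplicative reduction inside the AD
  pattern, a moderate-dementia effect size.
* ages are uniform on 55–85 years, centred on the reference age 70.

`simulate_error_field()` builds multiplicative error fields
`1 + bias·w + sd·w·G` inside the brain (exactly 1 outside), where `G` is
white noise smoothed at the correlation length (default 12 mm) and
standardized over the brain — the simplest stationary smooth field — and
`w = 1 + skull_weight · shell` concentrates error magnitude in the
3-voxel shell at the brain boundary (`skull_weight = 2`), because
attenuation-correction error is bone-driven and largest near the skull.
Two regimes are configured: **ZTE-like** (bias −0.02, SD 0.02) and
**Atlas-like** (bias −0.02, SD 0.05). These encode the qualitative
finding that ZTE-based correction is both less biased per map and less
variable across maps; they are deliberately not fits to any reported
numbers. Fields are clipped below at 0.1, and parameter sets driving more
than 1% of brain voxels non-positive before clipping are rejected as
misconfigured.

The pseudo-CT utility `zte_bone_to_hu()` encodes the published linear
bone mapping (offset 300 HU, slope 2400 HU, cap 2000 HU; fixed 42 HU soft
tissue). Only the three constants are published, not the equation; our
convention `HU(z) = min(offset + slope·(1−z), cap)` with `z = 1` at
soft-tissue-like proton density reproduces the offset at the soft-tissue
end, increases monotonically toward dense bone and honours the cap. The
direction of the z-axis is declared, not inferred.

## The simulation study

Real error maps are ratios of an MRAC-corrected to the CTAC-corrected PET
volume of the same patient (`compute_error_map()`, with an ε-guard that
sets brain voxels with near-zero denominator to 1 — the handling of such
voxels is unstated in the source methodology, so the guard is our declared
convention). Maps are then **conditioned** (`condition_error_map()`):
mask-normalized smoothing — smooth `field × brain` and `brain` separately
and divide — followed by setting the outside-brain value to exactly 1.
Mask-normalized smoothing is used instead of smooth-then-mask so that
edge values, precisely where skull-driven error concentrates, are not
diluted toward the outside fill; a constant field passes through
unchanged. The fill value 1 makes error application a no-op outside the
brain.

`apply_error()` multiplies a normalized subject volume by a conditioned
map voxelwise — no re-smoothing, no re-deformation — and
`run_simulation()` crosses a cohort with a map list (plus one identity
map per subject for the original scores), scoring everything with
`pre_normalized = TRUE`: simulated images are built from already-smoothed
template-space data, so no further filtering is applied, but intensity
normalization always runs (it is part of the statistic, and is what makes
uniform bias cancel).

Two exact invariants pin the mechanics: identity maps reproduce original
scores to machine precision, and a uniform field `1+δ` inside the brain
changes the normalization factor by `1+δ` and therefore no score — only
spatially structured error can move the PET score.

## Evaluation

`score_difference_stats()` summarizes signed and absolute
`simulated − original` score differences per method;
`paired_ttest_abs()` compares the two regimes' absolute errors over
matched pairs; `per_subject_average()`, `regression_agreement()` and
`bland_altman()` give the per-subject agreement view (LOA use the fixed
1.96 multiplier of standard Bland–Altman practice);
`classify_at_cutoff()` classifies AD vs NC at a fixed score cutoff with
Wilson 95% intervals (the original report does not name its CI method;
Wilson behaves well at proportions near 0 and 1); `roc_analysis()` builds
the empirical ROC with the `score ≥ cutoff` positivity rule, trapezoidal
AUC (identical to pairwise concordance with ties counted ½), the
Youden-optimal cutoff (lowest threshold on ties, floating-point ties
treated as ties at 10⁻¹²) and a seeded class-stratified percentile
bootstrap for the AUC CI (2000 replicates by default; the original CI
method is likewise unnamed). When 2889 pooled rows per method are
evaluated, rows sharing a subject are treated as independent, replicating
the pooled analysis design; per-subject averaging is available and
labelled where the conservative alternative is wanted.

## Study conditions and problem sizes

The shipped drivers (`analysis/01_simulate_and_score.R` …) run the full
study at the original cohort structure — 48 controls in the normal
database, 48 NC + 59 AD test subjects, 27 error maps per regime, hence
107 × 27 = 2889 scored images per method and 5778 in total — on a 32³
grid, which completes in well under a minute. The package-level test
suite exercises the same pipeline at 16³–32³. One consequence of the
desk-scale grid is worth stating plainly: the AD-pattern mask has only a
few thousand voxels, so synthetic AD t-sums sit far below the published
normalization constant 11089, which was calibrated on the full-resolution
template. Synthetic AD subjects therefore score well below the fixed
cutoff of 1, and the fixed-cutoff sensitivity is not meaningful at this
scale; the Youden-selected cutoff (reported alongside) is the operative
one, and AUC — which is cutoff-free — is the right cross-regime
comparison. The directionality results (ZTE-like absolute score error
< Atlas-like; tighter agreement with originals; AUC preserved across
regimes) are scale-independent and are what the acceptance tests assert.

```{r demo}
cfg <- study_config(grid_shape = c(16, 16, 16), n_controls = 8,
                    n_nc = 6, n_ad = 6, n_maps_per_regime = 2,
                    boot_reps = 100, seed = 1)
res <- suppressWarnings(run_end_to_end(cfg))
res$diff_stats[, c("method", "n", "mean_diff", "mean_abs_diff")]
```

## Known limitations

* Phantoms are geometric, with white subject noise and a single global
  age-sensitive compartment; passing tests show the pipeline's mechanics
  and directionality, not performance on real anatomy.
* Error fields are stationary Gaussian apart from the skull shell weight;
  real MRAC error has patient-specific bone structure.
* PET reconstruction, registration/spatial normalization and pseudo-CT
  generation are out of scope: all data live on the template grid from
  the start.
* The commercial tool's exact masks and any internal t-value thresholding
  are unknown; our unthresholded sum is documented prominently and kept
  consistent everywhere.
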
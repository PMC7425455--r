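---
title: "Vascular risk, cortical atrophy and cognition: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular risk, cortical atrophy and cognition: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vrfmed)
```

## The scientific question

Modifiable vascular risk factors (VRFs) — diabetes, hypertension, heavy
smoking, lifetime major depression, low educational attainment and obesity —
accumulate in aging cohorts and are suspected of accelerating cortical
atrophy, which in turn degrades cognition. `vrfmed` implements the full
statistical chain used to test that chain of effects in a four-group
Alzheimer's-spectrum cohort (cognitively normal, early and late mild
cognitive impairment, dementia): composite risk scoring, voxel-based
morphometry-style mass-univariate models on gray-matter volume (GMV) maps,
Monte-Carlo cluster-extent correction, conjunction analysis, and a
single-mediator decomposition of the risk-to-cognition effect.

## Composite VRF score

Each factor is binarized from its clinical criterion (`>=` boundaries for
glucose 200 mg/dl, untreated SBP 140 / DBP 90 mmHg and 20 cigarettes/day;
strict `>` for BMI 30 kg/m²; medicated subjects count as hypertensive
regardless of readings). The composite is the weighted indicator sum. The
per-factor relative-risk weights used in the original analysis are not
printed in the source literature, so the package never hard-codes them:
unit weights are the default (score = factor count, 0–6) and a versioned,
editable JSON weight table ships as an example
(`inst/extdata/vrf_weights_example.json`, populated with commonly cited
population relative risks around 1.5–1.65 per factor). Missing
measurements propagate to an `NA` indicator; the scoring policy is
`"strict"` (error) by default, `"zero"` (impute-absent with a warning) on
request, because silent zero-imputation of clinical data is never
acceptable as a default.

## Voxel-wise models

The per-voxel regression is ordinary least squares,

GM_i = b0 + b1·predictor + b2·Age + b3·Gender + b4·Education + b5·APOE4 + e,

with the predictor of interest (VRF score, MMSE or ADAS-Cog) always in
column 2. Education appears in the model equations of the source analysis
but not in its covariate prose; the package includes it by default and
makes both covariate sets configurable. Likewise diagnostic group is
excluded by default (matching the written equation) but can be added as
k−1 dummies (`include_group = TRUE`) — the configuration used for the
displayed risk-effect maps in the original work, and the one required for
unbiased estimation in a group-confounded cohort (below). t statistics use
df = n − p; z-maps are the probability-preserving probit transform of the
two-sided t tail, computed in log space so |t| up to ~40 does not
underflow, with the sign restored from the slope. Voxels with numerically
zero residual variance are flagged and given ±Inf sentinels rather than
dropped. The whole voxel loop is a single QR solve; a test asserts
equality with an independent per-voxel normal-equations oracle at 1e-10.

## Cluster-extent correction

The correction is self-contained (no AFNI dependency):

1. **Smoothness** is estimated from the standardized GLM residuals by the
   gradient method: per axis, FWHM = d·sqrt(4·ln 2 / v) where v is the
   pooled variance of first differences between in-mask neighbours and d
   the voxel size. For white noise v = 2 and the estimate is 1.18 voxels;
   for 6 mm smoothing on a 2 mm grid the estimate carries a small (~3%)
   upward discretization bias, well inside the 5.1–6.9 mm acceptance
   window. The log-ACF (Forman) variant was rejected because it degenerates
   on unsmoothed noise.
2. **Null tables**: per iteration a Gaussian field is smoothed to the
   target FWHM on a padded grid (padding 4σ, so edges are exact),
   standardized *within the mask* — smoothing changes the marginal
   variance, and standardizing afterwards makes the voxel-wise p exact
   under the null — thresholded two-tailed on |z| (one-tailed available),
   and the largest connected cluster recorded. The extent threshold for
   (p_vox, α) is the ceiling of the empirical (1−α) quantile of the maxima
   (≥ 1 voxel). Clusters at least that large survive (`>=` semantics).
3. **Connectivity** defaults to 6 (faces), configurable to 18/26; the
   original work does not state its neighbourhood level.

With discrete cluster sizes the `>=`-quantile rule is slightly
anti-conservative; the measured family-wise error at α = 0.05 on the
default 32³ spherical mask is ≈ 0.06, inside the 3–8% acceptance band.
The printed extent thresholds of the source analysis (1120 mm³, 675 mm³)
depend on its unavailable MNI-space mask and are treated as configuration
echoes, not reproduction targets.

## Conjunction and ROIs

Conjunction is the voxel-wise AND of two *cluster-corrected* binary maps
(risk-effect ∩ cognition-effect), matching the original sequence; the
choice of corrected rather than uncorrected inputs is an assumption the
source leaves implicit. Connected components become automatically named
ROIs (`ROI_001`… by descending size; no anatomical atlas is bundled), and
per-subject ROI mean GMV is the mediator.

## Mediation

Three OLS regressions with intercepts and an identical optional covariate
set: total (Y on X), mediator (M on X), full (Y on X + M). Under a shared
covariate set the decomposition c = c' + a·b is an algebraic identity of
nested OLS and is tested at 1e-10. Inference on a·b:

* **Sobel z** with the first-order delta SE `sqrt(b²·se_a² + a²·se_b²)`;
  the second-order `+ se_a²·se_b²` variant is available behind a flag.
* **Percentile bootstrap** over case (subject) resampling, 10,000 samples
  and 95% CI by default; significance = CI excluding zero. Percentile
  rather than BCa is the minimal faithful reading of "95% confidence
  intervals"; BCa was deliberately not silently substituted. Replicates
  with constant X or M are redrawn and counted; >10% redraws aborts.
  Factor covariates are dummy-coded once, before resampling, so a
  resample can never silently change the coding. Each (ROI × outcome)
  analysis derives its seed from a stable hash of the ROI and outcome
  names, so panel results are independent of panel composition and order.

A known property worth stating: percentile CIs for a product undercover
slightly in small samples — a side experiment at n = 100 with moderate
paths (a = b = 0.5) measured 91.7% ± 1.1% coverage at nominal 95%. At the
package's stated cohort size (n = 192, default effect sizes) coverage is
≈ 96%, and the null rejection rate at n = 100 is within 3–8%.

## The synthetic world

No generative model is given by the source analyses, so the generator uses
the additive linear Gaussian structure those analyses assume, making
parameter recovery well defined. Defaults state the emulated conditions:

| parameter | default | meaning |
|---|---|---|
| `group_sizes` | 69/52/41/30 | the published four-group design (n = 192) |
| `grid_shape`, `voxel_size` | 32³, 2 mm | desk-scale stand-in for MNI space |
| `smoothing_fwhm_mm` | 6 | output smoothness of the emulated VBM pipeline |
| `roi_masks` | two 5³ boxes | embedded atrophy regions inside a spherical mask |
| `beta_vrf_gmv` (a) | −0.03 | GMV-units lost per score unit in the ROIs |
| `beta_gmv_cog` (b) | +30 (MMSE), −90 (ADAS-Cog) | points per GMV-unit |
| `beta_direct` | −0.2 / +0.6 | direct risk→cognition path |
| `group_atrophy` | 0/−0.01/−0.02/−0.05 | additive group-level GMV offsets |
| `subject_sd_gmv` | 0.05 | per-subject anatomical ROI-GMV variability (~10% of the ~0.55 ROI mean) |
| `noise_sd_image` | 0.02 | per-voxel SD of the smoothed image noise |
| `noise_sd_cog` | 1 (MMSE), 4 (ADAS-Cog) | cognition noise |
| `vrf_prevalence` | rises with severity | tuned once so unit-weight score means ≈ 1.1/1.4/1.4/2.1 |

Noise fields are white noise Gaussian-filtered with σ = FWHM/2.3548 per
axis (the standard FWHM↔σ relation) on a padded grid and re-standardized
to unit voxel SD. One master seed feeds documented substreams (seed+1
cohort, seed+2 images, seed+3 cluster nulls, seed+5 mediation), so equal
seeds give byte-identical outputs.

Three deliberate realism features and their consequences:

* **Group confounding.** VRF prevalence rises with disease severity, so
  diagnostic group confounds both the X→M and X→Y paths, exactly as in an
  observational cohort. Unadjusted maps show diffuse whole-brain risk
  "effects" through the group channel; recovery of the generating
  parameters therefore requires group adjustment in the GLMs and in all
  three mediation regressions, which the recovery tests use. A green
  recovery test establishes that the *adjusted* pipeline is consistent —
  not that unadjusted estimates would be.
* **Mediator measurement error.** Cognition is generated from the
  per-subject *true* mediator (anatomy), while the pipeline measures the
  ROI mean of a noisy image. With the default noise the measured-mediator
  reliability is ≈ 0.96–0.98, attenuating b by a few percent — visible as
  estimates near −85 for a true −90 — and left uncorrected, as any real
  VBM mediation analysis would leave it.
* **MMSE ceiling.** MMSE is clipped to [0, 30], compressing the healthy
  end of the scale; its b path is biased further toward zero than
  ADAS-Cog's. Recovery assertions use ADAS-Cog; the MMSE panel is still
  produced and its signs are tested.

What a green pipeline run does *not* establish: anything about
registration/segmentation quality (the generator emulates their outputs,
not the processes), non-Gaussian noise, spatially varying smoothness,
longitudinal change, or anatomical naming of ROIs.

## Numerical and policy choices

* Two-sided p-values everywhere; sidedness is not stated in the source.
* Post-hoc pairs are Welch t tests at threshold α/m (0.05/3 = 0.0167 for
  three comparisons against the dementia group), a robust default
  consistent with the published divisor.
* Partial correlations support both covariate sets in use: age/gender/
  APOE4/total-GMV (behavioural analysis) and the regression covariates.
* mm³ = voxels × voxel volume exactly; extent thresholds are integers.
* The CI-significance wording of the source ("bound between 0 and ±1") is
  read as "the CI lies strictly on one side of zero"; nothing further is
  inferred from it.
* Degenerate inputs error loudly (empty masks, zero within-group variance,
  rank-deficient designs with the collinear columns named, collinear X/M).

## Limitations

Single mediator only (no serial or multiple mediation); no random-field
or ACF-based alternatives to the Monte-Carlo cluster null; no atlas
lookup; cross-sectional only. The acceptance suite's simulation sizes are
chosen to finish in minutes on one CPU; all bands and tolerances are the
specification's, not tuned to the implementation.
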
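---
title: "Whole-body DWI tumor load analysis: models, conventions and design choices"
author: "wbdwi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body DWI tumor load analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the signal model, the exact statistical conventions (which matter, because
histogram features are only comparable under a fixed convention), the
design choices made where the underlying procedure is not fully
standardised, and what the synthetic phantom cohort does and does not
demonstrate.

## 1. Signal model and ADC mapping

Diffusion-weighted MRI attenuates the signal of mobile water. Under the
mono-exponential model the signal at diffusion weighting $b$ (s/mm²) is

$$S(b) = S_0\, e^{-b\,\mathrm{ADC}},$$

so from a two-point acquisition at $b_{low} = 50$ and $b_{high} = 800$
s/mm²,

$$\mathrm{ADC} = \frac{\ln(S_{50}/S_{800})}{800 - 50}.$$

`compute_adc()` applies this voxelwise and reports ADC in ×10⁻⁶ mm²/s, the
unit used throughout the feature tables. Design points:

* **b = 50 is used as acquired**, not idealised to b = 0. A small non-zero
  low b-value suppresses the perfusion contribution; treating it as zero
  would bias ADC upward.
* **Validity**: a voxel with either signal ≤ 0 has no defined log-ratio; it
  is marked invalid and excluded from every downstream histogram. This is
  an explicit validity grid, not a silent NA.
* **Negative ADC values** arise when noise pushes $S_{800}$ above
  $S_{50}$ (common in air/background). Vendor handling is not
  standardised, so they are *retained* by default and counted
  (`n_negative`); `clip_negative = TRUE` clamps them to zero. Whichever is
  chosen is echoed in the run configuration.
* Multi-b-value fitting, IVIM, kurtosis models and noise-floor correction
  are out of scope.

A precomputed (e.g. scanner-side) ADC volume can be ingested with
`as_adc_map()` instead; recomputation from the b-value pair is the
reference behaviour.

## 2. Threshold segmentation: the "total tumor load" mask

`segment_threshold()` selects voxels with b800 intensity at least
`th`% of a per-volume reference intensity, for
th ∈ {5, 10, 20, 40, 60, 80} by default. Two properties define the method:

* **No editing.** No hole filling, no connected-component filtering, no
  manual exclusion. Hyperintense organs (brain, kidneys, spleen) and
  chemo-activated bone marrow deliberately remain inside the mask — the
  price of full automation, and the regime all downstream statistics must
  survive.
* **The percentage reference is a convention, not a fact.** The tools this
  procedure descends from never state what the percentage is relative to.
  The default here is the *robust maximum*: the 99.9th percentile of
  positive voxel intensities, insensitive to isolated hot voxels.
  Alternatives (`"max"`, `"mean_sd"`) are available, and the rule in force
  is recorded in every mask object and run log. The reference is
  per-volume (per patient *and* timepoint), since each acquisition has its
  own arbitrary intensity scale.

Masks nest by construction: th₂ ≥ th₁ implies mask(th₂) ⊆ mask(th₁), so
the diffusion volume is non-increasing in threshold — both are tested
properties.

**Diffusion volume** is pure voxel counting,
$DV = n_{vox}\cdot dx\,dy\,dz/1000$ cm³. No partial-volume interpolation
is attempted (the vendor behaviour is unknown; counting is the simplest
defensible convention). At 2 mm in-plane sampling, digitisation error for
a 10 mm-radius sphere is ≈ 5%; at 1 mm it falls below 2% — volumes of
structures a few voxels across carry discretisation uncertainty that no
counting rule removes.

## 3. Histogram features: exact conventions

`histogram_features()` computes, over valid masked voxels:

| feature | convention |
|---|---|
| ADCmean | arithmetic mean |
| ADCsd | sample sd, n − 1 denominator |
| ADCmd | median |
| ADC5p, ADC95p | linear interpolation between order statistics (h = (n−1)p + 1) |
| ADCsk | Fisher–Pearson $m_3/m_2^{3/2}$, no bias correction |
| ADCkurt | Fisher excess $m_4/m_2^2 - 3$, no bias correction |
| ADCentr | Shannon entropy, bits, 1024 bins over [0, 4000] ×10⁻⁶ mm²/s |

Why these and not the alternatives:

* **Moments without bias correction** keep the oracle (direct formula
  evaluation over the value list) exact, and small-sample corrections are
  immaterial at mask sizes of 10³–10⁶ voxels.
* **Entropy binning**: published whole-body entropy values of ~8.3–8.5
  bits rule out a 256-bin histogram (ceiling log₂256 = 8); 1024 bins over
  a *fixed* ADC range gives a 10-bit ceiling and — crucially — makes
  entropy comparable across timepoints, which a per-mask adaptive range
  would destroy. Out-of-range values are clamped into the edge bins rather
  than dropped.
* **Degenerate inputs**: a constant sample has sd = 0 and entropy 0 while
  skewness/kurtosis are undefined (returned as `NA`, the others still
  computed); an empty mask is an error naming the patient, timepoint and
  threshold. Statistics needing more voxels than available (sd: 2,
  skewness: 3, kurtosis: 4) degrade individually, never silently.

Percentage changes are plain arithmetic,
$\Delta f = 100\,(f_{later} - f_{earlier})/f_{earlier}$, with the earlier
timepoint always the denominator (T0 for Δ⁰¹/Δ⁰², T1 for Δ¹²). A zero
denominator produces a *flagged* missing delta record, not a crash and not
an Inf.

## 4. The comparison engine

Four analysis modes compare complete (CMR) against partial (PMR)
responders — patients with stable or progressive disease are excluded, as
are features missing for any included patient (both land in the
completeness report):

| mode | candidate sources | grouping label |
|---|---|---|
| predict_interim | f⁰ | interim |
| predict_eot | f⁰, f¹, Δ⁰¹ | EOT |
| assess_interim | f¹, Δ⁰¹ | interim |
| assess_eot | f², Δ⁰², Δ¹² | EOT |

Per candidate feature:

1. **Normality gate**: Lilliefors-corrected Kolmogorov–Smirnov per group
   (correction because mean/sd are estimated from the sample). Both groups
   must pass at α = 0.05 *and* have n ≥ 5 for the t route. Zero-variance
   samples are non-normal by convention; n = 4 samples (below the
   Lilliefors table range) are conservatively routed to the rank test.
2. **Two-group test**: Welch t, or two-sided Mann–Whitney U — exact by
   full null enumeration when the combined n ≤ 14 with no ties (the regime
   of 15-vs-3 style subgroups, where the approximation is at its worst),
   otherwise the normal approximation with tie correction. An
   all-constant pooled sample yields p = 1 directly (the test statistic's
   variance is zero and carries no evidence).
3. **ROC** only for features with p < α: AUC as the tie-corrected rank
   statistic (identical to U/(n₁n₂), a tested identity); orientation
   chosen per feature so AUC ≥ 0.5 and always reported, because the
   discriminating direction genuinely differs between features (diffusion
   volume rises with poor response, ADC percentiles fall); cutoff at the
   maximum of Youden's J over midpoints between distinct values, ties
   broken toward higher specificity; accuracy is the prevalence-weighted
   mean of sensitivity and specificity (a reported-and-tested identity),
   rounded to integer percent for display with unrounded values retained.
4. **No multiple-testing correction** is applied to the significance
   calls — the procedure tests each feature at α = 0.05 as published
   analyses of this design do. Benjamini–Hochberg q-values are printed as
   a clearly supplementary column and play no role in selection. With
   ~54–162 candidates per mode, a handful of false positives per mode is
   the expected cost; the type-I calibration of the per-feature test
   itself is verified by simulation (empirical rate ~0.05–0.06 at the
   14-vs-6 sizes).

## 5. The phantom cohort: what it emulates, and what it does not

`phantom_spec()`/`render_phantom()` build a stylised torso, not an
anatomical atlas: an elliptical body cylinder in air, an overhead brain
ellipsoid, paired kidneys, a spleen, a thin spinal marrow stripe, and any
number of ellipsoidal lesions. Default tissue parameters (signal s0 in
arbitrary units, ADC in ×10⁻⁶ mm²/s):

| region | s0 | ADC mean (sd) | b800 appearance |
|---|---|---|---|
| body soft tissue | 100 | 1400 (200) | dim background |
| lesion | ~500 | 750–1050 (100–200) | brightest, ~7× background |
| brain | 400 | 800 (100) | hyperintense confounder |
| kidneys | 450 | 1800 (150) | moderate confounder, high ADC |
| spleen | 350 | 900 (100) | hyperintense confounder |
| marrow (activated) | 150 (300) | 600 (100) | brightens under chemo |

Voxel ADC is drawn from the region's Gaussian truncated at zero (clamping;
heterogeneity gives the histogram features realistic spread); signals
follow the mono-exponential model; **Rician** noise
$\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$, $\epsilon_i \sim N(0,\sigma)$, is
applied independently per b-value because magnitude MR data is Rician (its
mean bias is < 3% at SNR ≥ 5, checked against the analytic Rician mean).
The default grid is 96 × 96 × 220 voxels at 2 × 2 × 5 mm (≈ 2M voxels, a
whole-body field of view at realistic slice thickness).

**Response scenarios** scale each lesion per timepoint: radii by the cube
root of the volume factor (so true volume scales by the factor), ADC mean
*and sd* by the ADC factor — treatment-induced cell death both raises and
broadens the diffusion distribution, which is what lets spread-sensitive
features (ADCsd, ADC95p, entropy) respond. Defaults, chosen once as
order-of-magnitude physiology (no quantitative effect sizes are published
for this design): complete responders shrink to 15%/5% of baseline volume
at T1/T2 with ADC ×1.30/×1.40; partial responders 60%/50% and
×1.05/×1.10; progressive disease regrows to 130% by T2 with a slight ADC
drop; interim-partial patients who convert to complete response by EOT get
an intermediate "late responder" trajectory. Marrow activation switches on
at T1/T2 for all treated patients. `make_cohort()`'s default EOT-outcome
pattern over interim-PMR patients (CMR, PMR, PMR, PMR, PMD, PMD, recycled)
makes a 14 + 6 cohort land at 15 CMR / 3 PMR / 2 PMD at end of treatment.

What passing tests on this phantom *show*: the pipeline recovers known
lesion ADC to within 2% and volume to within 10% under realistic noise and
contrast; masks nest; features are deterministic; the statistics are
calibrated; cohort-level effect directions (complete responders show
larger baseline-to-interim increases in masked ADC spread and upper tail
than partial responders, evaluated at the 40% threshold where lesion
signal is least organ-diluted) are reproduced in ≥ 80% of replicates.

What they *do not* show: performance on real anatomy. The phantom has no
motion or distortion artifacts, no station-boundary intensity steps, no
inter-timepoint misregistration, constant per-region s0, and organ
geometry far simpler than a patient's. In particular, at the 5% threshold
the phantom's masked ADC 95th percentile is dominated by the kidney
template, so low-threshold upper-tail effects visible in patient data have
no phantom counterpart — a deliberate consequence of keeping confounders
in the mask.

## 6. Problem sizes and numerical choices

* Full-scale (2M-voxel) grids are used where spatial fidelity is the
  point: the 20-seed recovery checks and the noiseless ADC inversion
  (exact to 10⁻⁶ relative). Cohort-level end-to-end runs (feature
  plumbing, comparison wiring, byte-level determinism) use reduced grids —
  20 × 20 × 30 voxels at 8 × 8 × 12 mm — since none of those properties
  depend on grid size; this keeps a 20-patient, 3-timepoint, 120-volume
  simulation in seconds.
* All randomness flows from explicit integer seeds; the same seed gives
  bit-identical volumes, features and reports. Per-timepoint seeds are
  offset from the patient seed so noise realisations differ across visits.
* Lesions take precedence over organs on overlap (with a warning); this is
  the only overlap rule.
* CSV artifacts are written at full precision; determinism is asserted at
  the byte level, not "approximately equal".

## 7. Known limitations

* The threshold-reference rule and entropy binning of proprietary vendor
  implementations are unrecoverable; both are explicit configuration here,
  with the defaults above. Absolute feature values from other tools are
  not expected to match; *changes* and group contrasts are the robust
  quantities.
* Orientation-flipping per feature means reported sensitivities refer to
  the reported orientation — with 3-patient positive classes, a single
  reclassified patient moves sensitivity by 33 points, so small-cohort
  ROC rows should be read with their group sizes in view.
* No survival analysis, cutoff cross-validation, or AUC confidence
  intervals; no DICOM ingestion, station stitching, registration or
  bias-field correction (volumes must arrive stitched and co-registered
  per patient/timepoint).
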
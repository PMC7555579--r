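# wbdwi

Fully automatic analysis of longitudinal whole-body diffusion-weighted MRI
(WB-DWI) for predicting and assessing chemotherapy response in Hodgkin's
lymphoma.

## The problem

Lymphoma response assessment leans on PET/CT, which carries an ionizing
radiation dose at every visit. WB-DWI is a radiation-free functional
alternative: lymphoma lesions are hypercellular, so water diffusion in them
is restricted — they appear bright on high-b-value images and dark on the
apparent diffusion coefficient (ADC) map. A fully automatic "total tumor
load" analysis skips expert mask editing entirely: it thresholds the
high-b-value image, accepts that normally hyperintense organs (brain,
kidneys, spleen, chemo-activated bone marrow) stay inside the mask, and asks
whether the resulting volume and ADC histogram features still discriminate
complete from partial responders.

This package implements that pipeline end to end, plus a synthetic
whole-body phantom cohort generator to validate every stage against known
ground truth.

## The method

Per patient and timepoint T ∈ {0 = baseline, 1 = interim, 2 = end of
treatment (EOT)}, from co-registered b = 50 and b = 800 s/mm² volumes:

1. **ADC map** (mono-exponential):
   `ADC = ln(S_50 / S_800) / (800 − 50)`, reported in ×10⁻⁶ mm²/s.
2. **Segmentation**: voxels with b800 intensity ≥ th% of a per-volume robust
   maximum, at th ∈ {5, 10, 20, 40, 60, 80} — no mask editing of any kind.
3. **Features** `f^T_th%`: diffusion volume DV (cm³) plus eight first-order
   ADC statistics over the mask (mean, sd, median, 5th/95th percentile,
   skewness, excess kurtosis, Shannon entropy).
4. **Percentage changes**: `Δf^{0T} = 100·(f^T − f^0)/f^0` and
   `Δf^{12} = 100·(f^2 − f^1)/f^1`.
5. **Statistics** for CMR-vs-PMR (Lugano labels are inputs, from PET
   reading): Lilliefors normality gate → Welch t or Mann–Whitney U
   (exact for small tie-free samples), then for significant features an
   ROC with Youden-optimal cutoff, sensitivity, specificity, accuracy.

## Worked example

```r
library(wbdwi)

# simulate a 20-patient longitudinal cohort (14 interim-CMR / 6 interim-PMR)
ch  <- make_cohort(n_cmr = 14, n_pmr = 6, out_dir = "sim", seed = 1,
                   dim = c(20, 20, 30), spacing = c(8, 8, 12), noise_sigma = 4)
rep <- run_pipeline(ch$manifest, data_dir = "sim", out_dir = "report")
print(rep)
```

```
<analysis_report>
  features: 3240 records (20 patients x timepoints x 6 thresholds)
  deltas:   3240 records
  predict_interim: 54 candidates, 0 significant at alpha = 0.05
  predict_eot: 162 candidates, 14 significant at alpha = 0.05
  assess_interim: 108 candidates, 30 significant at alpha = 0.05
  assess_eot: 162 candidates, 28 significant at alpha = 0.05
```

3240 = 20 patients × 3 timepoints × 6 thresholds × 9 features. Each
comparison row carries group medians and IQRs, the test used, p (and
supplementary Benjamini–Hochberg q), and — when significant — AUC, the
optimal cutoff in feature units, sensitivity/specificity/accuracy in
percent and the orientation (whether high or low values flag the poor
responders). `report/` holds the full CSV artifact set plus a `config.yaml`
echo of every analysis setting.

A thin command-line wrapper with subcommands `simulate`, `features`,
`analyze` and `report` is installed at
`system.file("cli", "wbdwi.R", package = "wbdwi")`.

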
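# calfmri

Calibrated dual-echo BOLD/ASL fMRI analysis of visual-evoked oxygen
metabolism, with FLAIR lesion quantification and a resampling framework
for classifying multiple sclerosis (MS) patients versus healthy controls
from single predictors.

The package is for imaging scientists who want a tested, reproducible
implementation of the full chain from raw dual-echo time series to a
ranked table of classifier accuracies — and for methodologists who want
each link of that chain (biophysical model, preprocessing operator,
ROI rule, resampling scheme) exposed as a small, verifiable function.

## The model at the core

The Davis model relates the BOLD signal change to CBF and CMRO₂ changes
through a participant-specific ceiling *M*:

```
ΔBOLD/BOLD₀ = M · (1 − (1 + ΔCBF/CBF₀)^(α−β) · (1 + ΔCMRO₂/CMRO₂|₀)^β)
```

with α = 0.38 and β = 1.3 by default. *M* is estimated from a hypercapnic
gas challenge (CO₂ breathing raises CBF with essentially unchanged
CMRO₂):

```
M = (ΔBOLD_hc/BOLD₀) / (1 − (1 + ΔCBF_hc/CBF₀)^(α−β))
```

Inverting the first equation for ΔCMRO₂/CMRO₂|₀ given measured task
responses yields the visual-evoked oxygen metabolism change (veCMRO₂),
and n = ΔCBF / ΔCMRO₂ is the flow–metabolism coupling ratio. Around this
sit: the dual-echo preprocessing chain (despiking, surround subtraction
of the labelled perfusion echo, BOLD pair averaging, 8 mm smoothing,
0.0039 Hz high-pass, boxcar GLM), the top-percentile overlap ROI rules,
slice-wise FLAIR lesion thresholding (≥ 1.25 SD over the slice mean,
≥ 3 mm³ to count as a distinct lesion, Dice inter-rater agreement), and
per-predictor classification with stratified BCa bootstrap intervals
(B = 10,000), leave-one-out cross-validation, permutation p-values
(5,000 permutations, add-one corrected) and Benjamini–Hochberg
adjustment. Synthetic generators produce every input with known ground
truth. The methods vignette
(`vignettes/calibrated-fmri-pipeline.Rmd`) documents each choice.

## Worked example

```r
library(calfmri)

# Calibrate M from gas-challenge ROI means, then invert the model
m_hat <- estimate_m(bold_0 = 412.0, bold_hc = 423.1,
                    cbf_0 = 14.9, cbf_hc = 36.8)
dm <- compute_delta_cmro2(delta_bold = 0.0118, delta_cbf = 0.9268, m = m_hat)
cat("M =", round(100 * m_hat, 2), "%\n")
cat("veCMRO2 =", round(100 * dm, 2), "%  n =",
    round(compute_n(0.9268, dm), 2), "\n")

# Screen a simulated 10 MS / 13 HC cohort (43 predictors; only the four
# evoked cfMRI measures carry true group effects)
tab <- make_participant_table(seed = 42)
res <- run_full_screen(tab, classification_config(n_boot = 2000,
                                                  n_perm = 999, seed = 7))
head(res[, c("predictor", "within_accuracy", "bca_lcl", "bca_ucl",
             "loocv_accuracy", "perm_p", "bh_p")], 5)
```

prints

```
M = 4.77 %
veCMRO2 = 27.84 %  n = 3.33
          predictor within_accuracy bca_lcl bca_ucl loocv_accuracy perm_p  bh_p
           ve_cmro2            0.91    0.52    1.00           0.91  0.001 0.043
             ve_cbf            0.82    0.59    0.95           0.82  0.007 0.150
        srt_delayed            0.77    0.59    0.95           0.73  0.030 0.430
 peg_9hole_dominant            0.74    0.57    1.00           0.70  0.042 0.452
   sf36_bodily_pain            0.73    0.55    0.91           0.68  0.061 0.525
```

The gas challenge gives this synthetic participant a BOLD ceiling of
4.77%; a +0.92% BOLD / +92.7% CBF visual response then implies a +27.8%
CMRO₂ response with a coupling ratio of 3.3. In the cohort screen, the
two predictors generated with the largest true group separations
(veCMRO₂, veCBF) top the accuracy ranking; veCMRO₂'s BCa interval
excludes chance and it alone survives BH correction, while the
null-generated predictors below produce the chance-level intervals and
large adjusted p-values one would hope for.

The `analysis/` directory holds the numbered workflow over the same
functions — `01_simulate_cohort.R` through `05_classification_screen.R` —
each writing its tables under `results/`.

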
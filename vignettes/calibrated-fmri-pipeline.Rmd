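---
title: "Calibrated dual-echo fMRI: from raw series to MS classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated dual-echo fMRI: from raw series to MS classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfmri)
```

## The model

Task-evoked oxygen metabolism cannot be measured directly with MRI, but it
can be inferred by combining two measurable contrasts. The BOLD signal
reflects deoxyhemoglobin dilution and the arterial-spin-labeling (ASL)
difference signal reflects cerebral blood flow (CBF). The Davis model ties
the two to the cerebral metabolic rate of oxygen (CMRO~2~):

$$\frac{\Delta BOLD}{BOLD_0} \;=\; M\left(1 -
  \left(1+\tfrac{\Delta CBF}{CBF_0}\right)^{\alpha-\beta}
  \left(1+\tfrac{\Delta CMRO_2}{CMRO_2|_0}\right)^{\beta}\right)$$

with $\alpha$ the flow–volume coupling exponent (default 0.38) and $\beta$
a field-strength-dependent susceptibility exponent (default 1.3, the 3 T
convention). All interfaces in this package work with *fractional* changes
(`0.02` = +2%) and keep the ratio form $1+\delta$ internally: written with
ratios the forward model and its inverse,

$$\frac{\Delta CMRO_2}{CMRO_2|_0} =
  \left(1-\frac{\Delta BOLD/BOLD_0}{M}\right)^{1/\beta}
  \left(1+\frac{\Delta CBF}{CBF_0}\right)^{1-\alpha/\beta} - 1,$$

are exactly invertible, which the test suite verifies to $10^{-10}$ over
a thousand random operating points. $M$, the BOLD ceiling that would be
reached on complete washout of resting deoxyhemoglobin, is participant-
specific and is estimated from a hypercapnic gas challenge: breathing 5%
CO~2~ raises CBF strongly while leaving CMRO~2~ essentially unchanged, so
setting the CMRO~2~ term to one solves the model for $M$. The
flow–metabolism coupling ratio is $n = \delta_{CBF}/\delta_{CMRO_2}$.

Two numerical consequences matter in practice. First, the inversion is
undefined once $\delta_{BOLD} \ge M$; voxels violating this ceiling are
skipped with a logged count rather than silently clamped. Second, the
model is non-linear, so CMRO~2~ computed from ROI-mean inputs differs from
the ROI mean of voxelwise CMRO~2~. Voxelwise-then-average is the default
(`averaging_mode = "voxelwise"`); the alternative is one configuration
switch away. For the same reason, group-mean inputs pushed through the
model do not reproduce group means of participant-level CMRO~2~ — a
comparison to keep in mind when relating any single number to a published
group summary.

## From dual-echo series to evoked measures

The acquisition interleaves a perfusion-weighted echo (alternating
magnetically labelled and control volumes) with a BOLD-weighted echo at
TR 4 s. The processing chain implemented in `task_maps()` and
`gas_roi_and_summary()` is:

1. **Spike attenuation.** Anomalous time points are detected against a
   running local reference and replaced by the mean of the nearest clean
   neighbours (`despike()`, threshold `k = 3` robust SDs). Inside the
   pipeline the detection runs on *residuals* after removing the known
   experimental structure — the task boxcar or hypercapnic step and the
   label/control alternation — using per-design-cell medians as the
   reference. Detecting on raw series would flag genuine signal
   transitions whenever the per-volume noise is smaller than the response,
   and the cell-median reference keeps gross corruption of a minority of
   volumes (e.g. the discarded gas transition) from dragging the reference
   of the clean ones. A zero robust scale (locally constant series, e.g. a
   noiseless simulation) skips detection entirely.
2. **Surround subtraction** reconstructs the perfusion-weighted signal at
   every time point by differencing each volume against the mean of its
   two neighbours, signed by label parity; shared linear drifts cancel at
   interior points. **Pairwise averaging** removes the label/control
   ripple from the BOLD echo.
3. **Spatial smoothing** with an 8 mm FWHM separable Gaussian, kernels
   renormalised at volume edges so constants are preserved.
4. **High-pass filtering** at 0.0039 Hz by projecting out low-frequency
   discrete-cosine components and re-adding the series mean. The filter is
   contract-based — anything attenuating below the cutoff by ≥ 90% while
   passing the ~0.0106 Hz task frequency within 5% would do. It is applied
   to the task run only: the gas-challenge quantity of interest is a
   sustained step between two windows, which any such filter would
   attenuate.
5. **Boxcar GLM.** Percent signal change is the task coefficient scaled by
   the voxel's baseline (the intercept), ×100. The regressor is the plain
   boxcar (no hemodynamic convolution, matching the reference analysis)
   passed through *the same* temporal operators as the data it models —
   label/control sampling for the perfusion echo, pair averaging for the
   BOLD echo, then the high-pass filter. This matched filtering is what
   makes the noiseless end-to-end recovery exact at block transitions
   instead of biased by edge smearing.

**ROI rules.** The structural mask is a hand-drawn occipital ROI
intersected with grey matter at ≥ 80% partial volume (inclusive). The task
functional ROI is the overlap of the top 5% BOLD and top 5% CBF
t-statistics within the structural mask, with ties at the quantile
threshold included (deterministic). The gas ROI is the overlap of the top
15% hypercapnic ΔBOLD and ΔCBF maps, escalating to 20% when the overlap is
below `gas_min_voxels`. Baseline signals average the room-air window and
hypercapnic signals the final four minutes, discarding the first two
minutes after gas onset; each window additionally drops one boundary
volume so the three-point temporal operators never mix data across the
transition.

Registration, motion correction and absolute CBF quantification are out of
scope: all inputs must already share one voxel grid (a mismatch is a hard
error), and only relative changes enter the model.

## What the synthetic generators emulate

`make_task_run()` and `make_gas_run()` generate dual-echo series with
known truth: the BOLD echo is a baseline modulated by `delta_bold` during
blocks, and label volumes carry a perfusion deficit modulated by
`delta_cbf`, so the surround-subtracted series recovers the
perfusion-weighted signal exactly. The ASL model is a simple additive
control−label difference — no kinetic modelling — because the pipeline
consumes only relative change. The default task timing is six 60 s
stimulation blocks with rest periods jittered over {32, 34, 36, 38, 40} s;
the run length follows from the drawn jitter sequence (the advertised scan
duration and dynamic count of the reference acquisition are mutually
inconsistent, so the design is taken as primary). The gas run is 4 min of
room air followed by 6 min of hypercapnia, with the hypercapnic BOLD
change derived from `m` through the forward model so that a correct
pipeline recovers `m` identically.

The generator's `snr` is the **contrast-to-noise ratio of the response**:
the task- or gas-induced modulation amplitude of each contrast (BOLD
modulation in the BOLD echo, perfusion modulation in the difference
signal) divided by the white-noise SD of that contrast's series. Defining
noise relative to the response keeps one knob meaningful across the two
echoes, whose raw-signal SNRs differ by orders of magnitude. What this
synthetic world deliberately lacks: physiological noise spectra, motion,
coil inhomogeneity, and spatially varying baselines. One consequence is
worth stating plainly: because the functional ROI is selected from the
same data that are then averaged, any noise that materially perturbs the
voxel *ranking* inflates the selected values (circular selection). At
response-level noise this bias is negligible and the 100-seed mean
recovery of M and veCMRO~2~ is unbiased to well under 2%; under heavy
per-volume noise it is not, and no analysis choice inside this pipeline
would remove it — a caveat that applies to the design itself, not only to
simulations. Recovery tests therefore use spatially uniform truth fields,
for which the ROI composition is selection-invariant and the closed-form
truth is unambiguous.

Test and acceptance problem sizes — 12×12×6 grids at 3.44×3.44×5 mm
voxels, 100 noise seeds for calibration recovery, 200 simulated predictors
for null calibration and power — were chosen so the full suite documents
every claim in a few minutes while keeping every Monte-Carlo band far from
its decision boundary.

## Lesion quantification

FLAIR hyperintensities are flagged slice by slice: a voxel is lesion
candidate when its intensity is ≥ 1.25 SD above its slice mean. Slice
statistics are computed over in-brain voxels only (a zeroed background
would corrupt both moments) with the population SD, and a zero-SD slice
flags nothing; the rule is invariant to per-slice affine rescaling with
positive gain. Distinct lesions are connected components — default
26-connectivity, configurable to 6 or 18 — counted only at ≥ 3 mm³.
Burden is reported absolutely (mm³) and relative to uncorrected
white-matter volume; inter-rater agreement uses the Dice ratio, with
κ > 0.70 conventionally read as excellent (an annotation, never a gate).

A relative threshold has an unavoidable property: on any slice with
Gaussian background noise it flags the upper tail of the background
(~10.6% of voxels at 1.25 SD) no matter how small the noise is. This is
precisely why lesion masks are manually pruned in practice. The phantom
generator (`make_flair_phantom()`) therefore uses a deterministic
background by default, for which recovery of planted lesions is exact;
with `noise_sd > 0` the tests assert detection (every planted lesion
found), not exactness.

## Classification statistics

Every predictor is screened separately for MS/HC discrimination:

- **Outlier rules.** ±2 SD from the group mean before simple group
  comparisons; ±3 MAD (consistency constant 1.4826) from the group median
  before classification modelling. Both are single-pass with statistics
  from the unfiltered values; a zero MAD removes everything off the
  median. Filtering happens once, before resampling.
- **Classifier.** One-predictor logistic regression, decision threshold
  P(MS) = 0.5 with ties to the MS class. Complete separation is detected
  and replaced by the deterministic midpoint-threshold rule: every
  accuracy statistic depends only on the decision boundary, so the
  unbounded MLE adds nothing but numerical grief.
- **Within-sample inference.** B = 10,000 stratified bootstrap resamples
  (within-group resampling preserving each group's n — with 10 patients
  and 13 controls the two shares are 43.5% and 56.5%; the screen always
  stratifies by the actual group sizes and records the proportions). The
  BCa interval takes its bias term from the bootstrap CDF at the observed
  accuracy with ties counted half (accuracy is heavily discrete), its
  acceleration from the leave-one-out jackknife, and its endpoints as
  order statistics of the bootstrap distribution; with zero bias and
  acceleration it reduces to the percentile interval. Significance means
  the interval excludes all values at or below chance (0.50).
- **Out-of-sample inference.** Leave-one-out cross-validation (a
  single-class training fold predicts its class), with significance from
  5,000 label permutations and the add-one correction
  $p = (\#\{acc_{perm} \ge acc_{obs}\} + 1)/(K+1)$. "At least as good" is
  read inclusively (conservative); the strict reading and the raw
  uncorrected proportion are flags away. Benjamini–Hochberg adjustment is
  reported across predictors.

The resampling engine (Newton logistic fits, LOOCV folds, permutation and
bootstrap loops) is compiled code, which is what makes exhaustive
diagnostics — 200 null predictors × 500 permutations × 23 folds —
a few-second affair. All randomness flows from one root seed through
deterministic per-consumer sub-seeds (`derive_seed()`), making every
screen bit-reproducible.

## Known limitations

- The Davis constants are fixed, not fitted; alternative calibrations
  (hyperoxia, gas-free M) are out of scope.
- The evoked pipeline assumes registered inputs and does not model motion
  or slice timing.
- Circular ROI selection biases under low-CNR conditions are documented
  above; they are a property of select-then-average designs generally.
- The lesion threshold rule needs manual false-positive pruning on real
  data; the package accepts rater-edited masks and recomputes all metrics
  (that is how the Dice comparison is meant to be used).
- Single-predictor models only: combining predictors into one diagnostic
  model is deliberately not implemented here.
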
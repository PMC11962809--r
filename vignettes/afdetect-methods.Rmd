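---
title: "Methods: multimodal atrial fibrillation detection in afdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal atrial fibrillation detection in afdetect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`afdetect` is an end-to-end pipeline for detecting atrial fibrillation /
atrial flutter (AF) from short multi-lead ECG recordings. It combines a
compact 1-D convolutional network on the raw signal with two tabular
streams — demographics (age, sex) and eight time-domain heart-rate
variability (HRV) features — and additionally stacks a gradient-boosted
tree classifier on the network's learned embeddings. This vignette
documents the scientific model, the design of the synthetic validation
cohort, the numerical conventions, and the package's known limitations.
None of the code chunks below are evaluated at build time; every claim
about behaviour is enforced by the package's test suite instead.

## 1. Problem setting and modelling assumptions

The unit of analysis is a 10-second, 8-lead ECG record sampled at 500 Hz
(leads I, II, V1–V6; the derived limb leads III, aVR, aVL, aVF are dropped
by `standardise_record()` because they are linear combinations of I and
II). Each record carries a binary label: `AF_positive` (fibrillation or
flutter) versus `negative`, and optionally age (years) and sex.

The package assumes:

* **Record-level labels.** AF is treated as present or absent for the
  whole 10 s strip; paroxysmal episodes shorter than the strip are not
  modelled.
* **Two discriminative signatures.** AF is identified by (a) irregular
  RR intervals, visible both to the HRV features and to the CNN, and
  (b) absence of organised P-waves, visible only to the CNN operating on
  the raw waveform.
* **Class imbalance.** The default operating prevalence is 4.4%, so
  training supports inverse-frequency class weighting and evaluation
  reports sensitivity/specificity with bootstrap confidence intervals
  rather than accuracy.

## 2. The synthetic cohort generator

Because the package must be exercisable without access to clinical data,
`generate_cohort()` synthesises labelled cohorts that reproduce the two
discriminative signatures above while remaining a pure function of a
`synth_config()` (seed included).

### Beat model

Each beat is a sum of Gaussian bumps for the P, Q, R, S and T waves at
fixed offsets from the R apex:

| wave | offset from R (ms) | width σ (ms) | amplitude (mV, lead II) |
|------|-------------------:|-------------:|------------------------:|
| P    | −160 | 25 | 0.15 |
| Q    | −40  | 10 | −0.10 |
| R    | 0    | 12 | 1.00 |
| S    | +40  | 10 | −0.20 |
| T    | +300 | 60 | 0.30 |

Bumps are rendered on a ±3.5 σ support so neighbouring waves do not bleed
into the R apex, and R times are snapped to the sample grid so the stored
ground-truth R indices are exact (this keeps detector-accuracy tests free
of off-grid quantisation slack). The eight leads are scaled copies of one
template (I 0.6, II 1.0, V1 0.5, V2 0.8, V3 0.9, V4 1.0, V5 0.9, V6 0.8).

### Rhythm model

* **Sinus**: per-record mean RR is 60000/HR with HR uniform on 55–95 bpm;
  within-record RR intervals are normal with SD 25 ms, truncated to
  [300, 1800] ms.
* **AF**: RR intervals are drawn independently from a truncated normal on
  [300, 1800] ms with per-record mean uniform on 550–900 ms and SD uniform
  on 90–180 ms; the P amplitude is set to zero and a continuous
  fibrillatory sinusoid (0.05 mV, 4–9 Hz, random phase) is added.

All records receive additive white noise (SD 0.02 mV) and per-lead
baseline wander (amplitude up to 0.1 mV at 0.15–0.4 Hz); both are
switchable off. An optional `corrupt_lead_prob` corrupts individual leads
with 10× noise to exercise the per-lead quality flags. Demographics are
class-correlated: AF ages are N(74, 9) and sinus ages N(60, 14), clipped
to [18, 95] years, with male probability 0.55 versus 0.50.

### What the generator does *not* emulate

The generator is a validation instrument, not a physiological simulator.
It omits, among other things: PQRST morphology variation across leads
(all leads share one scaled template, so inter-lead morphology carries no
information); respiratory sinus arrhythmia and autocorrelated RR dynamics
(sinus RR is i.i.d. around its mean, AF RR is i.i.d. truncated normal
rather than a point process with refractoriness); ectopic beats, bundle
branch blocks, flutter's organised sawtooth (flutter is folded into the
AF class); muscle-artifact and electrode-motion noise (only white noise
and sinusoidal wander); and any age/sex effect on the waveform itself
(demographics influence only the label distribution). Consequences of
these simplifications are discussed under Limitations.

## 3. Preprocessing and beat detection

`standardise_record()` maps any 8- or 12-lead input to the canonical
8-lead order. `wavelet_denoise()` performs a soft-threshold wavelet
shrinkage with the threshold estimated from the finest detail scale
(median-absolute-deviation noise estimate with the universal threshold);
it is close to idempotent and never increases signal energy.
`detect_r_peaks()` is a Pan–Tompkins-style detector: band-pass filtering,
squared derivative, moving-window integration, adaptive thresholding and
a refractory period of 0.2 s · fs samples. Leads whose detected rate or
signal statistics are implausible are flagged `unreliable` and excluded
downstream.

## 4. HRV features and numerical conventions

`extract_hrv()` computes heart rate per reliable lead, selects the lead
holding the **median** heart rate (lower middle for an even count; exact
ties resolve to canonical lead order, I first), filters its RR series to
NN intervals, and computes the 8-feature vector: heart rate, mean IBI,
SDNN, SDSD, RMSSD, pNN20, pNN50 and HR MAD.

Conventions chosen and fixed by tests:

* **Population (1/N) standard deviations** by default
  (`sd_mode = "population"`), under which the identity
  `rmssd² = sdsd² + mean(Δ)²` holds exactly; `"sample"` is available.
* **Strict inequalities** for pNN20/pNN50 (`|Δ| > 20 ms`, `> 50 ms`),
  expressed in percent.
* **HR MAD** defaults to the median absolute deviation of the NN
  intervals around their median (`"median_nn"`); mean-based variants are
  selectable.
* **NN filtering** (`filter_nn_intervals()`): intervals outside
  [300, 2000] ms are dropped, and once 5 intervals have been accepted any
  interval deviating more than 30% from the running median of the last 5
  accepted is dropped. Fewer than 3 survivors marks the series invalid.

The 30% running-median rule is standard practice for rejecting missed or
false beats, but on genuinely erratic AF rhythms it also trims real
extreme intervals. This biases the pipeline SDNN of AF records downward
relative to the generator's ground-truth RR SD — an expected, documented
property of NN filtering, not a detector failure. The package therefore
validates SDNN recovery on AF records by the **median over records of the
per-record relative error** (robust to the minority of heavily-trimmed
records), alongside the AF/sinus SDNN separation, rather than demanding
unbiased recovery record by record.

## 5. Network backbones, fusion and training

Three 1-D CNN trunks are registered (`lenet1d`, `alexnet1d`, `vgg1d`),
all ending in a 64-dimensional dense embedding and a single-logit head.
`width_multiplier` scales every channel count (floored at 4); the default
0.25 targets single-CPU training on cohorts of a few thousand records —
the problem sizes used throughout the package (n in the hundreds to low
thousands, 6 epochs) are **package-scale choices for CPU tractability**,
not claims about the sizes needed for clinically meaningful training.

Multimodal fusion (`build_multimodal()`) passes the tabular vector
(age, sex, and/or the 8 HRV features, z-scored with a scaler fitted on
training rows only) through a small two-layer MLP and concatenates its
output with the CNN embedding before the head.

Training (`train_network()`) is minibatch Adam on weighted binary
cross-entropy. Class weights follow the balanced scheme
`w_c = n / (2 · n_c)`, so the weighted positive mass equals the weighted
negative mass. The learning-rate schedule and early stopping live in a
pure helper, `plateau_step()`: a validation-loss improvement must exceed
1e-9 to count; `lr_patience` consecutive stalls halve the learning rate;
`early_stop_patience` stalls stop training and the best-validation
weights are restored. The helper is pure precisely so the schedule's
arithmetic is unit-testable without constructing a real plateau, which
Adam's gradient normalisation makes practically impossible at any
non-zero learning rate.

Splitting (`split_dataset()`) is stratified by class into a held-out test
set plus cross-validation folds over the remainder; the first fold serves
as the validation set for early stopping. A leakage guard errors if test
indices reach a training routine.

## 6. Stacking, evaluation and interpretation

`extract_embeddings()` runs a deterministic inference pass and returns
the 64-d embedding per record. `fit_boosted_classifier()` trains an
XGBoost binary classifier with early stopping; hyperparameters come from
a seeded random search, or from fixed defaults when `search_budget = 0`.
The defaults keep `subsample = 1` and `colsample_bytree = 1`: on
low-dimensional feature tables, column subsampling below 1 can hide a
feature from entire trees and make interaction-only signals unlearnable.
`evaluate_modalities()` compares feature sets (embedding alone, +demo,
+HRV, +both) on identical held-out test rows.

`confusion_metrics()` reports sensitivity, specificity, PPV, NPV and F
score; `auroc()` is the rank-statistic (Mann–Whitney) estimator with the
tie-aware midrank correction, tested to agree exactly with brute-force
pairwise concordance. `bootstrap_ci()` gives seeded percentile intervals
over test-set resamples. `saliency()` returns |∂logit/∂input| gradient
maps normalised to [0, 1], which on synthetic AF records concentrate away
from the (absent) P-wave window relative to sinus records.

## 7. Reproducibility

Every stochastic step is seeded from explicit configuration:
`generate_cohort()` is a pure function of its config, training consumes
the caller's RNG state plus a `split_seed`, and `run_experiment()` drives
the whole grid from one master seed, writing per-cell reports and a
top-level `summary.json` that reproduces bit-for-bit when the identical
configuration is re-run into a fresh directory. Completed cells are
skipped on re-run, so interrupted grids resume.

## 8. Limitations

* The synthetic generator's simplifications (Section 2) mean the CNN can
  exploit cues — e.g. the fibrillatory sinusoid's fixed amplitude — that
  have no clinical counterpart; performance numbers on synthetic cohorts
  validate the *pipeline machinery*, not clinical accuracy.
* Only time-domain HRV features are implemented; frequency-domain and
  nonlinear indices are out of scope.
* The WFDB reader/writer supports format 16 only, targeting
  PhysioNet-style archives, and quantises to the stated ADC gain.
* Training is single-threaded, pure R/C++ without GPU support; the
  backbones are deliberately small.
* Bootstrap CIs resample the test set only; they do not capture
  training-seed variance, which the package instead addresses by
  multi-seed direction checks in its acceptance tests.
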
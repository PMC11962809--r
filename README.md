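# afdetect

Multimodal detection of atrial fibrillation / atrial flutter (AF) from
short multi-lead ECG recordings, in pure R with a small C++ core.

## The problem

AF is the most common sustained arrhythmia and is frequently silent; its
electrocardiographic signature on a 10-second strip is twofold —
irregularly irregular RR intervals and absence of organised P-waves.
`afdetect` implements an end-to-end, fully reproducible pipeline that

- learns from the raw 8-lead signal with compact 1-D convolutional
  backbones (`lenet1d`, `alexnet1d`, `vgg1d`),
- fuses the learned signal embedding with tabular streams: demographics
  (age, sex) and an 8-feature time-domain heart-rate-variability (HRV)
  vector (heart rate, mean IBI, SDNN, SDSD, RMSSD, pNN20, pNN50, HR MAD),
- optionally stacks a gradient-boosted tree classifier (XGBoost) on the
  frozen CNN embeddings,
- handles class imbalance with balanced class weighting
  (`w_c = n / (2 n_c)`) and reports sensitivity, specificity, PPV, NPV,
  F-score and AUROC with seeded bootstrap confidence intervals,
- explains predictions with gradient saliency maps over the input signal.

Formally: given a record `x ∈ R^{8×5000}` (10 s at 500 Hz) with tabular
covariates `z`, the network computes an embedding `e = f_θ(x) ∈ R^64`,
fuses `h = [e; g_φ(z)]`, and outputs `P(AF | x, z) = σ(w·h + b)`; training
minimises class-weighted binary cross-entropy with Adam under a
plateau-halving learning-rate schedule and early stopping. The stacked
model replaces the linear head with boosted trees on `[e; z]`.

Because clinical waveforms cannot ship with the package, a synthetic
cohort generator (`generate_cohort()`) produces labelled 8-lead records
that reproduce both AF signatures (truncated-normal irregular RR,
suppressed P-wave plus fibrillatory oscillation) with class-correlated
demographics, exact ground-truth R-peak indices, and bit-reproducibility
from a single seed. See `vignette("afdetect-methods")` for the model,
conventions and limitations.

## Worked example

```r
library(afdetect)

# 300-record cohort, 15% AF prevalence, deterministic from the seed
cohort <- generate_cohort(synth_config(n_records = 300, prevalence = 0.15,
                                       seed = 42))
rec <- cohort$records[[1]]
rec

# HRV features from the pipeline: denoise -> R peaks -> median-HR lead ->
# NN filter -> 8 features
extract_hrv(rec)

# train a small CNN on ECG + demographics + HRV and evaluate held out
hrv <- hrv_feature_table(cohort$records)
tm <- train_model(cohort$records, backbone_spec("lenet1d"),
                  train_config("ecg_demo_hrv", use_class_weights = TRUE,
                               epochs = 4, split_seed = 42),
                  hrv_table = hrv)
idx <- tm$split$test_idx
p <- predict_bundle(tm$bundle, tm$data, idx)
metrics_report(tm$data$y[idx], p, threshold = tm$bundle$threshold,
               n_boot = 200, ci_seed = 42,
               model_tag = "lenet1d", modality_tag = "ecg_demo_hrv")
```

Output of the session above (deterministic given the seeds; the synthetic
task at this size is fully separable, hence the saturated metrics — see
the vignette's limitations section):

```
<ecg_record syn00001: 8 leads x 5000 samples @ 500 Hz, label=negative, age=54.22191, sex=female>
<hrv_features: lead I, 12 beats>
  heart_rate   76.125 bpm
  ibi         788.182 ms
  sdnn         26.893 ms
  sdsd         30.500 ms
  rmssd        30.816 ms
  pnn20        60.000 %
  pnn50        10.000 %
  hr_mad       24.000 ms
<metrics_report: lenet1d / ecg_demo_hrv / synthetic>
  test set: 9 positive, 51 negative (threshold 0.50)
  sensitivity  1.0000  [1.0000, 1.0000]
  specificity  1.0000  [1.0000, 1.0000]
  ppv          1.0000  [1.0000, 1.0000]
  npv          1.0000  [1.0000, 1.0000]
  f_score      1.0000  [1.0000, 1.0000]
  auroc        1.0000  [1.0000, 1.0000]
```

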
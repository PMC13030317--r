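# femgxdyn

Facial-EMG expression dynamics: simulation, spatio-temporal classification,
and workload association — in one reproducible R pipeline.

## The problem

Surface facial electromyography (fEMG) from a 7-channel VR face-mask
(corrugator, left/right frontalis, orbicularis, and zygomaticus) records a
rectified amplitude signal at 1000 Hz. From a short calibration session in
which a wearer holds maximal expressions (smile, frown, raised eyebrow,
interleaved neutral), a shared classifier can be trained to label short
signal windows with one of four expression classes and then applied to
unlabeled task recordings, turning raw muscle amplitude into a continuous
categorical *expression sequence* per scene. Summaries of those sequences —
occupancy ratios, burst run-lengths, transition matrices, entropy, latency —
can then be related to self-reported workload (NASA-TLX, 0–10 scale) with
mixed-effects models under FDR control.

Human fEMG of this kind cannot generally be shared, so `femgxdyn` pairs the
analysis chain with a seeded synthetic cohort generator that reproduces the
statistical structure the pipeline assumes (participant-specific resting
tone and MVIC, FACS-consistent burst activation, scene-dependent expression
prevalence, ratings from a known linear mixed model), giving every stage a
ground truth to be validated against.

## The core methods

- **Two-stage normalization.** Per channel,
  `x' = (x − neutral_baseline) / (MVIC − neutral_baseline)`, with the
  neutral baseline the median over neutral calibration blocks and MVIC the
  95th percentile over maximal-expression blocks; resting tone maps to ≈ 0
  and maximal contraction to ≈ 1.
- **Windowing.** Zero-overlap fixed-length windows (default 1 s); a segment
  of `T` samples yields `floor((T − w)/s) + 1` complete windows.
- **CNN–TCN classifier.** A CNN block (1-D convolutions over the 7 channels,
  batch-norm, ReLU, max-pooling) feeding a TCN block (residual dilated
  causal convolutions, dilations 1/2/4) and a fully connected softmax head;
  trained with class-weighted cross-entropy, Adam, and early stopping on
  validation weighted F1. CNN, TCN, LSTM, CNN-LSTM, and GRU baselines share
  the same contract. Evaluation is leave-one-participant-out (LOPO): every
  participant is the test set exactly once, with participant-disjoint
  validation splits.
- **Expression features.** 81 named descriptors per participant × scene
  sequence (ratios, counts, neutral→X transitions, burst statistics,
  entropy, switches/persistence, dominance/Gini, latency, full 4×4
  transition counts and probabilities).
- **Workload statistics.** Features are z-scored (population SD), reduced
  with PCA (population covariance, sign-fixed loadings), and related to
  NASA-TLX subscales via
  `rating ~ feature + scene + feature:scene + (1 | participant)` fit by
  REML with Powell's derivative-free BOBYQA optimizer; p-values receive
  Benjamini–Hochberg FDR adjustment.

## Worked example

```r
library(femgxdyn)

cfg <- synthetic_config(n_participants = 12, sample_rate = 50,
                        scene_duration = 60, baseline_duration = 120,
                        calibration_hold = 4, calibration_reps = 2,
                        snr = 30, seed = 42)
cohort <- generate_cohort(cfg)
wp <- windowing_params(50)          # 1-s windows at 50 Hz

windows <- list()
for (p in names(cohort$calibration)) {
  prof <- compute_calibration_profile(cohort$calibration[[p]])
  norm <- normalize_recording(cohort$calibration[[p]], prof)
  windows <- c(windows, segment_windows(norm, wp))
}

lopo <- lopo_cross_validate(windows, expression_model(seed = 42))
print(lopo)
```

```
LOPO cross-validation over 12 participants
  test accuracy     1.0000 +/- 0.0000
  test macro_f1     1.0000 +/- 0.0000
  test weighted_f1  1.0000 +/- 0.0000
  test roc_auc      1.0000 +/- 0.0000
```

At this signal-to-noise ratio the four calibration expressions are fully
separable, so every held-out participant classifies perfectly; lowering
`snr` degrades the metrics smoothly. Applying the retrained model to the
scene recordings and summarizing the predicted sequences recovers the
scene structure the generator plants — suppressed expressiveness under
cognitive demand, elevated smiling under physical/dual demand:

```r
model <- retrain_full(windows, expression_model(seed = 42))
seqs <- list()
for (p in names(cohort$recordings)) {
  prof <- compute_calibration_profile(cohort$calibration[[p]])
  for (sc in names(cohort$recordings[[p]])) {
    nrec <- normalize_recording(cohort$recordings[[p]][[sc]], prof)
    seqs[[paste(p, sc)]] <- predict_sequence(model, nrec, wp)
  }
}
tab <- cohort_scene_table(baseline_corrected(scene_summary(seqs)))
tab$scene_means[, c("scene", "mean_delta_non_neutral")]
```

```
      scene mean_delta_non_neutral
   baseline                 0.0000
  emotional                 0.0208
  cognitive                -0.0250
   physical                 0.0944
       dual                 0.1181
```

The whole chain (plus feature extraction, PCA, and mixed models) can also
be run in one call via `run_pipeline(pipeline_config(...))`, or from a
shell through the thin wrapper `inst/cli/femg-xdyn.R`.

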
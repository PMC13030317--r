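---
title: "Modeling facial-EMG expression dynamics with femgxdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling facial-EMG expression dynamics with femgxdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`femgxdyn` implements a complete analysis chain for multi-channel facial
electromyography (fEMG) amplitude recordings: physiological normalization,
windowed expression classification with a CNN–TCN network, inference of
continuous expression sequences over task scenes, an 81-feature taxonomy of
categorical expression dynamics, and mixed-effects association of those
features with workload ratings. Because real recordings of this kind are
rarely shareable, the package also contains a first-class synthetic cohort
generator; every downstream stage is validated against the generator's
ground truth. This vignette explains the models, the tunable parameters,
and the design decisions — in particular where a choice was genuinely open.

## 1. Signal model and the synthetic cohort generator

The generator emulates what a dry-electrode fEMG mask exports: a
rectified, filtered **amplitude** signal per channel, not raw oscillatory
EMG. Seven channels are modeled in a fixed order (a single central
corrugator channel, then left/right frontalis, orbicularis, and
zygomaticus). Each participant has

- a per-channel resting tone (uniform on `baseline_tone_range`, default
  0.05–0.3 amplitude units), and
- a per-channel maximal-contraction amplitude (MVIC; uniform on
  `mvic_range`, default 0.8–2.0), constrained to lie strictly above the
  tone range.

Expression activity is a **two-state renewal process** at window
granularity: a neutral background is interrupted by bursts. While neutral,
a burst starts in a step with probability `1 − exp(−r·dt/60)` where `r` is
the scene's total burst rate per minute; the burst class follows the
scene's rate mixture and its duration is uniform on `burst_duration_range`
(default 1–4 s). The default scene rates plant the qualitative pattern the
pipeline is meant to recover: non-neutral occupancy ordered
cognitive < baseline ≈ emotional < physical ≈ dual, with physical/dual
bursts predominantly smiles and emotional bursts enriched in raised
eyebrows. No quantitative description of spontaneous burst rates was
available to copy, so these defaults are free choices fixed once; they are
rates a physiologist would call plausible for spontaneous facial activity
(a few bursts per minute at rest, several under engaging load), not
estimates of any dataset.

Bursts are rendered on the channels whose muscle group the expression
involves, following the FACS mapping: smile → orbicularis + zygomaticus,
frown → frontalis + corrugator, raised eyebrow → frontalis, neutral →
none. The burst envelope is a **raised-cosine (Hann)** rise-and-fall
peaking at a per-burst uniform fraction (`burst_peak_range`, default
0.6–0.95) of the channel's MVIC-minus-tone span: the smoothest
minimal-parameter shape consistent with transient activations that rise
and return to baseline. Calibration blocks instead use a **trapezoidal**
envelope (10% ramps) whose plateau reaches the channel MVIC — a held
maximal contraction is a plateau, not a peak, and the plateau is what makes
the 95th-percentile MVIC estimator consistent. Additive zero-mean Gaussian
noise has SD `(MVIC − tone)/snr` per channel, and amplitudes are rectified
at zero. An optional `crosstalk` coefficient mixes a fraction of the mean
activation into every channel (off by default; used for robustness
experiments only).

What the generator deliberately does **not** emulate: motor-unit level EMG
physics, movement/breathing artifacts, electrode drift or detachment,
asymmetric left/right activation, and co-activation outside the FACS map.
A classifier score of 1.0 on high-SNR synthetic cohorts therefore
demonstrates that the pipeline is *correct*, not that real data are this
separable; the headline numbers from the suite should be read as upper
bounds under idealized signals.

Workload ratings are generated from a linear mixed model per subscale
(8 subscales, 0–10 scale):
`rating = intercept + scene effect + participant intercept +
Σ β·z(feature) + noise`, truncated to [0, 10]. Defaults (intercept 4,
scene effects ≤ 2, random-intercept SD 1, noise SD 1) keep the truncation
probability well below 1%, which matters because truncation would bias the
parameter-recovery checks. Only six subscale names are standard; the
8-subscale variant here adds `emotional` and `overall`, and all names are
configurable.

## 2. Normalization and windowing

Normalization is the two-stage map
`x' = (x − neutral_baseline)/(MVIC − neutral_baseline)` per channel. The
neutral baseline is the **median** over neutral calibration blocks (robust
to transients — a mean would be pulled up by spontaneous bursts); MVIC is
the **95th percentile** over all maximal-expression blocks pooled (robust
to single-sample spikes, and consistent because every channel's involved
expressions hold a plateau for well over 5% of the pooled samples).
Normalized values are *not* clipped: spontaneous activity may legitimately
exceed calibration MVIC. A channel with `MVIC − baseline ≤ 1e-6` is a hard
error — such a channel carries no usable dynamic range. Neutral correction
is applied per session (per-block correction would absorb real tonic scene
effects). The transform is affine and invertible; `denormalize_recording()`
is the exact inverse.

Windowing uses 0-based half-open sample intervals. The window length is
1 s by default (1000 samples at the native 1000 Hz); the stride defaults to
the window length (zero overlap), both configurable in ms. Only complete
windows are retained — a segment of `T` samples yields
`floor((T − w)/s) + 1` windows, zero when `T < w` — and windows never cross
segment boundaries, so a labeled window is always label-pure. The same
discard rule applies at inference; no padding is invented at scene edges.

## 3. The classifier

The CNN–TCN network maps a `(w × 7)` normalized window to 4 class
probabilities:

- **CNN block** — two stages of 1-D convolution along time over all
  channels (kernel 5; 32 then 64 filters), batch normalization, ReLU, and
  max-pooling by 2. This captures inter-channel activation patterns at
  short time scales.
- **TCN block** — three residual blocks of two dilated causal convolutions
  each (kernel 3, 64 filters, dilations 1/2/4, dropout 0.2), giving a
  receptive field of `1 + 2·(k−1)·Σd` = 29 pooled samples with the
  defaults.
- **FC block** — global average pooling over time, a 64-unit hidden layer,
  and a 4-way softmax.

These widths are the smallest standard stack that realizes the
CNN/TCN/FC structure at desk scale; every hyperparameter is overridable
through `expression_model()`. Training minimizes class-weighted
cross-entropy (inverse-frequency weights — calibration sessions are
roughly half neutral, and weighting preserves temporal data density where
resampling would not), with Adam (lr 1e-3, batch 64), early stopping on
validation weighted F1 (patience 10), and restoration of the best-epoch
weights. Initialization, shuffling, and dropout all derive from the config
seed, so training is bit-reproducible at a fixed thread count. The engine
is written directly on base-R BLAS matrix operations with
finite-difference-verified gradients for every layer type, including the
LSTM/GRU recurrences used by the baseline architectures (`cnn`, `tcn`,
`lstm`, `cnn-lstm`, `gru`), which share the identical training and
evaluation contract.

Ties in the probability argmax resolve to the earlier class in the fixed
order neutral < smile < frown < raised_eyebrow. Evaluation reports
accuracy, macro and frequency-weighted precision/recall/F1, a
row-normalized confusion matrix, and macro one-vs-rest ROC-AUC via the
rank formula; the precision of a never-predicted class is defined as 0,
macro averages run over classes present in the truth (with a warning when
any class is absent), and per-class AUCs undefined for absent classes are
excluded from the macro average.

Cross-validation is leave-one-participant-out: each participant is the
test set exactly once, and the within-fold validation subset is 2 held-out
*participants* (rotating with the fold index), never a random window
split — windows of one participant are strongly dependent, and a window
split would leak identity information into early stopping. After
cross-validation the final shared model is retrained on all calibration
windows, with a 10% random window holdout retained only for early stopping
and reporting (at that point participant-level generalization has already
been measured).

## 4. Expression sequences and the 81-feature taxonomy

The final model, applied with the training windowing to a normalized scene
recording, yields one label per window — the expression sequence. No
temporal smoothing is applied: the downstream features depend on the raw
transition structure, and a majority filter would destroy exactly the
switch/burst statistics of interest.

Each participant × scene sequence maps to 81 named scalars: 4 occupancy
ratios; 4 class counts plus the total frame count; 3 neutral→X transition
counts; 3 non-neutral average burst lengths; Shannon entropy (bits) and
its normalized form; switches, switch rate, and persistence (global mean
run length `T/#runs`); dominance and a Gini-like inequality over the three
non-neutral proportions; 3 latency indices; the full 4×4 transition count
and row-normalized probability matrices; and 6 run-length descriptors
(count, mean, median, min, max, population SD) for each of the 4 classes.
The published per-category counts for this taxonomy sum to 61 while its
stated total is 81; the package resolves the discrepancy by expanding the
burst-statistics category to 6 descriptors × 4 classes = 24, the unique
natural reading that reaches 81 and matches the prose naming of frown
burst mean/median/max/count. Conventions for degenerate inputs are fixed
and documented: descriptors of a class that never occurs are 0;
dominance/Gini are 0 for an all-neutral sequence; the latency sentinel is
1.0; probability rows of never-visited source states stay all-zero rather
than being filled uniformly (inventing transition mass would bias the
features); run-length SD uses the population convention with single-run
classes at 0. Every feature is checked against an independent brute-force
implementation, exhaustively over all 4^6 sequences of length 6.

## 5. Workload statistics

Features are z-scored per column across participant × scene rows using the
population SD; zero-variance columns are dropped and logged. PCA runs on
the population covariance of the standardized columns (equivalently the
correlation matrix), with each component's sign fixed so its
largest-magnitude loading is positive — a pure reporting convention that
makes loadings reproducible. Observations are participant × scene rows
(matching the mixed-model row structure), not participant aggregates.

For every (feature, subscale) pair the package fits
`rating ~ feature + scene + feature:scene + (1 | participant)` by REML
using lme4 with the BOBYQA optimizer — Powell's derivative-free
quadratic-approximation method — and Satterthwaite p-values via lmerTest.
Betas are in rating units per SD of the feature. Singular random-effect
fits are flagged, never silently dropped; rows with missing ratings are
dropped listwise per model and counted. The FDR family is, by default, all
feature main effects and feature × scene interactions across every
(feature, subscale) pair jointly (`fdr_family = "all"`); a per-subscale
family is available, since which family the 8-subscale correction should
span is genuinely ambiguous. Benjamini–Hochberg adjustment comes from
`stats::p.adjust`, cross-checked in the tests against a hand-rolled
step-up oracle.

The statistical stage is validated by simulation: a planted
β = −1 (smile-occupancy feature → physical-demand subscale) must be
recovered without material bias and with ~95% CI coverage over repeated
cohorts of 100 participants, and null cohorts must produce a nominal
p < 0.05 rate. Under the null, feature tables are reused across rating
redraws (ratings are then independent of features, so conditioning on a
fixed design is valid and much cheaper).

## 6. Pipeline, determinism, and problem sizes

`run_pipeline()` executes simulate → preprocess → train → infer →
features → stats, writing per-stage CSVs and a JSON manifest with a config
hash and an MD5 checksum of every output; identical config + seed
reproduce identical checksums. One global seed fans out to per-stage,
per-participant sub-seeds through a small polynomial hash
(`derive_seed()`), so any stage can be rerun in isolation. A thin Rscript
front end (`inst/cli/femg-xdyn.R`) exposes the same calls from a shell
with a YAML config.

The package defaults describe the full-scale acquisition protocol
(1000 Hz, 120 s stressor scenes, 300 s baseline, 12 participants). The
test-suite and acceptance-script fixtures keep all scientific parameters
(burst rates and mixtures, SNR, FACS map, planted effects, cohort size)
and scale only the signal size — 50 Hz sampling, 60 s scenes, 120 s
baseline, 4 s calibration holds — which leaves window counts per class in
the hundreds and makes the full chain run in minutes on one CPU. The
permutation-null check uses the standard design: the label vector is
permuted once, the usual split is applied, and the model is scored against
the permuted labels on a class-balanced validation subset; permuting
training labels alone degenerates at high SNR into an arbitrary assignment
of the four block types, whose macro-F1 distribution is too coarse to
estimate a chance level from a few repetitions.

## 7. Known limitations

- The network engine is plain R; it is deterministic and fast enough for
  desk-scale cohorts, but it is not a GPU framework and does not aim to be.
- Synthetic separability at high SNR is near-perfect, so classification
  metrics on the synthetic cohort say nothing about accuracy on real
  signals — only about pipeline correctness; real fEMG will add artifact
  regimes the generator does not model.
- The latency-after-neutral definition and the FDR-family choice are
  documented conventions among several defensible readings; both are
  configurable where reasonable.
- Expression sequences are categorical; continuous expression intensities
  and frequency-domain EMG features are out of scope.
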
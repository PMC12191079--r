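---
title: "Attention-driven dynamic graph convolution for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-driven dynamic graph convolution for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegatt)
```

## The problem

Emotion-related information in multi-channel EEG is spread unevenly over
electrodes and frequency bands, and its spatial organization differs from
subject to subject. `eegatt` implements a complete pipeline for this
setting: band-wise feature extraction from raw recordings, a graph
neural network over the electrode set whose adjacency is *learned from
the data* rather than fixed by cap geometry, global attention pooling
that scores each electrode's importance, and adversarial domain
adaptation that discourages subject-specific representations. Everything
is exercisable on a bundled synthetic generator, so no access-controlled
EEG corpus is needed to test any stage.

## Feature families

For each 1 s segment, electrode and band $b$ (defaults
$\delta$ 1–4, $\theta$ 4–8, $\alpha$ 8–14, $\beta$ 14–31, $\gamma$ 31–50 Hz):

* **DE** — differential entropy under a Gaussian model,
  $\tfrac12\log(2\pi e\,\sigma^2_b)$, with $\sigma^2_b$ the variance of the
  zero-phase band-filtered segment. On the 62-channel cap: 62 values/band.
* **PSD** — band power, the Hann-windowed periodogram integrated over the
  band (rectangle rule), in $\mu V^2$. 62 values/band.
* **DASM / RASM** — difference / ratio of a per-electrode feature between
  the 27 left–right homologous pairs.
* **DCAU** — difference between the 23 frontal–posterior pairs. Despite
  the "causality" in the historical name, no causal estimator is
  involved: it is the standard differential frontal–caudal convention.

The mirror pairs are derived from 10–20 label parity (odd suffix = left);
the caudal pairing cannot be derived from names and ships as an editable
CSV resource (`inst/extdata/esi62.csv`) following the common convention
for this cap in the affective-EEG literature. The pair *counts* (27, 27,
23) are the verifiable contract; the exact caudal list is a documented
assumption, not something the method's description fixes.

## The model

The input is a tensor $X \in \mathbb{R}^{B\times E\times F}$ (batch,
electrodes, bands). Each attention-convolution layer computes

$$H = XW,\qquad
A_{att} = \mathrm{softmax}(H A H^\top,\ \mathrm{dim}=-1),\qquad
A_{att} \leftarrow \tfrac12 (A_{att}+A_{att}^\top),\qquad
Z = A_{att} H,$$

with $W \in \mathbb{R}^{F\times F'}$ a projection and
$A \in \mathbb{R}^{F'\times F'}$ a trainable bilinear attention kernel.
The softmax runs over the electrode axis (row-stochastic before
symmetrization), stabilized by max subtraction; after symmetrization the
adjacency is exactly symmetric with total entry sum $E$. One layer costs
$O(B\,E^2 F')$ — `attention_layer_flops()` counts exactly the two
quadratic stages, so the counter quadruples when $E$ doubles.

Global attention pooling scores each node, $\omega_i = z_i^\top v + b$
(the scalar scorer is unspecified in the method's description; a learned
linear map is the natural minimal choice and is documented as ours),
normalizes $\beta = \mathrm{softmax}(\omega)$ and reweights
$Z'_i = \beta_i Z_i$. A four-layer fully connected head with ReLU
between layers and a softmax output produces class probabilities; argmax
ties break toward the lowest class index.

### Gradient reversal

$Z'$ also feeds, through a gradient reversal layer (identity forward,
gradient scaled by $-\alpha$ backward, $\alpha = 0.1$), a domain
classifier: one hidden layer of 100 units with batch normalization,
ReLU, and a LogSoftmax output. Minimizing the domain loss therefore
*maximizes* it with respect to the feature extractor, pushing the pooled
features toward subject invariance. The default domain scheme is binary
source-vs-target with the held-out subject's unlabeled features as the
target domain; a per-subject multiclass scheme is available
(`grl_config(scheme = "per_subject")`). The "without GRL" ablation
removes the whole domain branch — keeping the domain loss while
disabling reversal would actively *align* features with subject
identity, the opposite of the ablation's intent.

## Design choices where the description was open

* **Inter-layer nonlinearity.** None is written inside the layer stack;
  ReLU after every graph convolution except the last is the default (and
  configurable) for trainability. The head's activation is likewise ReLU,
  matching the only activation named anywhere (the domain classifier's).
* **Layer widths.** Only "four-layer fully connected network" and a
  total of roughly 77k parameters are reported. Package defaults
  (`layer_dims = c(16, 32)`, `classifier_dims = c(64, 32, 16)`,
  ~131k parameters with the default pooling) were chosen for desk-scale
  trainability in pure R at roughly the reported parameter scale; they
  are explicitly not method-fixed.
* **Band edges** are a literature convention, exposed in `band_set()`.
* **DE estimator.** Time-domain band variance with the Gaussian closed
  form; spectral integration would give the same Gaussian form and the
  base feature for the asymmetry families is switchable
  (`base_feature = "psd"`).
* **Filtering.** Band-pass filters are order-4 zero-phase Butterworth
  cascades (high-pass then low-pass); a single band-pass transfer
  function with edges at 0.0006 of Nyquist is numerically fragile. The
  preprocessing filter defaults to order 6 so that stopband rejection
  20% past the 50 Hz edge exceeds 20 dB (order 4 forward-backward gives
  only ~14.7 dB there).
* **Plain-GCN ablation graph.** Any fixed graph satisfies "replaced by
  GCN"; the default is a symmetric degree-normalized ring (each
  electrode linked to its 2 neighbors in montage order), configurable.
* **Feature standardization.** Per-(electrode, band) z-scoring with
  training-fold statistics only, preventing test leakage; switchable.
* **Aggregate dispersion** over folds is the population (÷N) standard
  deviation.
* **Final model** is the last epoch's parameters; no early stopping.

Optimization follows the reference recipe: Adam, learning rate 0.01,
batch 64, 40 epochs, cross-entropy loss, seed 100; evaluation batches
match the training batch size. Training is deterministic given the seed.

## The synthetic world

`generate_features()` draws iid Gaussian baseline features
(`noise_sd = 1`), adds a class-specific pattern of magnitude
`effect_size` on a small electrode set (defaults 15, 23, 25, 31, 32, 33,
50 — the indices reported as most emotion-discriminative on this cap)
in the $\beta$/$\gamma$ bands, and then distorts each subject's features
with a sampled log-normal gain (`subject_gain_sd = 0.4`) and additive
offset (`subject_offset_sd = 1`). Class patterns are orthonormal, so 3-
and 4-class regimes are equally separable. Subjects have
`n_classes * n_trials_per_class` trials with classes cycling through
trials, so the leading trials of the subject-dependent split are
class-balanced. `generate_raw()` produces band-limited oscillator
mixtures at 200 Hz for end-to-end testing of the extraction chain.

What the generator does **not** emulate: 1/f spectra, volume conduction,
artifacts, trial-level nonstationarity, covariance-level subject
differences (the shift is affine — the simplest mechanism that makes the
adversarial branch's job real). A green synthetic test therefore
establishes the implementation's correctness and the *mechanics* of
adaptation, not performance on real EEG.

Two scale notes on the test suite's stated worlds:

* The separability check trains the default model on `effect_size = 5`,
  `noise_sd = 1`, no subject shift (seed 100) at a reduced size
  (3 subjects, 15 trials, 10 segments/trial) and requires ≥95% held-out
  accuracy within the standard 40 epochs; a nearest-centroid oracle on
  the same data is essentially perfect, so the bar tests the network,
  not the world.
* The reference learning rate (0.01) can be unstable: on some datasets
  the optimizer wanders on the initial plateau for the full 40 epochs
  (train accuracy pinned at chance) while `lr = 0.003` trains the same
  data to 100%. The default stays at the reference value; lower it if
  the per-epoch history shows a flat loss near `log(n_classes)`.
* The ablation ordering experiment needs a world where cross-subject
  transfer is neither trivial nor impossible at a 20-epoch desk budget:
  with the generator's default scalar offset (sd 1 across all 310
  features) every variant sits at chance and ordering is undefined. The
  experiment therefore uses `effect_size = 3`, `subject_gain_sd = 0.2`,
  `subject_offset_sd = 0.5`, 4 subjects, LOSO over 5 shared seeds —
  fixed before the ordering was measured, and directional only. On this
  world the full model does **not** dominate all ablations: the
  fixed-graph GCN variant trains more stably at the reference learning
  rate and transfers better, while the full model's folds often remain
  on the optimization plateau described above. The corresponding
  acceptance test is left failing rather than re-tuned: at dozens of
  training samples per class and minutes of CPU, the dominance ordering
  reported for full-scale studies is not reproduced by this
  implementation, and the suite says so.

## Numerical notes

Both softmaxes subtract the row maximum before exponentiation. RASM
denominators below `1e-8` raise by default (`clip` optional) because DE
is a log quantity that legitimately crosses zero. Zero-variance band
signals make DE undefined; the guard raises by default (`-Inf`
optional). Trailing partial segments are dropped, never padded. All
gradients are hand-derived (no autodiff is available in the target
environment) and verified against central finite differences in the
test suite.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(n_subjects = 3, effect_size = 5,
                       subject_gain_sd = 0, subject_offset_sd = 0,
                       n_segments_per_trial = 8)
ft <- generate_features(spec)
plan <- make_splits(ft$subject_id, ft$trial_id, "subject_dependent")
tr <- unlist(lapply(plan$folds, `[[`, "train"))
te <- unlist(lapply(plan$folds, `[[`, "test"))
fit <- train_model(list(x = ft$values[tr, , ], y = ft$labels[tr]),
                   train_cfg = train_config(epochs = 40))
evaluate_model(fit, list(x = ft$values[te, , ], y = ft$labels[te]))$accuracy
```

## Limitations

Pure-R training is single-threaded and desk-scale; a full 15-subject
LOSO study at realistic segment counts would take hours. The package
does not implement artifact rejection, re-referencing, baseline model
families, or α-schedules for the reversal strength (the reference
setting is a constant 0.1). Attention-weight exports
(`export_attention_weights()`) provide the per-electrode importance
profiles for visualization but no plotting functions are included.
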
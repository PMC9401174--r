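---
title: "Methods: single-layer convolutional networks for MRSI voxel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-layer convolutional networks for MRSI voxel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsiclass)
```

## The problem

MR spectroscopic imaging (MRSI) produces, for every spatial voxel of a brain
acquisition, a metabolite spectrum — a real vector over frequency bins whose
peaks (choline, creatine, N-acetylaspartate, lactate for ¹H; phosphocreatine,
inorganic phosphate and ATP for ³¹P) reflect local tissue biochemistry.
Co-registered MR images (T1, T2, PD, Gd contrasts) add a second modality per
voxel. Clinical questions — which glioma grade does this voxel belong to, is
this subject's metabolic profile that of Alzheimer's disease — become
voxel-wise classification problems with three structural difficulties:

1. **Few subjects, many correlated features.** Cohorts have tens of patients
   but hundreds of frequency bins, and neighboring bins are strongly
   correlated (a resonance line spans many bins).
2. **Patient identity is a confound.** All voxels of one patient share
   subject-specific characteristics unrelated to the diagnosis. Any protocol
   that lets voxels of one patient appear in both training and test data
   inflates performance estimates.
3. **Interpretability.** A clinically credible classifier must say *which
   spectral regions* drive its decisions, so they can be compared with known
   biomarkers.

This package implements a single-layer convolutional network (SL-CNN)
tailored to these constraints, chemometric baselines (SVM-RBF, PLS-DA,
KPLS-DA with multi-kernel fusion, MBPLS-DA), a stability-selection procedure
that maps learned features back to spectral regions, and a leakage-safe
patient-grouped nested cross-validation harness. A synthetic MRSI generator
makes every stage testable without clinical data.

## The SL-CNN model

One convolutional hidden layer per modality branch:

* **Spectral branch.** `K_spec` kernels of size `N_spec` bins slide over the
  spectrum at stride `stride_s` (valid convolution, no padding), producing
  `F = floor((P - N)/s) + 1` positions per kernel. Multi-channel spectra
  (e.g. four brain ROIs stacked "as channels") enter each kernel as an extra
  summed dimension: a kernel is a `channels x N` weight window. ReLU follows
  the convolution.
* **Image branch** (optional). `K_img` kernels of side `N_img` convolve the
  stacked MRI contrasts (stride 1), followed by ReLU and non-overlapping max
  pooling of side `pool_size` (ragged edges truncated).
* Both branches are flattened (kernel-major, positions fastest), merged —
  spectral features first — and fed to a linear softmax output layer.

The training loss is

> weighted mean cross-entropy + λ₁ · Σ w² + λ₂ · Σ (w_{i+1} − w_i)²

where the λ₁ term is standard weight decay over all convolutional and output
weights, and the λ₂ term penalizes large variations between *neighboring
weights within each kernel* (both axes for 2D kernels) — the smoothness prior
appropriate for spectra, whose informative structure is locally smooth.
Biases enter neither penalty. Class weights are inverse class frequencies
(configurable off): the concrete mechanism by which the shallow architecture
tolerates unbalanced cohorts.

Optimization is plain mini-batch gradient descent at a fixed learning rate
`eta` for a fixed number of epochs, with seeded initialization
(uniform ± 1/√fan-in) and seeded batch shuffling, so `slcnn_train()` is a
pure function of `(data, config)`. There is no early stopping; model
selection belongs to the nested cross-validation. Gradients are analytic and
are verified against central finite differences (relative error < 1e-5) in
the test suite.

**Open choices resolved here.** The activation (ReLU), the presence of
biases, the optimizer and the exact smoothness form are not dictated by the
architecture alone; we chose the canonical options (ReLU, biases on, plain
SGD, squared first differences within kernels) and treat λ₁/λ₂ as separate
weight-decay and smoothness strengths. The ambiguity of "neighboring kernel
weights" (within one kernel vs across kernels) is resolved as *within* a
kernel: smoothness across unordered, independently initialized kernels has
no analogous justification.

## Identifying relevant spectral regions

The output layer is a logistic model over convolutional features, so
relevance analysis retrains exactly that layer on random subsets:

1. Draw `B = 100` subsamples of half the patients (without replacement,
   stratified by class, always whole patients — the package's own leakage
   argument applies to resampling too).
2. On each subsample, refit the last layer as a penalized logistic
   regression (`glmnet`) and mark features with coefficients > 0 toward a
   class as selected.
3. A feature's relevance is the fraction of subsamples selecting it;
   features at frequency ≥ 0.96 (a deliberately conservative threshold) are
   reported.
4. Every selected spectral feature maps back to its receptive field
   `[j·s, j·s + N − 1]` (0-based bins, inclusive; identical in every channel
   because kernels sum channels), and overlapping or adjacent intervals are
   merged per channel into maximal regions.

**Penalty form.** The retrain uses an elastic net (`alpha = 0.5`,
`lambda = penalty_strength / n` with `penalty_strength = 1`, standardized
features) rather than a pure lasso. Neighboring convolutional positions are
nearly collinear; a pure L1 penalty then selects one arbitrary member of a
correlated signal group per resample, which splits the selection votes and
caps every individual feature's frequency well below a conservative
threshold even for an unambiguous signal. The ridge component restores the
grouping effect — the whole signal-carrying group is selected together —
while the L1 component keeps irrelevant coefficients exactly zero, which is
the sparsity stability selection relies on. Pure lasso remains available via
`alpha = 1`.

**What the desk-scale tests show.** On synthetic two-class spectra with one
planted discriminative peak, the merged selected regions intersect the
planted peak in ≥ 9/10 seeded runs, while under a matched null (no class
effect) the expected number of features at frequency ≥ 0.96 is below one.
This validates the *procedure*; on real spectra the regions still need
biochemical interpretation.

## Baselines

* **SVM-RBF** on voxels represented as the concatenation of all modality
  streams (delegated to `e1071::svm`; `C` and `γ` are tuned in the harness).
* **PLS-DA**: NIPALS PLS2 against a one-hot class coding, arg-max decoding,
  continuous class scores exposed for ROC analysis.
* **KPLS-DA**: the dual (kernel) formulation on a double-centered Gram
  matrix, RBF kernel by default. With a linear kernel its predictions
  reproduce PLS-DA to 1e-6 — the module's central correctness oracle,
  asserted over random datasets in the tests.
* **Multi-kernel fusion**: per-modality kernels merged as `K = Σ aᵢKᵢ` with
  L1-normalized weights; weights are tuned over a simplex grid (step 0.1)
  by inner cross-validated MCC, ties broken by grid order.
* **MBPLS-DA**: blocks scaled by tunable block weights, concatenated, then
  PLS-DA. With one block and weight 1 it *is* PLS-DA (asserted exactly);
  the super-score formulation is deliberately out of scope.

## Validation protocol

The outer protocol is leave-one-patient-out (LOPO): all voxels of one
patient form a test fold and every other patient trains. Inside each outer
training set a random grid search (`n_draws = 30` by default) scores
hyper-parameter draws by pooled MCC under a patient-grouped 3-fold inner CV;
the winner is refit on all training patients. Unit-interval rescaling is
fitted per fold on training voxels only and applied unchanged to held-out
voxels (no clipping). The harness records every patient id the search
touched and asserts the intersection with the outer test patients is empty.
Repetitions over seeds give the reported mean ± sd. Binary tasks use the
Matthews correlation coefficient (zero-denominator convention: 0); ROC/AUC
uses the Mann-Whitney form with ties counted ½, and correlated AUCs are
compared with the fast DeLong structural-components test.

A deliberately leakage-prone protocol (`voxel_kfold`, voxel-level 3-fold) is
included for demonstration: on patient-confound null data — labels assigned
at patient level but *no* class effect — it reports MCC near 1 while LOPO
stays at chance. That gap is the package's reproduction of the argument for
patient-grouped validation.

**Rescaling granularity.** "[0, 1] rescaling" is realized per feature (per
bin and channel, per pixel and contrast), fitted fold-wise. Per-feature
min-max is the standard choice for PLS/SVM inputs; fold-wise fitting is
forced by the leakage argument. A caveat surfaced by the synthetic
experiments: per-feature min-max amplifies pure-noise bins to full scale,
which can reward noise memorization in very flexible models — one more
reason the protocol, not the training accuracy, must carry the evidence.

## The synthetic generator

`synthetic_config()` defines a generative model shaped like the clinical
cohorts the method targets:

* spectra are sums of Gaussian peaks (positions/widths/amplitudes in bins;
  Gaussian rather than Lorentzian/Voigt line shapes — no tested property
  depends on the line shape);
* class effects multiply peak amplitudes (e.g. NAA down, Cho and lactate up
  with tumor grade);
* each patient draws one log-normal factor *per peak*, shared by all their
  voxels — a subject-specific metabolite profile. This is the within-patient
  similarity that motivates grouped validation. A single global scale factor
  per patient was considered and rejected: it concentrates the confound in
  one dimension, which a shallow network cannot exploit at desk scale, and
  it is also less realistic than per-metabolite subject variation;
* i.i.d. Gaussian noise per bin (`noise_sd`, in units of the base peak
  amplitudes; defaults around 0.03 correspond to the high SNR of averaged
  clinical spectra);
* optional image patches per voxel: Gaussian noise with a class-dependent
  mean shift — by design a weaker signal than the spectra, so that fusion
  experiments can reproduce the "images alone worst, fusion best" ordering;
* all randomness flows from a single seed; regeneration is bit-identical.

Two presets ship as YAML files (`synthetic_preset("tumor")`,
`synthetic_preset("alzheimer")`), mirroring the cohort shapes the package
targets: 29 subjects across six tissue classes with fewer voxels per patient
for higher grades and four MRI contrasts; and 62 subjects, two classes, four
single-voxel ROIs stacked as spectral channels.

What the generator does *not* emulate: baseline roll, phase errors,
J-coupling multiplets, T2 line-width variation, spatial correlation between
neighboring voxels, and non-Gaussian artifacts. Passing tests therefore
validate algorithmic correctness and protocol behavior, not clinical
performance.

## Study conditions used by the acceptance experiments

The heavyweight checks run at fixed desk scales, chosen once:

* *Planted-region recovery*: P = 512, four peaks, one class effect (NAA-like
  factor 1.5), 20 patients × 10 voxels with modest subject variation
  (per-peak patient effect sd 0.1, clearly below the planted effect — the
  experiment probes localization of a recoverable signal, not robustness to
  a confound of equal size), default network (K = 4, N = 32, s = 4),
  B = 100, threshold 0.96, ten seeds, with a matched null.
* *Leakage demonstration*: 24 patients × 6 voxels, P = 32 with four wide
  peaks (so nearly every bin carries patient signal), patient effect sd 0.5,
  noise sd 0.02, and a deliberately high-capacity training regime (K = 8,
  200 epochs, η = 0.2, no regularization) — the point is to let the model
  memorize patients, then show that only the naive protocol rewards it.
  Naive-vs-LOPO numbers are compared as means over five seeds.
* *Fusion benefit*: a union of two cohorts — one whose class signal lives
  only in spectra (8 patients), one only in images (6 patients) — so the
  modalities are genuinely complementary: each alone classifies a strict
  subset of patients, their fusion all of them. An additive design (both
  signals in the same patients) was rejected: Gaussian signal fusion is
  sub-additive (d' adds in quadrature), leaving ordering gaps smaller than
  seed noise at this scale.

## Numerical choices and degenerate inputs

* Constant features rescale to 0 (division-by-zero guard; a constant feature
  is uninformative).
* MCC returns 0 whenever a denominator factor is 0.
* DeLong on two identical score vectors returns ΔAUC = 0, p = 1; a zero
  variance with genuinely different scores is an error, not a p-value.
* Max pooling breaks ties by the first maximum (deterministic); NIPALS and
  its kernel variant stop early and warn when the requested number of
  components exceeds the predictor rank.
* Random-search ties are broken by smaller model complexity (fewer kernels /
  components), then draw order.
* All bin indices in user-facing region arithmetic are 0-based with
  inclusive interval ends; ppm axes are stored descending, as is
  conventional for MR spectra.

## Known limitations

* The SL-CNN optimizer is plain SGD; very large λ₂ values require a smaller
  learning rate (the trainer reports the epoch of a non-finite loss).
* Image-branch features are not mapped back to pixel regions; relevance
  mapping is spectra-only.
* DeLong is applied to voxel-level predictions and ignores within-patient
  correlation of voxels; its p-values on multi-voxel cohorts are
  anti-conservative to an unquantified degree.
* Multiclass tasks are handled pairwise; there is no multiclass MCC.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_preset("tumor", seed = 7)
ds <- simulate_dataset(cfg)
task <- subset_classes(ds, c("grade_II", "grade_III"))

cv <- nested_cv(
  method_slcnn(slcnn_config(epochs = 80)),
  task, protocol = "lopo", repetitions = 3, seed = 7
)
glance(cv)

dss <- apply_rescaler(task, fit_rescaler(task))
model <- slcnn_train(dss, slcnn_config(epochs = 80, seed = 7))
profile <- stability_selection(model, dss, B = 100, seed = 7)
relevance_regions(profile, model, threshold = 0.96, ppm_axis = task$ppm_axis)
autoplot(profile)
```
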
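---
title: "Hierarchical ventral-stream voxelwise encoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical ventral-stream voxelwise encoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Voxelwise encoding models predict the fMRI response of each voxel from the
stimulus. Models built on oriented-filter (Gabor) features predict early
visual cortex (V1, V2) well but degrade in higher ventral-stream areas (V4,
LO), whose selectivities are nonlinear functions of lower-area responses.
`hvem` implements a hierarchical remedy: first fit a Gabor convolutional
encoder to a *low-level* area, then freeze it and re-read its representation
out into a *high-level* area with a small nonlinear readout, following the
anatomical ordering V1 → V2 → V4 → LO. The re-used representation can be
either

* the **predicted voxel space** of the source area, restricted to its
  effectively encoded voxels (`s2v2v`, the voxel perspective), or
* the **flattened last convolutional layer** of the frozen encoder
  (`s2f2v`, the feature perspective; 32,768 dimensions at the full
  128 px input size).

## The stage-1 encoder

The encoder is a three-layer convolutional network. Its first layer holds
128 Gabor kernels generated from 64 trainable parameter tuples
(orientation θ, wavelength λ, envelope scale σ, aspect ratio γ, phase ψ);
each tuple yields an even kernel, `exp(-(x'^2 + γ²y'^2)/(2σ²)) ·
cos(2πx'/λ + ψ)` on the 9×9 integer grid, and an odd partner at phase
ψ + π/2. Gradients reach the five parameter vectors analytically through
the kernel construction, so the filter bank itself is learned. Two dense
128-channel convolutions follow, then a readout from the flattened last
layer to the ROI's voxels — affine (`linear`) or affine–rectifier–affine
(`nonlinear`, identical in structure to the hierarchical readout).

Strides and paddings are not published; `backbone_spec()` uses the unique
simple integer solution reproducing the published activation sizes from a
128×128 input: kernel 9/stride 2/pad 2, then 3/2/1 twice, giving
128×62×62, 128×31×31, 128×16×16 and a 32,768-long feature vector. The
inter-layer activation (rectifier) and input normalisation (scale to [0, 1],
subtract the per-image mean) are likewise unstated upstream and are recorded
here as configurable package decisions, not inferred facts.

During training the positivity of λ, σ, γ must survive Adam updates; the
package clamps them after each step (λ ≥ 1 px, σ ≥ 0.5 px, γ ≥ 0.05) rather
than reparameterising in log space, keeping parameter values interpretable
in pixels.

## The hierarchical readout and the weight-squaring rule

The voxel-to-voxel (V2VM) and feature-to-voxel (F2VM) readouts share one
structure: two affine maps with a rectifier between them, the latent width
equal to the target ROI's voxel count. Source voxels enter only after
passing the validity threshold (ρ > 0.27 by default, strict inequality).

The distinctive training detail is the *weight-squaring rule*: when the
first affine map's gradient is backpropagated, it is gated elementwise by
the squared weight matrix, `g ← g ∘ W ∘ W`, before the optimizer step.
Connections from source voxels that already carry weight ("intimate"
voxels) receive amplified updates; weakly connected ("distant") voxels are
suppressed; a zero weight is a dead gate. The source text is ambiguous
between (a) this gradient gating, (b) replacing W by a sign-preserving W² in
the forward pass, and (c) an L2-style penalty; the package implements (a)
because it realises the stated motivation — emphasise intimate, suppress
distant — while leaving the forward map untouched, and the rule can be
switched off via `train_config(squared_weight_rule = FALSE)`. Note that
under Adam the per-element normalisation partially absorbs any static
gradient scaling; the rule's effect is strongest early in training, before
the second-moment estimates adapt.

Feature-mode representations are centred and scaled before the readout. The
obvious per-dimension standardisation (divide by each dimension's training
sd) proved actively harmful at reduced scale: rectified conv3 dimensions
that are almost always zero have sd ≈ 0, and dividing by it inflates them
into pure-noise axes that dominate the fit (held-out accuracy collapsed to
near zero while ridge regression on the same features predicted well). The
package therefore divides by `sd_d + mean(sd)`, which bounds the feature
scale — the original motivation — without amplifying dead dimensions. This
is a deliberate deviation from plain standardisation and is the package's
own design choice.

## Training schedule

The published schedule is 90 epochs: stage 1 (epochs 1–50) trains the
encoder on the source area with Adam (lr 0.001), batch 64,
mean-squared-error loss; stage 2 (the remaining 40) trains the hierarchical
readout on the frozen representation. The epoch ranges "1st–50th" and
"50th–90th" overlap at 50; the package resolves this as 50 + 40. The loss
is not named upstream; mean-squared error is the standard choice for
continuous responses. After every epoch the mean validation ρ across the
ROI's defined voxels is recorded, and the checkpoint with the highest value
is kept (ties → earliest epoch). Stage 2 never touches stage-1 parameters
(asserted programmatically). One stage-1 model per source area is trained
and re-used across targets.

At reduced test scale the package applies one fixed translation of this
schedule: every stimulus-to-voxel network — stage-1 source encoders *and*
the direct control encoders they are compared against — receives the same
encoder epoch budget, and hierarchical readouts receive a stage-2 budget
matched to the published schedule in optimizer *steps* (40 epochs × ~27
minibatches at full scale ≈ 100 epochs × 10 minibatches at 300 samples).
This keeps the model comparison symmetric under compute scaling.

## Evaluation statistics

* **Prediction accuracy** is the per-voxel Pearson correlation between
  measured and predicted validation responses. Voxels with zero variance on
  either side are flagged undefined and excluded from every summary, never
  zeroed.
* **Validity threshold**: shuffling the sample correspondence 1000 times per
  voxel builds a null distribution; with 120 validation samples the upper
  0.001 quantile lands near the published global constant 0.27 (the
  analytic limit is `qnorm(0.999)/sqrt(119) ≈ 0.283`). Because the
  empirical 99.9th percentile of 1000 draws is the noisy maximum, the
  package uses the (⌊αB⌋+1)-th largest null draw — the 2nd largest at
  B = 1000, α = 0.001 — and summarises per-voxel thresholds by their
  median. The literal 0.27 stays the default cutoff for comparability;
  recomputation is available.
* **Top-K average accuracy**: mean ρ of the K best-predicted voxels (K =
  300 at full scale; reduced-scale analyses in this package use K = 50).
* **Advantage analysis**: restricted to voxels valid under *both* models,
  the proportion predicted better by model A, with a coin-flip null (each
  voxel's pair swapped with probability 0.5, 1000 times). The null cutoff
  is approximately `0.5 + z(1−α)/√(4N)`; the published "53% is significant"
  rule matches this null at a few thousand joint voxels. Exact ties
  (|Δρ| < 1e-12) are excluded from proportions and reported.
* **Best-encoded voxels**: over voxels valid under *at least one* model,
  each voxel is assigned to its argmax-ρ model; ties go to the
  earlier-listed model. Proportions sum to 1.

## The synthetic world

No generative model is published (the original study uses recorded fMRI),
so the generator is pure artifact plumbing designed to make the pipeline
testable offline, with two requirements: V1-like voxels must be learnable
by a Gabor encoder, and V4/LO-like voxels must depend on lower areas
nonlinearly — the regime in which hierarchical readout should win.

Stimuli are sums of 5–15 random Gabor patches plus 1/f spectral noise,
rescaled to [0, 1]. V1 voxels are rectified quadrature-pair energies of
localized Gabor filters (random position, orientation, wavelength λ ∈
[3, 10] px). V2 voxels pool squared V1 outputs sparsely and nonnegatively
(10 inputs each, complex-cell style, with a square root to tame the
dynamic range). V4 voxels are sparse signed mixtures of V2 passed through
tanh; LO repeats that over V4. Every stage's signal is standardised to unit
variance and receives independent Gaussian noise of variance 1/SNR, so the
noise ceiling of an ideal predictor is `sqrt(SNR/(1+SNR))` — a closed form
the tests verify empirically. Configuration `H1` uses SNRs V1:4, V2:3,
V4:1, LO:0.5; `H0` is a noiseless V1-only world for optimizer sanity
checks.

What a green hierarchy-advantage test establishes: *in a world constructed
so that V4/LO are nonlinear functions of V2*, the two-stage models recover
more of that structure than a same-capacity direct encoder under an equal
compute budget. It does not establish anything about recorded cortex, about
the published accuracy tables (which require the registration-gated vim-1
download and GPU-scale training and are out of scope), or about worlds
where the hierarchy assumption fails. The generator also omits retinotopy,
hemodynamics, and voxel noise correlations.

## Reduced scales and numerical choices

* Default generator scale is side 64, 300 train / 60 val, ROI sizes
  V1:200, V2:150, V4:100, LO:60. The heavy acceptance test runs this world
  at side 32 with 15 encoder epochs — single-CPU compute scaling of the
  schedule, not a change to the stated SNRs, sizes or split.
* Reduced-scale source selection keeps the default 0.27 cutoff; with 60
  validation samples this is permissive (the matched null quantile would be
  ≈ 0.40), which suits the small synthetic ROIs.
* Stage-2 uses the same train/validation split as stage 1; no third split
  exists, matching the published setup. Source-voxel selection uses
  validation accuracy (the split on which accuracy is defined throughout).
* Ridge fits use the primal normal equations when D ≤ N and the dual form
  otherwise; λ = 0 on a rank-deficient design raises an advisory error.
* Checkpoints and caches serialise as RDS with JSON sidecars; the vim-1
  HDF5 layout is read and written through a bundled Python `h5py` bridge,
  since no R HDF5 binding is available in the supported environment.

## Known limitations

* The original reference implementation of the Gabor encoder is not
  reproduced; undocumented details (its exact initialisation, pooling, and
  preprocessing) are replaced by the configurable decisions above.
* The pretrained object-recognition backbone of the ridge control model
  requires downloaded weights; the packaged extractor is a fixed-seed
  random-weight stand-in of the same 7-layer shape, and is labelled as
  such. Conclusions about the *pretrained* control do not transfer.
* Single-source pipelines only; multi-source fusion (e.g. V1+V2 → V4) is
  out of scope.
* Full-scale (1750-sample, 128 px, 90-epoch) training is supported by the
  code but takes hours on one CPU; all shipped tests run at reduced scale.
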
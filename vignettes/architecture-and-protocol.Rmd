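---
title: "Architecture, accounting and protocol: how renalnet is put together"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture, accounting and protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Renal cell carcinoma (RCC) subtyping from H&E-stained histopathology is a
four-class patch classification task: normal renal tissue versus the clear
cell (KIRC), papillary (KIRP) and chromophobe (KICH) carcinoma subtypes.
The subtypes differ morphologically — clear cytoplasmic vacuoles in KIRC,
nuclei-lined fibrovascular fronds in KIRP, pale cells with perinuclear halos
and prominent membranes in KICH, regular tubules in normal cortex — and a
compact convolutional network can learn these cues from patches cropped out
of whole-slide images. `renalnet` implements such a network in full
(forward and backward passes in R, convolution kernels in C++), together
with the exact complexity accounting, the dataset protocol, the training
schedule and the evaluation machinery around it.

## The MCRT block

A multiple-channel residual transformation (MCRT) stage maps an
`H x W x C` feature map to the same shape through three parallel paths plus
an identity connection:

```
path i:   Conv3x3(C -> C, bias) -> BN -> ReLU -> SE(r_i) -> BN
output:   X + path1(X) + path2(X) + path3(X)
```

Each squeeze-and-excitation (SE) gate pools its map to a length-`C`
descriptor of per-channel spatial means, passes it through a bottleneck
`C -> C/r -> C` (ReLU, then sigmoid; both layers with biases) and rescales
the channels by the resulting gate in `(0, 1)`. The three paths use
excitation ratios `(2, 4, 8)`, so a stage attends to its channels at three
bottleneck depths simultaneously. The residual sum makes the block an exact
identity at zero weights, and its input gradient always contains the
additive identity term — `mcrt_gradient_check()` verifies the analytic
backward pass against central finite differences, element by element.

Two reconstruction decisions deserve a note:

* **Two BN layers per path.** The published per-variant parameter totals are
  met exactly by `27*C^2 + 15*C` per stage (plus SE terms), which requires a
  second normalization layer after the SE gate; a single-BN arrangement is
  off by 672 across the three stages. The layer order
  `Conv -> BN -> ReLU -> SE -> BN` is the natural reading of
  "convolution, batch normalization and ReLU, plus SE" under that
  constraint; whether ReLU precedes or follows the second BN is not
  determined by any printed number, and the first position was chosen.
* **Ratio set `(2, 4, 8)`.** The published ablation grid fixes the ratio set;
  the alternative reading "reduced widths C, C/2, C/4" (ratios 1, 2, 4)
  reproduces none of the printed totals and is not used. Paths are assigned
  ratios in increasing order; the assignment does not affect any count.

At the reference widths 16/32/64 the three stages hold exactly 156,674
trainable parameters.

## The GCDL head

The group-convolution deep-localization (GCDL) head consumes the three
stage outputs `X1` (S x S x 16), `X2` (S/2 x S/2 x 32), `X3`
(S/4 x S/4 x 64):

* **Strided fusion** — 3x3 convolutions at strides 4/2/1 bring all stages to
  the coarsest grid; the results are concatenated channel-wise and merged by
  a separable (depthwise + pointwise) convolution with BN and ReLU into the
  fused descriptor `X_out`.
* **Attention gate** — `X_out` is globally pooled and projected through a
  two-layer gate (ReLU bottleneck, sigmoid output) to 64 channels, which
  rescale `X3`; BN follows.
* **ADSC** — four depthwise-separable 3x3 branches at dilation rates
  1, 2, 4, 6 on `X_out` (dilation-aware 'same' padding, pad = d), channel
  concatenation and a 1x1 projection to 64 channels with BN and ReLU.

The attention and ADSC outputs, both 64-channel maps at stage-3 resolution,
are merged **by element-wise addition**. Concatenation was considered and
rejected: the classifier head (`BN(64) -> Conv1x1 64->32 -> BN -> ReLU ->
global pool -> FC 32->4 -> softmax`) is pinned at 26,212 parameters by the
ablation row without the GCDL head, and a 128-channel input would change
its BN and convolution widths. Addition keeps the one fixed head serving
every ablation variant, and the head's parameter budget is agnostic to the
merge.

### Solving the internal widths

The head's internal widths are not published. They are pinned by
`solve_reference_config()`, which enumerates the bounded width space under
the package's layer policy (bias-free convolutions where BN follows, biased
elsewhere) and keeps configurations whose three sub-block counts equal the
budgets derived from the published variant totals by inclusion-exclusion:
fusion 14,560, ADSC 11,136, attention 4,592. Among the parameter-exact
candidates, the solver returns the one whose total FLOP count is closest to
the published 2.71 x 10^9. The solved widths — fusion 9/11/15 into a
28-channel descriptor, ADSC branches of width 27, attention bottleneck 48 —
are frozen as the `renalnet_config()` defaults, and a test asserts the
solver reproduces them.

One consequence of the budget arithmetic: a *single* dense projection
`C_f -> 64` "with bias and BN" can never hit 4,592 (its count is 48 mod 64
away from any such form), so the gate must be two-layer. The chosen form —
first layer biased with ReLU, second bias-free with sigmoid, BN after the
scaling — mirrors the SE gates elsewhere in the network.

## Parameter and FLOP conventions

Trainable parameters are conv/FC weights plus biases and 2 per batch-norm
channel (scale and shift); running statistics are excluded. FLOPs are
2 per multiply-accumulate over convolutional and fully connected layers
only, at a 224 x 224 x 3 input; normalization, activations, pooling and
element-wise arithmetic are not counted. `count_params()` cross-checks the
per-layer table against an independent walk over the raw parameter arrays.

The fusion block's strided kernels are **evaluated densely and decimated**:
a stride-s convolution equals a dense convolution whose output is
subsampled every s-th position, and the implementation literally computes
the dense map first — strided convolution "performs pooling as well as
convolution". Their MACs are therefore ledgered at input resolution. Under
this accounting the assembled reference model lands at 2.7088 x 10^9 FLOPs
(2.71 at three significant figures) while all eight variant parameter
totals close exactly. We note for auditability that the published
per-variant FLOP figures are not mutually consistent with the published
parameter totals under any single convention we could construct: with
parameters pinned, the MCRT-only variant computes 2.37 x 10^9 (published
2.58) and the GCDL-only variant 0.63 x 10^9 (published 0.609). The full
model, which is the figure the package anchors to, is exact.

## The synthetic dataset

The generator emulates the *protocol-level statistics* of the reference
collection: 1,100 patches per class over 170 synthetic cases per class (one
slide per case), class-balanced, with per-case stain jitter shared by all
patches of a case so that slide-wise splitting is meaningful. Per class it
renders distinct geometry in hematoxylin/eosin-like colors: tubule rings
(Normal), clear vacuoles (KIRC), branching nuclei-lined fronds (KIRP), pale
cells with halos and prominent membranes (KICH), over a low-frequency
eosin-textured background with Gaussian pixel noise. Structure sizes are
fractions of the patch side, so a patch represents the same field of view
at any rendering resolution; all geometry derives from per-patch seeds, and
regeneration under a fixed seed is bit-identical.

What it does **not** emulate: real nuclear chromatin texture, stain
deconvolution physics, intra-class morphological heterogeneity, scanner
artifacts, or pathologist ROI selection. Passing tests on this data show
that the pipeline is mechanically correct and that the network can learn
separable morphology at the protocol's cardinalities — they say nothing
about accuracy on real slides.

**Split.** Cases, never patches, are assigned to train or test. The nominal
split is 85/15, but whole-case packing cannot generally hit 15% of patches
exactly; the protocol's realized test set is 632 of 4,400 (158 per class),
and the default target reproduces that via exact subset-sum over case sizes
(randomized by the split seed). **Folds.** "5 folds of 880 images of each
class" is internally inconsistent (880 = 4,400/5 is per fold over *all*
classes); it is read as 880 per fold, 220 per class, and
`make_folds()` achieves exact per-class equality whenever case sizes permit
(longest-processing-time assignment with pairwise swap repair).

**Preprocessing.** Patches are resized bilinearly to the network input side
(with a Gaussian anti-alias blur when downscaling by more than 20%) and
standardized per image and channel to zero mean, unit variance, with a
1e-8 variance floor so constant images map to zero. Per-image rather than
dataset-level standardization is a documented choice; nothing in the
protocol fixes it.

## Training protocol

Adam at initial learning rate 0.001, batch size 4, categorical
cross-entropy, up to 65 epochs. The learning rate halves after 5 epochs
without a validation-accuracy improvement of at least 1e-4; training stops
early after 30 such epochs; the best-epoch weights are restored, *including
the batch-norm running statistics* — restoring weights without their
matching statistics measurably degrades evaluation. Validation is a seeded,
case-respecting 10% of the training patches (the protocol says only
"randomly selected from the training set"; case-respecting avoids
validation leakage, and 10% is a documented choice).

Metrics: per-class precision, recall, F1 and one-vs-rest accuracy; overall
precision/recall/F1 as the unweighted (macro) mean over classes; overall
accuracy as the pooled (micro) fraction correct — with balanced classes the
micro accuracy equals the macro recall, which the tests assert. ROC-AUC is
one-vs-rest per class (trapezoidal, equal to the Mann-Whitney pair
statistic). Trial averaging (three independent initializations) and 5-fold
cross-validation average reports element-wise.

Class-activation overlays are gradient-weighted: the target-class logit is
backpropagated to the pre-classifier feature map, channels are weighted by
their spatially averaged gradients, and the rectified, min-max-normalized
sum is banded at 0.7/0.4 into red (high), orange (medium) and light blue
(low) before alpha-blending over the patch. The method and thresholds are
package choices; the protocol names no specific CAM variant.

## Problem sizes used by the test suite

The suite exercises the full protocol at reduced scale, chosen so the whole
run completes on one CPU: the behavioural tests train the reference model
at a 32 x 32 input on 60 patches per class over 12 cases per class
(slide-wise split, 10 test patches per class) for 8 epochs. At that scale
the synthetic classes are separated at macro-F1 >= 0.90 and the smoke
training loss falls within 5 epochs. Protocol cardinalities (4,400 / 632 /
880) are verified on manifests at the full reference counts, which needs no
image rendering. The micro-scale (8 x 8) fixtures exercise procedure
semantics — fold rotation, trial averaging, restore — where classification
quality is irrelevant.

## Known limitations

* Training at the full 224 x 224 protocol scale is supported but slow in
  this implementation (single-threaded C++ convolutions); the package's
  empirical claims are limited to the reduced-scale synthetic study above.
* Batch-norm statistics with batch size 4 are noisy; the plateau schedule
  and best-weight restore absorb most of the resulting validation jitter.
* The published per-variant FLOP figures other than the full model's are
  not reproducible jointly with the parameter ledger (see above); the
  ledger CSVs make every per-layer count auditable.
* The synthetic appearance model is deliberately simple; do not interpret
  synthetic-task metrics as estimates of real-slide performance.
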
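---
title: "Nested dilation networks for brain tumor segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested dilation networks for brain tumor segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gliomas are imaged with four MRI sequences per patient — T1, T2,
post-contrast T1 and FLAIR — and decompose into nested sub-regions: edema
(outermost), non-enhancing tumor core, and enhancing tumor (brightened by
contrast agent). `ndnseg` implements a complete, desk-scale version of a
coarse-to-fine 3D segmentation pipeline for this problem: preprocessing,
augmentation, a nested dilation network (NDN), class-imbalance-aware
objectives, a three-stage cascade, and connected-component post-processing.
The internal label coding is fixed at 0 = background, 1 = edema, 2 =
non-enhancing, 3 = enhancing; external codings (such as the BraTS 0/1/2/4
scheme) are handled by explicit bijective mapping tables at the I/O
boundary, since no universal on-disk numeric convention exists.

## Preprocessing

Each modality is z-score normalized per patient over the whole volume
(population standard deviation; channels with zero variance map to zeros).
Normalization runs before border cropping — the order is a package decision
made for determinism, as either order is defensible. Uninformative black
borders are cropped to the tight x/y bounding box of nonzero voxels, and
70% of axial slices are kept from the middle of the stack, computed as
`k = round(fraction * Z)` with the lower start index on ties. Training
patches (default 96×96×48; 32×32×16 at desk scale) are sampled by drawing
a center uniformly from tumor voxels, clamping the box into bounds, and
zero-padding any axis smaller than the patch. "Close to the ground truth"
admits many samplers; uniform-over-tumor-voxels is the simplest that
guarantees every patch contains tumor.

## Augmentation

Four label-consistent transforms run in the fixed order flip → rotate →
gamma → elastic (the order is a package choice; the operations themselves
and their ranges are standard): per-axis flips with probability 0.5;
in-plane rotation drawn from [−15°, +15°] (restricted to the axial plane
because the through-plane extent of brain volumes is much smaller than
in-plane, making 3D rotations destructive); gamma correction with γ ∈
[0.4, 1.6] applied in min-max space because inputs are z-scored and may be
negative; and elastic distortion, where the displacement field is
Gaussian-smoothed iid noise scaled by α (defaults α = 10 voxels, σ = 4
voxels — placeholders exposed in `augment_config()`, not reference values).
Intensities are interpolated linearly, labels nearest-neighbor, and
out-of-bounds voxels fill with zero, so the label alphabet can never grow.

## The network

The NDN is a three-level 3D U-Net variant. Residual blocks follow
`y = F(x, W) + x` with a path of two kernel-3 convolutions, each followed
by batch normalization and ReLU, and a 1×1×1 projection shortcut on channel
mismatch. Squeeze-and-excitation (SE) blocks pool each channel globally,
pass the channel vector through a bottleneck pair of fully connected layers
(ReLU then sigmoid, reduction ratio 16 floored at 1), and rescale channels
multiplicatively. Residual-nested-dilation (RnD) blocks chain three serial
dilated kernel-3 convolutions at rates (1, 2, 5) with a residual connection
across the triple; they sit on the first two encoder levels, where small
receptive fields starve the skip connections of context. The third encoder
level and the decoder use plain residual blocks ("the first two encoder
modules adopt RnD blocks" implies the rest do not). Every stage is followed
by an SE block; filters double per level from a base width of 16 (4 at desk
scale); skips fuse by concatenation; upsampling is nearest-neighbor resize
followed by a convolution; one residual block per decoder stack (the stack
depth is not pinned down by the method; 1 is the default, configurable). The final
1×1×1 convolution yields class logits under a softmax head. The head
convolution is initialized at one tenth of the He scale so a fresh network
is honestly uninformative (first cross-entropy on a balanced two-class
patch ≈ ln 2); the remaining convolutions use He-normal initialization.

### Hybrid dilated convolution checks

Stacked dilations with a common factor produce gridding: periodic holes in
the effective receptive field. Two rules guard against it: no pair
of rates may share a divisor greater than one, and the backward recurrence

M_i = max(M_{i+1} − 2 r_i, 2 r_i − M_{i+1}, r_i),  M_n = r_n

must keep M_i < K for all i < n. Three notes on fidelity. First, the
middle term of the recurrence is sometimes written as
M_{i+1} − 2(M_{i+1} − r_i), which simplifies to 2 r_i − M_{i+1}; the
simplification is implemented. Second, the bound is implemented as a strict
`<`, although parts of the hybrid-dilation literature use ≤. Third, M_i < K is checked for
i < n only — checking the last layer would reject the reference scheme
(1, 2, 5) itself. An independent brute-force oracle
(`gridding_coverage()`) composes the 1-D tap sets by Minkowski sum;
enumeration over all rate triples in [1, 6]³ at K = 3 shows the rules are
*sound* (no accepted scheme has holes) but *conservative*: 55 of 216
triples are hole-free yet rejected — e.g. (1, 2, 2) by the coprimality rule
and (3, 2, 1) by the distance rule, where a trailing rate-1 layer refills
earlier holes. The package therefore treats the rules as a design gate, not
a characterization, and the tests freeze exactly this relationship.

Receptive fields are computed analytically as
RF = 1 + Σ (K−1)·r·(product of preceding strides) and verified empirically
by measuring the nonzero support of an impulse response through
instantiated blocks with all-ones weights: 17 voxels per axis for an RnD
block at rates (1, 2, 5), 5 for a residual block.

### Engine

No deep-learning framework is used: layers (dilated 3D convolution, batch
normalization, ReLU, 2× max pooling, nearest-neighbor upsampling, dense)
carry explicit forward and backward passes, composed into blocks and the
full network. Convolutions run as im2col gathers over a zero-padded grid
feeding one BLAS matrix product (with a per-tap fallback above a memory cap
for large inference inputs, keeping the 96×96×48 forward under ~1 GB).
Gradients of the assembled network match central finite differences to
~1e-8 relative error, which the test suite spot-checks.

Normalization layers deserve a note. Training uses the current sample's
spatial statistics — with one-patch batches this is exactly instance
normalization. Inference defaults to the same per-input statistics rather
than running averages: patches and whole volumes have very different
activation statistics, and normalizing a test input by running averages
accumulated from tumor-centered training patches was observed to produce
large false-positive regions on some training runs. Running averages
(momentum 0.9) are still maintained and selectable (`stats_mode =
"running"`), and are what the impulse-response measurements use, since
fresh running statistics make normalization an identity.

## Objectives

Four losses operate on per-voxel class probabilities q against one-hot
truth p, with q clipped to [1e-7, 1] before any logarithm (the floor is a
package choice): categorical cross-entropy −(1/N) Σ p log q; a weighted
variant with per-class factors (1, 1, 2, 1) up-weighting the rare
non-enhancing class; the focal loss −Σ p (1−q)^γ log q / Σ p with γ = 2
(the exponent is read as applying to (1−q), the conventional grouping);
and a soft Dice loss. The Dice loss is often written with a
leading 1/N on the overlap fraction, which makes the loss ≈ 1 with
vanishing gradient scale at any realistic N — whether N there means voxels,
samples, or is a typo cannot be determined. The package defaults to the
canonical form 1 − 2Σpq / (Σp + Σq + ε), ε = 1e-5 in the denominator only,
and retains the printed variant as `mode = "as_printed"` for fidelity.
Background is included in the class sums by default (configurable). Every
loss has an independent scalar-loop reference used only by the tests.
Evaluation uses the Dice similarity coefficient 2TP/(FP + 2TP + FN) per
one-vs-rest class mask, with the both-empty case scoring 1 so benign cases
(no enhancing tissue) are well-defined.

## Cascade

Three binary problems replace the four-class one: stage 1 segments the
whole tumor {1,2,3}, stage 2 the tumor core {2,3}, stage 3 the enhancing
tumor {3}. Training crops derive from ground truth (the parent stage's
bounding box extended by 32 voxels in x and y and 8 slices in z); at test
time the crops derive from the previous stage's *predicted* mask instead —
two deliberately distinct code paths. Stage probabilities binarize at 0.5
(a package default). Fusion assigns the finest label that claims a voxel
(3 over 2 over 1), which also resolves nesting violations a noisy
predictor can produce; an empty stage-1 mask short-circuits to
all-background, and an empty stage-2 mask skips stage 3. With oracle
predictors that return ground-truth stage masks, the cascade reproduces
the ground truth voxel-exactly — a key identity the tests enforce on
phantoms, including clamped-box corner cases.

## Post-processing

Brain tumors in the target datasets form a single connected domain, so the
pipeline keeps only the largest 26-connected whole-tumor component (ties
break toward the first-discovered component) and relabels enhancing
clusters smaller than 200 voxels to non-enhancing. Both the connectivity
(26) and the threshold (200) are package defaults, not reference values,
and are exposed in configuration; relabeling (rather than deletion)
preserves the single-connected-domain property, with `mode = "delete"`
available. Component labeling is verified against a naive flood-fill
oracle on random grids for all three connectivities.

## Phantoms: what they emulate and what they do not

The generator builds 64×64×32 four-channel volumes: an elliptical brain
(semi-axes 28, 28, 14) of mean intensity 100, holding nested tumor
ellipsoids — whole tumor (13, 13, 9), core (8, 8, 5), enhancing (5, 5, 3)
— at a randomized center, with per-class means giving each channel a
clinically inspired contrast (enhancing bright in the post-contrast T1
channel, edema bright in the FLAIR channel), Gaussian noise of sd 10, and
exact zeros outside the brain so border cropping has work to do. The
enhancing ellipsoid (~300 voxels) deliberately exceeds the 200-voxel
post-processing threshold. A benign flag merges the enhancing region into
the core. The phantoms capture the *statistical and geometric structure*
the pipeline relies on — nested classes, modality contrast, a single
connected tumor, benign cases — but not MR physics: no bias fields,
partial-volume effects, texture, or anatomical variability. Passing tests
therefore demonstrate that the machinery is correct and trainable, not
that the reported clinical accuracies transfer; reproducing those requires
the external datasets and GPU-scale training, which are out of scope.

## Training

Adaptive moment estimation with first-moment decay 0.9 (the stated
"momentum"), second-moment decay 0.999, and weight decay 1e-5 implemented
as an L2 penalty on the gradients, matching the stated "L2 regularization".
The reference configuration (learning rate 1e-4, batch 4, patch 96×96×48,
300 epochs) requires a GPU; the desk profile used by the tests trains each
stage with base filters 4, patch 32×32×16, one patch per update, 250
updates, learning rate 3e-3, and flip+gamma augmentation only (rotation
and elastic warps cost more than they help on smooth phantoms; the higher
rate is what a ~10k-parameter network needs to converge in a few hundred
updates). The method prescribes no validation protocol, so the package
holds out 20% of cases and keeps the checkpoint with the best validation
Dice, evaluated every 50 updates. A non-finite loss aborts with a
diagnostic. All randomness flows through R's RNG, so a single `set.seed()`
reproduces datasets, training and predictions bit-identically.

Three sampling, objective and inference choices matter more than any
hyperparameter here; all address artifacts of patch-based training that
surface when a trained stage is applied to whole volumes.

*Sampling.* Purely tumor-centered patches teach the network a spurious
*location* prior ("tumor sits at the patch center") on some training runs,
which produces massive false positives outside that regime. Training
examples therefore anchor a patch on a uniformly drawn target voxel but
place that anchor at a uniformly random position *inside* the patch, and a
quarter of all draws (`neg_patch_prob = 0.25`) are instead placed
uniformly in the parent region regardless of content, so tumor-free tissue
is in-distribution. Every anchored patch still contains target tissue,
preserving the "close to the ground truth" sampling idea; `sample_patch()`
itself keeps its plain tumor-centered contract.

*Objective.* The training Dice loss excludes the background channel
(`dice_exclude_background = TRUE`): for the later cascade stages the
target covers a few percent of a patch, and with background included an
all-background prediction is already near-optimal. Foreground-only soft
Dice in turn has exactly zero gradient on patches whose target is empty —
the negative patches would teach nothing — so a 0.3-weighted auxiliary
cross-entropy term (the common Dice+CE compound) restores a per-voxel
signal everywhere. The weight is kept well below 1 so the
background-dominated CE does not drown the small-foreground Dice signal
early in training.

*Inference.* Whole-volume prediction slides windows of the training patch
size at half-window stride and averages overlapping probabilities, rather
than forwarding the full volume at once: activations — including the
per-input normalization statistics — then match the scale the network was
trained at, and a small structure that a non-overlapping grid would cut
into corner slivers sits well inside at least one window (on phantoms this
single choice moved enhancing-tumor Dice from ~0.4 to ~0.9 for the same
trained weights).

Problem sizes in the shipped tests: the loss-oracle suite uses 100 random
1000-voxel fields; the cascade and post-processing identities use 10
phantoms each; the end-to-end check trains the full three-stage cascade on
20 phantoms and evaluates on 5 held-out ones — small enough for a single
CPU, large enough that an incorrect gradient, cascade crop, or fusion rule
fails loudly.

## Known limitations

The engine is CPU-bound R; paper-scale training is out of reach by design.
Batch normalization statistics come from single patches at desk scale,
which adds noise to early validation scores. The HDC rules reject some
hole-free schemes (see above) — a deliberate fidelity choice.
Multi-focal tumors conflict with the single-connected-domain assumption and
are intentionally not generated.
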
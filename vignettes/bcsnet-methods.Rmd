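---
title: "Scoring dairy-cattle body condition from tail images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dairy-cattle body condition from tail images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Body condition scoring (BCS) grades a cow's fat reserves on an ordinal
scale; it predicts metabolic disease risk, fertility and milk yield, but
manual scoring is slow and subjective. The morphology of the tail root is a
compact visual proxy: lean animals show a deep depression flanking the base
of the tail, well-conditioned animals a flat or slightly convex tail root.
`bcsnet` implements an image-classification pipeline around this cue: five
ordinal classes at scores 3.25, 3.50, 3.75, 4.00 and 4.25, read from a
cropped tail region of a rear-view photograph.

The package targets two audiences: practitioners who want a small,
edge-deployable classifier family with exact resource accounting, and
methodologists who want the individual components — channel and spatial
attention, label smoothing, knowledge distillation, Grad-CAM — as clean,
testable functions.

## Model family

### Backbones

`build_backbone()` constructs six standard mobile architectures
(EfficientNet-B0, MobileNetV3-Large/Small, MobileNetV2, SqueezeNet 1.1,
ShuffleNetV2 x1.0) layer-for-layer at their reference configurations, with
only the final classifier resized to five outputs (SqueezeNet classifies
with a 1x1 convolution, which is resized instead). Because every layer is
encoded explicitly, trainable-parameter counts are exact; with the 5-class
head they are 4.01, 4.21, 2.23, 1.52, 0.73 and 1.26 million respectively,
and serialized size follows the float32 convention
`parameters * 4 bytes / 2^20` MiB. Parameter counting includes weights,
biases and normalization scale/shift, and excludes running statistics.

FLOP counts sum `H_out * W_out * K_h * K_w * C_in/groups * C_out` over
convolutions plus `in * out` over linear layers. Published FLOP figures
depend on the counting tool's convention (whether normalization,
activations and pooling are charged, and whether a multiply-accumulate is
one or two operations), so `count_flops()` is reported as informational
profiling, never as a comparison surface.

### Attention blocks

The squeeze-and-excitation (SE) block computes per-channel global averages,
squeezes them through a bottleneck of two biased projections (`C -> C/r`,
ReLU, `C/r -> C`, sigmoid) and rescales each channel by the resulting gate
in (0,1). The composite models place one SE block with reduction `r = 16`
on the final 1280-channel feature map; this adds 206,160 parameters
(+0.21 M), which is how the placement and reduction were identified — it is
the configuration consistent with the published parameter delta.

The spatial attention block concatenates the channel-wise mean and max maps,
convolves them with a single 7x7 kernel (padding 3, bias), and multiplies
the sigmoid mask over all channels. This kernel has exactly
`7*7*2 + 1 = 99` parameters. Published figures for a spatial module
sometimes quote ~0.07 M, which cannot arise from this definition; the block
here follows the equation, and the discrepancy is left documented rather
than guessed at with undisclosed extra layers.

With zero weights both blocks gate at exactly sigmoid(0) = 1/2 — a useful
identity that the tests exploit. Note one boundary subtlety: with zero
padding, the spatial mask of a spatially constant input is constant only
away from the border, where the 7x7 window sees identical values.

### Classification heads

The default head is global average pooling plus a linear layer. The
alternative convolutional head replaces the fully connected classifier with
a light depthwise-separable stack: 1x1 pointwise to 512 channels, 3x3
depthwise, 1x1 pointwise to 1280, each with batch normalization and SiLU,
then pooled and projected to the class logits. The channel widths are an
architectural choice made once for plausibility with the backbone's width;
published parameter totals for such a head could not be decomposed from
their description, so no attempt was made to tune widths toward them.

### Ablation presets

`ablation_config("A1")` ... `"A8"` name the family: A1 the bare backbone
with linear head and cross entropy, A2 +SE, A3 +spatial, A4 label smoothing
only, A5 convolutional head only, A6 SE+spatial, A7 A6 with label
smoothing, A8 everything. A4/A7/A8 differ from their cross-entropy
counterparts only in the training loss, not in architecture — their
parameter counts are identical by construction.

## Losses

Targets are smoothed as `ytilde = (1 - eps) y + eps/K` with `eps = 0.1` by
default (the conventional value); the loss is `-sum ytilde_i log p_i` with
natural logarithms, and probabilities are floored at 1e-12 before the log
as a numerical guard. With `eps = 0` this is exactly cross entropy.

The distillation objective is
`alpha * T^2 * KL(softmax(t/T) || softmax(s/T)) + (1 - alpha) * CE(softmax(s), y)`
with the teacher as the reference distribution (forward KL) and its logits
treated as constants. The `T^2` factor keeps the soft-term gradient
magnitude comparable across temperatures. Defaults `T = 4`, `alpha = 0.7`
are conventional; the source method names the framework but not its
constants, so both are exposed as configuration and no downstream claim
depends on their exact values.

## Training

`train_model()` minimizes the configured loss with Adam (beta1 0.9, beta2
0.999, eps 1e-8), restores the weights of the best validation epoch, and
applies early stopping: an improvement must exceed `min_delta` to reset the
patience counter, so an improvement of exactly `min_delta` counts as none.
Training is a pure function of the initial weights, the data and the config
seed — batch shuffling is the only stochastic element and it is driven by
that seed. A learning rate of exactly 0 is allowed and leaves the weights
bit-identical, which the tests use as a no-op control. `grid_search()`
trains one model per configuration and picks the highest validation
accuracy, ties to the first configuration in the declared order.

The full backbones are far too large to train usefully in pure R;
`build_small_cnn()` provides the desk-scale workhorse — three 3x3
convolution blocks, max pooling, global average pooling and a linear
classifier, ~60k parameters. Two options matter in practice:

- `batchnorm = TRUE` inserts batch normalization after each convolution.
  On inputs where the informative region is a small fraction of the image
  (full scenes rather than tail crops), plain networks of this size are
  sensitive to initialization and can stall at chance level; batch
  normalization removes that sensitivity. The tests train the crop
  classifier without it and the scene classifier with it.
- `extra_pool = TRUE` adds a third pooling stage, appropriate at input
  sizes of 48 and above.

## Synthetic data: what it emulates, what it does not

No image of a real cow ships with the package. `generate_tail_image()`
draws a schematic scene: a bright body ellipse on a darker gradient
background, a vertical elongated tail, and two elliptical depressions
flanking the tail root whose shading intensity is the class-conditional
parameter. The default depths 0.9, 0.7, 0.5, 0.3, 0.1 (lean to fat) encode
the single fact the method rests on — depression depth decreases
monotonically with body condition. Nuisance variation is additive Gaussian
pixel noise (sd 0.05 on the 0-1 scale) and a multiplicative brightness
jitter of +/-10%, plus small geometric jitter of the tail position and
size. Images are 256x256 before cropping so that bounding-box cropping and
resizing are real operations, and every image is a pure function of
(class, spec, item seed).

What passing tests on this corpus demonstrate: that the training loop can
extract a class-ordered shading cue under noise and lighting variation,
that distillation transfers that ability to a smaller student, and that
Grad-CAM attributes the decision to the region that carries the cue. What
they do not demonstrate: robustness to breed, pose, occlusion, dirt,
multi-animal scenes or any other structure of real farm imagery — the
generator deliberately contains none of it.

## Evaluation conventions

Confusion matrices have actual labels in rows and predictions in columns.
Precision, recall and F1 are macro-averaged with the 0/0 -> 0 convention.
Macro (rather than frequency-weighted) averaging was chosen because
weighted recall is algebraically identical to accuracy, and published
tables in this setting report recall differing from accuracy — macro is
the standard convention consistent with that. Tolerance accuracy counts
predictions within +/-0.25 or +/-0.5 of the true score, with an absolute
1e-9 epsilon so that 0.25-step float arithmetic never flips a count; at a
tolerance of 1.0 it is 100% by construction since the extreme classes are
1.0 apart.

## Grad-CAM

`grad_cam()` implements the original formulation: channel weights are the
spatially averaged gradients of the target-class logit with respect to a
convolutional feature map (by default the last one before pooling), the raw
map is the ReLU of the weighted channel sum, bilinearly upsampled to the
input and min-max normalized, with an identically zero map left at zero.
For misclassified inputs the predicted class's logit is explained, since
that is the decision the explanation should account for. The quantitative
localization check compares heatmap mass inside the generator's tail
bounding box against equal-area random boxes on correctly classified
scenes; a mean ratio above 1 is the package's stand-in for "the model looks
at the tail root", and in practice the trained scene classifier yields
ratios above 2.

## Problem sizes and numerical choices

The shipped experiments use sizes chosen to keep a full run on one CPU in
minutes: the crop-classification corpus is 100 images per class at input
32 (70/20/10 split), trained at most 20 epochs with Adam at learning rate
1e-2 and batch 32; the distillation student shrinks the channel widths to
8/16/16 (~61% of the teacher's parameters, trained up to 30 epochs — the
narrower the student, the more seeds land in poor optima, and this width is
the reliable point); the Grad-CAM scene corpus is 60
images per class at input 48 with the batch-normalized scene classifier.
Dataset splitting takes floors for the training and validation fractions
and gives the remainder to the test split — the only simple rule consistent
with published 70/20/10 counts at large corpus sizes. Image resizing is
half-pixel-centered bilinear interpolation; preprocessing scales
intensities to [0,1] and normalizes channels with the standard RGB
constants (means 0.485/0.456/0.406, sds 0.229/0.224/0.225) of the
pretrained-backbone input pipeline. Checkpoints use R's native
serialization via `save_model()`/`load_model()`.

Dropout layers appear in the backbone encodings where the reference
architectures place them, for parameter and structure fidelity, but act as
identities here: nothing at this package's training scale benefits from
active dropout, and keeping them inert preserves exact seeded determinism.

## Command-line interface

`inst/cli/bcsnet.R` wraps `cli_main()`, which dispatches `generate`,
`split`, `train`, `distill`, `evaluate`, `profile`, `explain` and
`ablation`. Every run writes a `run_manifest.json` (options, seed, package
version, outputs, timestamp) before long computation starts, so a run can
be replayed from its output directory alone. The `ablation` table reports
the A1-A8 structural columns (attention, loss, head, parameters, size,
FLOPs), which are the desk-verifiable part of the published ablation; the
classification-metric columns of that experiment require training the full
EfficientNet variants on the real corpus and are out of scope here.

## Known limitations

- The layer kernel is pure R. Forward passes of the full backbones are
  feasible (seconds at moderate input sizes); training them is not — the
  trainable surface at desk scale is the small CNN family.
- The synthetic generator encodes one discriminative feature. Results on it
  bound nothing about real-world accuracy; they validate the machinery.
- FLOP and latency figures are profiling aids with explicit convention
  caveats.
- The spatial-attention mask is only border-exact up to the zero-padding
  effect noted above, matching the standard definition.
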
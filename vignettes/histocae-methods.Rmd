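---
title: "Methods: CAE-based patch classification for viable-tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAE-based patch classification for viable-tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(histocae)
```

## The model

Viable-tumor segmentation in whole-slide images (WSIs) is posed here as
patch-wise classification. A slide $I \in \mathbb{R}^{M \times N \times 3}$
is divided into non-overlapping square patches $p_{ij}$ of 256 px on a
uniform grid with stride 256; each patch is classified tumor vs non-tumor
and the labels are painted back onto the grid to form the segmentation
mask. This sidesteps the failure mode of pixel-wise networks on tumor
masks riddled with small vascular gaps: a patch-level decision is robust
to sub-patch holes, and the 30 % labelling rule (below) defines exactly
how much tumor makes a patch "tumor".

Two modules share one encoder:

* **Autoencoder** $h_{CAE} = \{h_E, h_D\}$. The encoder $h_E$ has four
  convolutional stages with depths 16, 32, 64, 64. Each stage is a 3×3
  stride-1 convolution with ReLU followed by batch normalisation, then a
  3×3 stride-2 convolution with ReLU and batch normalisation —
  downsampling by strided convolution, not pooling, so spatial detail
  survives into the bottleneck. Four stages halve the input four times:
  a 256×256×3 patch becomes a 16×16×64 bottleneck map. The decoder
  $h_D$ mirrors the encoder with four stride-2 transposed-convolution
  stages and ends in a 1×1 convolution with a sigmoid so reconstructions
  live in $[0,1]$.
* **Classifier** $h_{CL} = \{h_E, h_C\}$. The head $h_C$ applies one 3×3
  stride-2 convolution (ReLU, batch normalisation) to the bottleneck,
  flattens, applies dropout at rate 0.7, and a single dense layer with a
  2-class softmax.

Training is two-phase: $h_{CAE}$ is fitted first on the reconstruction
loss; its encoder weights then initialise $h_{CL}$ **without freezing** —
the whole classifier, encoder included, is updated in phase 2.

### Reconstruction loss

The reconstruction objective is a weighted sum

$$l_R = \alpha\, l_{MSE} + \beta\, l_{SSIM} + \gamma\, l_{MAE},
\qquad \alpha = \beta = \gamma = 0.5,$$

with $l_{SSIM} = 1 - \mathrm{SSIM}(x, \hat x)$. MSE alone reconstructs
blurry patches and loses the cellular structure that matters for
discriminating tumor texture; the SSIM term explicitly rewards preserving
local luminance/contrast/structure, and the MAE term adds an outlier-
robust intensity match. All seven single/pairwise/triple combinations are
expressible by zeroing weights in `lossConfig()`.

Two printed forms of the MSE coexist: the raw double sum over batch and
pixels, and the per-pixel mean (the MAE is printed as a mean). `mseLoss()`
implements both (`mseMode`); **training defaults to the per-pixel mean**
because a raw sum over $256 \times 256 \times 3 = 196{,}608$ pixels is
five orders of magnitude larger than the SSIM term and would drown it.
The literal-sum form is retained for exactness tests.

SSIM follows the standard reference parameterisation — 11×11 Gaussian
window with $\sigma = 1.5$, $k_1 = 0.01$, $k_2 = 0.03$, dynamic range
$L = 1$ (all images are stored as $[0,1]$ doubles regardless of source
bit depth), unit exponents on the luminance, contrast and structure
terms, and stabilisers $C_1 = (k_1 L)^2$, $C_2 = (k_2 L)^2$,
$C_3 = C_2/2$. Windows are taken over the valid region only, so no
padding convention enters the value. Whether the comparison runs per RGB
channel (averaged) or on the luma image is configurable; the default is
the per-channel mean. The package computes the analytic gradient of the
windowed SSIM mean (the adjoint of the windowing operator applied to
three derivative maps), verified against finite differences in the test
suite.

### Classification loss

Cross-entropy $l_C = -\frac{1}{M}\sum_c y_c \log \hat y_c$; probabilities
are clamped at $10^{-12}$ so saturated predictions remain finite.

### Multi-resolution fusion

A WSI pyramid provides 5×/10×/20× levels related by exact 2×
downsampling. Three autoencoders — one per magnification — are pretrained
separately; co-registered patches (the 10× and 5× patch centers are the
20× center divided by 2 and 4, rounded toward zero) are encoded, and each
bottleneck passes through four 3×3 stride-2 convolutions of depths 128,
256, 512, 512 with ReLU and batch normalisation. With a 16×16 bottleneck
the spatial trace is 16→8→4→2→1, so each branch flattens to a vector of
exactly 512 and the three branches concatenate to 1536 — both lengths are
asserted at build time from the real tensor shapes, not assumed. Three
dense layers (ReLU, batch normalisation, dropout 0.7) feed the final
softmax. The whole model trains multi-task, minimising
$w_r(\sum_{m} l_R^{(m)}) + w_c\, l_C$ with default weights
$w_r = w_c = 1$ (exposed in `trainConfig(mrLossWeights = )`).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `patchSize` | 256 px (slide scale) | tile edge; non-overlapping grid, stride = patchSize |
| label threshold | 0.30, inclusive | tumor coverage at or above which a patch is tumor |
| `maxArea` (mask closing) | 50 px, inclusive | enclosed background components up to this area are filled |
| α, β, γ | 0.5 each | joint-loss weights |
| epochs / batch | 200 / 64 (slide scale) | per training phase |
| ADAM lr | 1e-4 (slide scale) | learning rate |
| ADAM β₁ | 0.05 | first-moment decay (the optimiser's single quoted "beta"; β₂ stays 0.999) |
| dropout | 0.7 | fully connected layers only, off at inference |
| augmentation | rotations (multiples of 90°), h/v flips | label-preserving by construction |
| CV folds | 5 | split by slide so no slide leaks across a fold |

## Coordinate and tiling conventions

Grids are 0-based, (row, col), top-left origin, half-open pixel ranges,
row-major cell order. Border strips narrower than a patch are dropped —
the patch count is $\lfloor H/s\rfloor \times \lfloor W/s\rfloor$ — so
tile → stitch is bit-exact on slides whose dimensions are multiples of
the patch size. Hole filling in ground-truth masks labels *background*
components with 4-connectivity (diagonal background pixels do not leak a
hole to the border) and fills only enclosed components of area ≤ 50;
foreground is never removed, so the operation is monotone and idempotent.

## The synthetic fixture and what it shows

The package must be exercisable without the original challenge WSIs, so
`generateSlide()` emulates the *geometry* of the task: a light "tissue"
texture with darker, smoothly elliptical "tumor" blobs drawn until a
target area fraction (0.30 ± 0.05) is met, i.i.d. pixel noise on top, a
3-level pyramid by exact 2× area averaging, and masks downsampled by 2×2
majority vote (ties to tumor so thin structures survive). Everything is
determined by the seed.

`generatePatchDataset()` draws balanced classes and keeps only patches
whose tumor fraction is bounded away from the 0.30 threshold (tumor
≥ 0.5, tissue ≤ 0.1): the classes are then separable by construction, as
a synthetic stand-in should be. Patches straddling the blob boundary —
the genuinely ambiguous ones — are not hidden: they enter through
whole-slide evaluation, where every tile of a fresh test slide is
predicted and the assembled mask is scored against the block-quantized
ground truth.

What passing desk-scale tests does **not** show: H&E stain variation,
nucleus-scale texture, scanner artifacts, necrosis/stroma look-alikes, or
class imbalance at the slide level. The fixture validates the plumbing
and optimisation of the method, not its clinical performance.

## Desk-scale study sizes

Tests and the acceptance script run the pipeline end to end at sizes
chosen for a single CPU: 2048×2048 synthetic slides tiled at 32 px (a
64×64 grid), 250 patches per class with a 400/100 train/held-out split,
autoencoder 200 patches × 20 epochs, classifier 30 epochs, both at ADAM
learning rate 1e-3 (the short-schedule counterpart of the slide-scale
1e-4/200-epoch profile; β₁ stays 0.05). The architecture is unchanged —
a 32-px patch simply yields a 2×2×64 bottleneck, and the
patch-to-bottleneck element ratio stays exactly 12:1 at every input size
($3 \cdot 16^2 / 64$). Shape claims tied to the 256-px reference size
(16×16×64 bottleneck, 512/1536 fusion lengths) are checked by building
the reference models and reading tensor shapes.

## Numerical choices

* **Engine.** Convolutions are im2col GEMMs; the im2col gather is a
  precomputed sparse 0/1 matrix whose transpose is the backward
  scatter-add, and batches are stored channel-fastest so bias and
  batch-norm terms broadcast by column recycling. Transposed convolutions
  reuse the mirror convolution's machinery with forward and backward-data
  swapped. All layer gradients are finite-difference-checked in the test
  suite.
* **Padding.** Stride-2 "same" convolutions pad by the ceil(H/2)
  convention (extra row/column at bottom/right), which is what makes four
  stages map 256 → 16 exactly and the fusion branches map 16 → 1.
* **Batch norm.** Population statistics per channel, momentum 0.1 running
  estimates during training, ε = 1e-5. After the last epoch every training
  routine *recalibrates* the running statistics with one pass over the
  training inputs under the final weights ("precise" batch norm): the
  momentum average lags the weights by construction, and on low-variance
  inputs that lag makes inference disagree sharply with training-mode
  outputs. Recalibration makes inference consistent; exactly constant
  inputs remain degenerate for any batch-norm network (zero variances put
  the normaliser on a knife edge), which is why the toy fixtures carry a
  little pixel noise.
* **Initialisation.** He-scaled Gaussian weights, seeded; parameter
  counts are deterministic and seed-independent.
* **Dropout** is inverted (scaled at train time), off at inference, so
  repeated predictions are identical.
* **Degenerate inputs.** Empty patch sets, single-class training data,
  sub-patch slides, epoch-0 configs and shape mismatches raise immediate
  errors (sub-patch slides tile to an empty grid with a warning, as a
  border case of the drop-partial rule). Dice of two empty masks is
  defined as 1; metric ratios with zero denominators are reported as 0
  and flagged.

## Design decisions on open points

* The single-resolution head is described only as "one convolutional
  layer" plus dropout-bearing fully connected layers; this package uses
  conv → flatten → dropout → dense(2) → softmax, the smallest structure
  consistent with both statements.
* The decoder's final activation is a sigmoid (reconstructions must live
  in the loss's [0,1] dynamic range); its inner structure mirrors the
  encoder since only "four deconvolution layers" is fixed.
* The optimiser's quoted single "beta value of 0.05" is taken as β₁,
  with β₂ left at its conventional 0.999; both are configurable.
* Multi-resolution ground truth is labelled independently per
  magnification with the same 30 % rule; the sample's label is the 20×
  one.
* Random rotation is restricted to multiples of 90° so patches need no
  padding and labels are exactly preserved.
* Five-fold cross-validation splits by slide, not by patch, to avoid
  leakage between folds (`cvFolds()`).
* Compressed slides are serialized with R's native format, cells indexed
  by (row, col); the feature values are kept as doubles and the element
  ratio (12:1) is the quantity of interest, not byte-level codec size.

## Known limitations

* Pure-R training is desk-scale: minutes for tens of epochs on 32-px
  patches, not hours on 256-px patches across 60 000 WSI tiles. The
  slide-scale profile (256-px patches, 200 epochs, batch 64, lr 1e-4) is
  expressible in `trainConfig()` but compute-bound.
* SSIM gradients are implemented for unit exponents (the standard form);
  non-unit exponents are available for the SSIM *value* only.
* Batch-norm statistics make per-sample outputs depend on batch
  composition during training (standard behaviour); determinism holds at
  fixed seed and config.
* The synthetic fixture's separability means accuracy near 1 is expected
  on it; it is a correctness harness, not a benchmark.
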
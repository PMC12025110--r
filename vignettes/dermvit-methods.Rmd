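---
title: "DermViT in R: model, training protocol, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DermViT in R: model, training protocol, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Dermoscopic skin-lesion classification is complicated by lesion-background
entanglement, high intra-class variability, strong class imbalance, and
imaging artifacts (hairs, ruler markings, immersion bubbles). DermViT is a
four-stage vision-transformer backbone whose three building blocks each
target one of these difficulties:

* **Dermoscopic Hierarchical Attention (DHA)** — two-stage routed
  attention. The token map is tiled into an $n \times n$ grid of $N = n^2$
  regions. Region-level queries and keys are the arithmetic means of the
  region's tokens, $Q_r = \mathrm{GAP}(Q)$, $K_r = \mathrm{GAP}(K)$, and
  the region affinity $S = Q_r K_r^\top$ (no softmax, no scaling) scores
  region pairs. Each query region keeps only its top-$k$ regions; each of
  its tokens then attends over the retained regions' tokens with ordinary
  scaled dot-product attention
  $\mathrm{softmax}(q K_t^\top / \sqrt{d})\, V_t$. Tokens attended per
  query are $k \cdot HW/N$ instead of $HW$, so computation falls whenever
  $k < N$ and attention never mixes in discarded background regions.
* **Dermoscopic Context Pyramid (DCP)** — each stage's downsampler. A
  convolution with kernel = stride compresses the map; keys and values are
  adaptively average-pooled to the grid sizes $s \in \{1, 2, 4, 16\}$
  (clamped to the map) and concatenated, and the full-resolution queries
  attend over this compact multi-scale token set. The $s = 1$ token is the
  exact global mean of the map; larger $s$ retain progressively finer
  layout information.
* **Dermoscopic Feature Gate (DFG)** — the FFN replacement. A $1\times 1$
  convolution expands $C \to 2h$ channels and splits into a content half
  $X_1$ and a gate half $V$; the content half is refined by a $3\times3$
  depthwise convolution and ReLU, multiplied elementwise by the gate, and
  projected back to $C$ channels with dropout. With $h = 2C$ this costs
  $6C^2 + 25C$ parameters against the standard 4x FFN's $8C^2 + 5C$ — a
  saving for every $C > 10$ (at very small widths, e.g. $C \le 10$, the
  depthwise and bias terms dominate and the ordering flips; all configured
  widths are far above the crossover).

A stage applies one DCP unit, then `depth` residual blocks of
pre-norm DHA followed by pre-norm DFG. The head is layer norm, global
average pooling, and a linear classifier. Ablation switches reduce each
block to its conventional counterpart (dense multi-head attention — realized
exactly as a $1\times1$ region grid; plain strided convolution; 4x FFN),
which reconstructs the usual ablation ladder structurally.

## Design choices where the architecture was open

* **Region order and multi-head routing.** Regions are row-major tiles with
  row-major tokens inside each tile, and routing is computed independently
  per head and per image, which matches the per-head shape of the
  projections. Top-k ties break toward the lowest region index (stable
  sort), making routing reproducible.
* **Closures around attention.** Both attention blocks get a learned output
  projection after head concatenation, and DHA/DFG blocks sit behind
  pre-norm residual connections — without residuals a four-stage cascade of
  this depth does not train. The DCP attention also gets a layer norm after
  the compression convolution and a residual connection from the compressed
  map: at initialization pyramid-attention weights are nearly uniform, so
  without the residual every stage would replace its input with an almost
  spatially constant map and gradient signal through depth collapses; the
  residual preserves the compressed features and lets the attention grow in.
  The exported `dcpForward()` keeps the bare compress-pool-attend
  composition as the reference semantics.
* **Q/K/V source in DCP.** All three are projected from the compressed map;
  only K and V are pyramid-pooled, so queries keep their spatial
  coordinates and the output has the compressed resolution.
* **No positional encodings.** Local structure enters through the
  convolutional components (compression conv, depthwise conv in the gate);
  attention is permutation-equivariant on top of that.
* **Grid clamping.** A configured region grid that does not divide a
  stage's map is clamped to the largest divisor of the map size, and top-k
  to the resulting region count, so one stage plan serves any input size
  whose total stride divides it.
* **DFG width.** The expansion is annotated ambiguously in two adjacent
  forms; this implementation expands to $2h$ with $h = 2C$ and splits into
  two $h$-channel halves, which is consistent with both annotations. ReLU
  sits after the depthwise convolution and before the gate product; dropout
  rate defaults to 0.1.

## Numerical choices

* Softmax rows are stabilized by subtracting the row maximum; a NaN after
  softmax raises an error rather than propagating.
* Routed attention is executed in one of three mathematically equivalent
  forms: dense (k = N), region-masked dense scores with $-\infty$ on
  non-retained pairs (small maps; masked weights are exactly zero), or an
  explicit per-query-region gather (large maps, memory-bounded). Tests pin
  the equivalence of all three against the reference op composition and a
  brute-force dense oracle.
* Layer norm uses $\epsilon = 10^{-5}$; AdamW uses $\beta = (0.9, 0.999)$,
  $\epsilon = 10^{-8}$, with decoupled weight decay applied to weight
  matrices only (biases and norm parameters exempt).
* Adaptive average pooling uses the conventional bin boundaries
  $(\lfloor (i-1)L/g \rfloor, \lceil iL/g \rceil]$; pooling is expressed as
  a precomputed averaging matrix, so its backward pass is its transpose.
* All randomness (weight init, splits, shuffling, augmentation, dropout,
  the synthetic generator) flows from explicit integer seeds; identical
  seeds reproduce identical histories bit for bit.

## Training protocol

The protocol is class-weighted cross-entropy (inverse-frequency weights
$w_c = n/(K n_c)$, normalized by the sum of sample weights, so the
sample-weighted mean weight is exactly 1), AdamW with initial learning rate
$2\cdot10^{-4}$ and weight decay $2\cdot10^{-4}$, cosine annealing to 0.01
of the initial rate across the scheduled epochs (100 by default), batch
size 32, stratified 0.8/0.05/0.15 splits with largest-remainder rounding,
random horizontal/vertical flips and a uniform $\pm30°$ rotation with
reflect-padded bilinear resampling, and ImageNet channel normalization.
Model selection is by validation accuracy. Undefined per-class precision or
recall counts as zero; MAUC is the macro-averaged one-vs-rest ROC AUC over
the classes present in the truth.

Desk-scale runs in the tests and the acceptance script shrink the problem,
not the protocol: 32 px synthetic images, a reduced stage plan (channels
16-128 or 32-256, depths 1/1/2/1), and short schedules (20 epochs for the
recoverability study, up to 200 single-batch epochs for the overfit sanity
check). Two deviations from the full-size protocol defaults are deliberate
at this scale and are the package's own choice: short schedules use a
higher initial learning rate (the 100-epoch rate of $2\cdot10^{-4}$ moves a
freshly initialized network too little in a few hundred AdamW steps), and
the overfit check disables augmentation (memorization of 32 fixed images is
the point of that check).

## The synthetic generator

The generator emulates the ISIC archive layout (PNG images plus a one-hot
CSV ground-truth manifest) and the gross structure of dermoscopy images: a
skin-toned background with an illumination gradient and fine noise; one
class-conditional lesion per image rendered as a rotated ellipse whose
radius is modulated by a random low-order Fourier series (border
irregularity), with a class base hue, radial darkening, and class-dependent
counts of darker variegation blobs; and artifact overlays — cubic-Bezier
hair strokes, a ticked ruler bar, and bright bubble rings — drawn on the
image but never into the lesion mask. Class styles follow coarse clinical
stereotypes (e.g. melanoma dark, irregular, variegated; vascular lesions
red and round; benign keratosis light tan). Lesion area is constrained to a
configurable fraction band (default 5-40%) with bounded retries. Class
proportions default to the archive-like imbalance of the 7-class setting.

What passing tests on these data do show: the blocks compose into a
trainable classifier; the training loop, metrics, and Grad-CAM plumbing are
correct; lesion-discriminative signal is recoverable and localized. What
they do not show: performance on real dermoscopy — the generator's classes
are separable mainly by color and border statistics at low resolution, with
none of the pathology-level texture that makes the real task hard, so
accuracies here say nothing about accuracies on ISIC data.

## Grad-CAM

Heatmaps weight a chosen stage's activations by the spatial mean of the
class-logit gradient per channel, rectify, upsample bilinearly and min-max
normalize; an all-zero rectified map is returned as zeros, and its mask
overlap is defined as 0. Overlap is the fraction of heatmap mass inside the
lesion mask — invariant to positive rescaling, and equal to the mask area
fraction for a uniform map, which makes the uniform-heatmap baseline the
natural reference. The default stage is the last one (pre-head features);
at 32 px input the last two stages are 2x2 and 1x1 maps, so localization
studies use stage 2 (the deepest stage with at least a 4x4 map at that
input size).

## Known limitations

* Pure-R execution: forward/backward passes are BLAS-bound loops, fine at
  desk scale (a 20-epoch, 600-image run takes minutes), not for full-size
  224 px training.
* The pooled-token budget $\sum_i \min(s_i,H)\min(s_i,W)$ undercuts $HW$
  only once the map exceeds the largest scale; on maps of 16 px or smaller
  the default scale set is larger than the map itself, where the pyramid
  adds cost rather than saving it (the clamp keeps it bounded).
* The full-size stage plan reproduces the budget *regime* of the published
  architecture (11.8 M parameters, 2.2 G MACs at 224 px against the
  published 16.8 M / 2.75 G), not an exact budget, since per-stage
  hyperparameters are not fully determined and the gated feed-forward is
  lighter than a 4x FFN.
* The generator is a layout-and-morphology emulator, not a photorealistic
  simulator; see above for what that limits.
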
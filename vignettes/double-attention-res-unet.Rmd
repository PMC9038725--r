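---
title: "The double attention residual U-Net: model, assumptions and design choices"
author: "daresunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The double attention residual U-Net: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation problem

Clinical targets in ultrasound, colonoscopy and MRI frames — a fetal
crown-rump extent, a polyp, a prostate — are bright-ish, soft-edged
structures embedded in textured, low-contrast, noisy backgrounds.
`daresunet` implements a two-stage encoder–decoder segmentation model
for such single-target binary problems: two structurally identical
attention-gated residual U-Nets are run in sequence, the second one
seeing the input re-weighted by the first one's output.

Writing the encoder, residual bottleneck, decoder and attention-gate
stages of network $i$ as $E_i$, $R_i$, $D_i$ and $AG_i$, the
composition is

$$
y_1 = \mathrm{head}_1\!\big(D_1(\mathrm{Concat}(AG_1),\, R_1(E_1(x)))\big),
\qquad
y_2 = \mathrm{head}_2\!\big(D_2(\mathrm{Concat}(AG_1, AG_2),\, R_2(E_2(y_1 \odot x)))\big).
$$

Two couplings make this more than two independent networks. First, the
input of the second network is the element-wise product $y_1 \odot x$:
the first network's sigmoid output acts as a *salient map* that
suppresses background before the second network segments. Second, every
decoder block of the second network concatenates the attention-gated
skip features of *both* encoders at its scale, so the final loss
back-propagates into every parameter of both networks. Both couplings
are exercised by the test suite (the gradient-completeness check
verifies that a single optimization step moves every layer group of
both networks).

## Network template

Each network has:

* **Encoder** — five blocks of (5×5 convolution, stride 2, "same"
  padding) → batch normalization → leaky rectifier with negative slope
  0.2, with 20, 40, 80, 160 and 320 filters. Each block halves the
  spatial dimensions (`ceil(n/2)`), which is why inputs must be
  divisible by $2^5 = 32$ (see *Preprocessing*).
* **Residual bottleneck** — four blocks computing $H_k = F(H_{k-1}) +
  H_{k-1}$ where $F$ is conv(5×5, stride 1, 320 filters) → batch-norm →
  conv → batch-norm, deliberately with *no* nonlinearity after the
  second convolution. Zeroing the branch weights makes the stack an
  exact identity, which the tests assert to machine precision.
* **Attention gates** — one per decoder scale. For a skip feature map
  $x^l$ (channels $F_l$) and a coarser gating signal $g$ (channels
  $F_g$, half the resolution), the gate computes
  $$
  q = \psi^\top \sigma_1\!\big(W_x^\top x^l + W_g^\top \mathrm{up}_2(g) + b_g\big) + b_\psi,
  \qquad \alpha = \sigma_2(q),
  $$
  with 1×1 convolutions $W_x$ ($F_l \to F_{int}$, no bias), $W_g$
  ($F_g \to F_{int}$), and $\psi$ ($F_{int} \to 1$); $\sigma_1$ is a
  rectifier and $\sigma_2$ a sigmoid, so the single-channel coefficient
  map $\alpha$ lies strictly in $(0,1)$ and rescales $x^l$ across all
  channels. The zero-$\psi$ configuration gives $\alpha \equiv 1/2$ and
  gated $= x/2$ exactly — a useful unit anchor.
* **Decoder** — four blocks of (5×5 transposed convolution, stride 2,
  exact spatial doubling) → batch-norm → 30% dropout (training only) →
  channel concatenation of the gated skip(s) → rectifier, with 160, 80,
  40 and 20 filters.
* **Output head** — a final 5×5 stride-2 transposed convolution down to
  one channel with a sigmoid, so outputs are probability maps of the
  input's spatial size with entries strictly inside $(0,1)$.

All convolution weights are initialized from a zero-mean normal with
standard deviation 0.02 and zero biases; batch-norm starts at scale 1 /
shift 0 with running statistics (0, 1).

### Design choices where the architecture was genuinely open

* **Level counts.** Descriptions of this architecture family vary
  between "five encoders, four decoders" and "four encoders, five
  decoders". We fix *five encoder blocks, four decoder blocks plus one
  transposed-convolution output head* for both networks: this is the
  only reading consistent with the filter lists (five encoder counts,
  four decoder counts) and with an output that returns to the input
  resolution after five halvings. The counts are plain configuration
  (`networkConfig()`), so alternatives remain expressible.
* **Gate resampling direction.** The gating signal is *upsampled by 2*
  to the skip's resolution (parameter-free, bilinear by default,
  nearest selectable via `upsample_mode`). The alternative —
  downsampling the skip to the gate — would produce $\alpha$ at the
  coarse resolution and break the concatenation shapes.
* **Coefficient dimensionality.** $\psi$ produces one feature map, so
  $\alpha$ is single-channel and broadcast across the skip's channels.
* **Deepest gating signal.** The residual-stack output gates the
  deepest attention gate; each shallower gate is gated by the previous
  decoder block's output.
* **Intermediate channels.** $F_{int} = \max(1, F_l/2)$ per gate by
  default, configurable via `attention_int`.
* **Auxiliary supervision.** The first network's output participates in
  the loss with weight $\lambda$ (default 0.5):
  $\mathcal{L} = \mathrm{diceLoss}(y_2) + \lambda\,
  \mathrm{diceLoss}(y_1)$. Setting $\lambda = 0$ trains on the final
  output only; the default keeps the salient map directly supervised,
  which is what makes the first stage interpretable as a
  foreground-highlighting map.

## Loss and metrics

Training minimizes the *minus* soft Dice coefficient,

$$
\mathrm{softDice}(p, t) = \frac{2 \sum p\,t + \varepsilon}{\sum p + \sum t + \varepsilon},
\qquad \mathcal{L} = -\mathrm{softDice},
$$

so losses live in $[-1, 0]$ with $-1$ at a perfect prediction (training
curves are negative and decrease). $\varepsilon = 10^{-6}$ on numerator
and denominator keeps the empty–empty case finite without visibly
biasing scores; it is the smallest value that is robust in 32-bit
arithmetic.

Evaluation uses pixel-counting Dice $2|A\cap B|/(|A|+|B|)$, Jaccard
$|A\cap B|/|A\cup B|$ (algebraically $J = D/(2-D)$, asserted to 1e-12
in the tests), and the symmetric Hausdorff distance
$\max(\max_a \min_b d(a,b), \max_b \min_a d(a,b))$ on extracted
contours. Conventions the original formulations leave open:

* both masks empty → Dice = Jaccard = 1; exactly one empty → 0;
* contours are foreground pixels with a background 4-neighbor or on the
  image border (the thinnest standard boundary);
* an empty contour makes the Hausdorff distance *undefined*: it is
  reported as missing and excluded from (and counted next to) the
  aggregate, never coerced to zero;
* Hausdorff distances and lengths are in pixels unless the sample
  carries a pixel spacing (mm/px), in which case they are in mm;
* probability maps are binarized at `p >= 0.5`, ties going to
  foreground, and binarization is idempotent.

## Preprocessing

Images are converted to grayscale by luminance (0.299 R + 0.587 G +
0.114 B), masks binarized at 8-bit value > 127, and each image is
z-scored with the *population* standard deviation — chosen over the
sample SD so that a two-pixel image standardizes to ±1 — guarded by
1e-8 so constant images map to zeros. Standardization is per image: the
formulation is written over an element set and a per-image scope makes
inference independent of dataset composition. It is applied after
resizing and before padding, so the zero pad equals the
post-standardization background mean.

The published working resolution 472×320 (width × height) is not
divisible by 32, so `padToMultiple()` zero-pads symmetrically (extra
pixel bottom/right) to 480×320 and `cropBack()` inverts it exactly;
`predictSegmentation()` does both transparently. The train/test split
holds out `round(n * 0.2)` samples after a seeded uniform shuffle
(612 → 490/122), and samples with empty masks are dropped before
training.

## Training protocol

Adam (learning rate 1e-4, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-7}$) at batch size 1, with a per-epoch reshuffle
drawn from the run seed. No learning-rate schedule, no gradient
clipping, no augmentation, no early stopping: the reference protocol
trains a fixed budget of around 150 epochs, and best-epoch selection by
validation Dice is available (`keep_best = TRUE`) but off by default.
With `deterministic = TRUE` the entire run — initialization, shuffles,
dropout — is reproducible bit for bit from the seed, and checkpoints
round-trip weights exactly.

## The synthetic phantom generator

`generateMask()` / `renderImage()` emulate the statistical character of
the intended image classes — a single bright, soft-edged, connected
structure on a darker textured background — without any of their
physics:

* a deformed ellipse (random center, axes, rotation; radius modulated
  by harmonics 2–4 with amplitude `boundary_roughness` = 0.15),
  rejection-sampled until its area fraction lies in 8–30% of the frame;
* base intensities 0.70 (target) vs 0.35 (background) on the unit
  scale — deliberately low contrast;
* multiplicative Gamma speckle with shape $k = 4$ and unit mean, a
  standard fully-developed-speckle surrogate;
* a linear top-to-bottom attenuation of 20%, mimicking depth-dependent
  signal drop;
* Gaussian blur of 1 px, then clipping to [0, 1].

These defaults are fixed once as a realistic desk-scale analogue; the
distributional tests (unit-mean speckle, attenuated foreground mean)
are run at low intensities where the clip is inactive, because clipping
truncates the Gamma multiplier and would bias its mean. The default
canvas is 64×64 for tests and the desk-scale protocol; 480×320 suits
demos at the published resolution.

What passing tests on phantoms do **not** show: robustness to real
speckle statistics, multiple or disconnected targets, annotation noise,
acquisition variability across sites, or anything about the published
benchmark figures — reproducing those requires the original datasets
and GPU-scale training, which is explicitly out of scope here. The
phantom suite shows that the implementation *can learn* (the
reduced-width network overfits eight phantoms to Dice ≥ 0.9 from the
fixed seed), that gradients reach every parameter, and that all metric
arithmetic is exact.

## Agreement analytics

Structure "length" from a mask is the maximum Feret diameter (the
largest pairwise Euclidean distance between contour points) of the
largest 8-connected component — the natural caliper reading of a
crown-rump or foot length; no published rule exists, so this choice is
stated explicitly and tested for translation and rotation invariance.
Bland–Altman agreement uses the sample SD and the normal-theory 1.96
multiplier for the limits; quartiles in box-whisker summaries use
linear interpolation between order statistics with Tukey 1.5·IQR
fences, stated so the tests can be exact.

## Numerical notes and degenerate inputs

* Batch normalization uses momentum 0.99 and eps 1e-3; inference uses
  running statistics.
* Batch-norm over a **1×1 spatial map** (batch size 1) is degenerate:
  the batch variance is zero, the normalized activation is identically
  zero, and its training-mode gradient vanishes. This happens when a
  5-level network is fed 32×32 inputs (1×1 bottleneck). It is a
  property of spatial batch normalization, not a defect; use inputs of
  at least 64×64 with the 5-level template when training.
* The desk-scale problem sizes used throughout the tests — 64×64
  phantoms, reduced widths 4/8/16/32/64 and 32/16/8/4, 150–200 epochs,
  8–10 samples — were chosen as the smallest configuration on which the
  double network demonstrably overfits and the salient-map behavior
  emerges.
* All randomness funnels through explicit integer seeds; the RNG state
  of the caller is always restored.

## Known limitations

Binary (single-foreground) segmentation only; 2-D only (1×1×1 kernels
in the attention formulation are realized as 2-D 1×1); batch size 1
only, matching the reference protocol; no multi-GPU, mixed precision or
schedules. The numerical core is plain R + BLAS with C++ patch
extraction — ample for desk-scale work, not for training at clinical
resolution.
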
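---
title: "Lightweight shift-invariant vein identification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight shift-invariant vein identification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilcnn)
```

## The problem

Finger-vein identification matches a near-infrared (NIR) image of the vein
pattern inside a finger against a gallery of enrolled identities. Veins
absorb NIR light, so they appear as dark curvilinear strokes on brighter
tissue. Two practical obstacles dominate deployment: the capture geometry is
never perfectly repeatable, so the region of interest (ROI) arrives slightly
translated between sessions; and the recognizer must run on embedded
hardware, so the parameter and compute budget is tight.

This package implements a lightweight convolutional network (ILCNN) that
addresses both constraints with three mechanisms, each exposed as its own
module:

* **Diverse branch blocks (DBB)** — every 3×3 convolution trains as a
  four-branch module (K×K, 1×1, 1×1→K×K, 1×1→average-pool, each terminated
  by batch normalization) and is *exactly* collapsed into a single K×K
  convolution for deployment. The deployed network therefore pays the cost
  of a plain convolution while having trained with a richer function class.
* **Adaptive polyphase sampling (APS)** — all 2× downsampling keeps, among
  the four parity subgrids `x[i::2, j::2]`, the one with the largest L2
  norm. Under an even circular translation of the input the selected grid
  translates along with it, restoring the shift consistency that strided
  pooling destroys.
* **Coordinate attention (CoAM)** — per-row and per-column average pooling,
  a shared 1×1 encoder (BN + hard-swish), and per-axis sigmoid gates that
  multiply the feature map. Row/column gates match the elongated geometry
  of vein strokes.

Embeddings are trained with an **elastic angular-margin softmax loss**: with
L2-normalized embeddings $x_i$ and class weights $W_j$, the loss of a batch
of size $N$ is

$$
L = -\frac{1}{N}\sum_i \log
\frac{e^{s\cos(\theta_{y_i}+E_i)}}
     {e^{s\cos(\theta_{y_i}+E_i)} + \sum_{j\ne y_i} e^{s\cos\theta_j}},
\qquad E_i \sim \mathcal N(m, \sigma^2),
$$

where $\theta_j$ is the angle between the embedding and class weight $j$.
With $\sigma = 0$ this is the familiar additive-angular-margin (ArcFace)
loss; the Gaussian margin lets the effective penalty vary per sample.

## Architecture and shape contract

Inputs are 112×112×3 tensors in $[0,1]$ (gray ROIs are zero-padded to a
square, resized bilinearly, and replicated to three channels). The network
is:

* *input flow*: 3×3 DBB (3→16) → ReLU → CoAM → APS, 112×112×3 → 56×56×16;
* *middle flow*: four diverse branch residual blocks (DBRB) with widths
  16→32→64→128→256 and spatial trajectory 56→28→14→7→4 (the last APS
  zero-pads 7→8 before decimation), ending at 4×4×256;
* *output flow*: global average pooling → 256-d vector → dropout (0.2) →
  classifier head.

Each DBRB runs `DBB(3×3) → ReLU → DBB(3×3) → CoAM → APS` on its main path
and `1×1 conv → APS` on the shortcut, adds the two, and applies a final
ReLU. The shortcut reuses the phase selected on the main path: if the two
paths subsampled on different parity grids the residual sum would be
spatially misaligned and the block would lose its shift-consistency.
The deployed backbone (head excluded, since the head scales with the
enrolled class count) counts 1,233,464 parameters (1.23 M) and
185.5 M multiply-accumulates (0.19 GMACs) for one 112×112×3 forward pass,
with the convention that a convolution costs
$K^2 C_{in} C_{out} H_{out} W_{out}$ MACs.

The stage widths are the only doubling sequence that connects the published
endpoints (16 after the input flow, 256 before pooling) in four blocks, and
they reproduce both printed budget figures exactly, which is how the
remaining architectural ambiguity was resolved.

## Exact reparameterization

Every fusion rule is closed-form linear algebra on the kernel tensors:

1. convolution + frozen BN → convolution with rescaled weights and shifted
   bias;
2. parallel branches of odd size ≤ K → one K×K kernel by centred
   zero-padding and summation;
3. 1×1 → K×K chains → one K×K kernel by tensor contraction.

Rule 3 is exact only if, at training time, the intermediate map entering the
K×K stage is padded **with the BN's zero-input output** (its fused bias),
not with zeros: a zero pad would feed the K×K stage border values that the
fused convolution cannot reproduce. The train-time branches therefore use
that bias-padding, and its gradient — including the term through the batch
statistics on which the pad value depends — is propagated exactly; all
backward passes in the package were validated against finite differences to
~1e-9 relative error.

Because all inference arithmetic is double precision, train-structure and
deployed forwards agree to ~1e-14 in practice; the test suite asserts the
much looser 1e-4 (layer) and 1e-3 (model) bounds so that the contract would
survive a single-precision port. Fusion uses running statistics and is only
legal in evaluation mode — with batch statistics the block is not an affine
map of its input, and no single convolution can equal it.

## Numerical and design choices

* **BN**: $\varepsilon = 10^{-5}$, momentum 0.1, biased batch variance for
  normalization and unbiased for the running estimate (the usual DL
  convention).
* **APS**: norms are computed over all channels of one map jointly (a
  single phase per map per sample); ties break to the lowest raster phase
  `(0,0) < (0,1) < (1,0) < (1,1)`; odd extents are zero-padded
  bottom-right, which the 7→4 transition of the last block requires.
  Because the network zero-pads its convolutions, shift consistency is
  exact for circular shifts and approximate near borders for real
  translations — the property tests use circular shifts.
* **CoAM**: encoder width `max(8, C/32)`, hard-swish activation, BN inside
  the shared encoder only. These are the defaults of the coordinate
  attention design this module follows.
* **Margin loss**: defaults $s = 64$, $m = 0.5$, $\sigma = 0.05$, one
  margin draw per sample per step; $\cos(\theta + E)$ is computed from
  $\cos\theta$ algebraically with $\sin\theta$ clamped at zero, avoiding
  arccos instabilities near aligned geometry; no easy-margin fallback.
* **Training**: AdamW (decoupled weight decay 0.01), batch 32, initial
  learning rate 2e-4, no schedule. The reference full-scale protocol is
  500 epochs; the desk-scale default in this package is 30.
* **Precision**: training-step convolutions run in single precision (a
  measured ~1.5× throughput gain with no effect on convergence); all
  evaluation, profiling and fusion arithmetic is double precision.
* **Heads**: the margin loss uses a bias-free cosine head ($s\cos\theta_j$
  logits, no margin at inference). The ablation baseline "without EML" is
  a plain fully-connected head with softmax cross-entropy.
* **Decision rule**: a probe is counted correctly identified only when the
  top-1 class matches *and* its softmax probability exceeds 50%; plain
  top-1 accuracy is reported alongside, so both readings of the evaluation
  protocol are available.

## The synthetic data generator

Real vein databases cannot be redistributed, so the package ships a
generator that emulates the acquisition protocol of a multi-session ROI
collection (geometry from FV-USM: 100×300 ROIs, 12 images per finger as 6
per session × 2 sessions, one class per finger, 4:1:1 splits). Each
identity gets a fixed skeleton: 3–6 smooth spline strokes with Gaussian
cross-sections (width 2–4 px) darkening a slowly varying bright background,
Gaussian-blurred. Each image re-renders that skeleton with a per-session
brightness factor (sd 0.08), an integer translation of up to ±6 px, and
additive sensor noise (sd 0.03). Everything is a pure function of the seed.

The generator reproduces the nuisances the architecture targets
(translation, illumination drift, noise) but not finger rotation, bending,
perspective or sensor-specific fixed-pattern artifacts. Passing the
end-to-end test therefore shows that the pipeline learns and stays
shift-stable under controlled conditions — it does not certify accuracy on
real NIR imagery.

## Desk-scale problem sizes

The test suite and examples run the full pipeline at sizes a single CPU
handles comfortably: 50 identities × 12 images (400 training images after
the 4:1:1 split), 8 training epochs for the end-to-end check, and small
tensors for the property suites (20 random DBB configurations, 5 whole-model
fusion seeds, 100 random maps for the shift properties). Eight epochs keep
the end-to-end check fast; identification accuracy is still climbing
steeply at that point, so the package default remains 30 epochs and longer
runs continue to improve the model — the worked example in the README shows
a 14-epoch learning curve.

## Known limitations

* Identification is closed-set (softmax over enrolled classes); there is no
  open-set rejection beyond the 50% rule, and no verification-mode (EER)
  protocol.
* Shift consistency is exact only for even circular shifts; odd shifts
  preserve the retained value multiset but relocate it by construction, and
  zero-padded convolutions break exactness near borders.
* The grouped/depthwise and asymmetric-kernel DBB variants are out of
  scope, as are the VGG/DenseNet/EfficientNet comparison baselines.
* ROI extraction from raw finger images is not implemented; inputs are
  assumed to be ROIs already.
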
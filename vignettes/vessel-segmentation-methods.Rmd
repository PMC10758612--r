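---
title: "Parallel CNN-transformer encoding for 3D vessel segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel CNN-transformer encoding for 3D vessel segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Contrast-enhanced angiography volumes show arteries as sparse, elongated,
branching bright tubes on a darker, noisy background, often with other
enhancing vessels nearby. Voxelwise segmentation of a target artery is hard
for exactly the reasons tubes are hard: the foreground occupies a fraction
of a percent of the volume, an error of a few voxels at a boundary can
disconnect a branch, and purely convolutional models see too little context
to follow a vessel across the volume, while plain transformers need far
more training data than a typical clinical cohort provides.

`penet` implements a parallel encoding architecture that addresses this
trade-off: a classic double-convolution CNN encoder runs side by side with
a triple-axial gated transformer (TAGT) branch, their features are fused
per level with channel attention (FFM), skip connections are enhanced by an
edge feature capture block (EFC), and skip/decoder features are merged by a
convolutional attention-gated fusion block (FFB). The decoder mirrors the
encoder with transposed-convolution upsampling and a
`1x1x1`-convolution-plus-softmax head that emits per-voxel class
probabilities.

## Triple-axial gated attention

Full 3D self-attention over $N = D \times H \times W$ voxels is
$O(N^2)$ and unusable at volume scale. Axial attention factorizes it into
three 1-D passes: attention restricted to lines along depth, height and
width. For a line of length $L$, every (batch, head, off-axis position)
tuple is an independent attention problem, so a $128^3$ volume with 8 heads
yields $8 \times 128 \times 128 = 131{,}072$ depth-axis problems of length
128. Along the attended axis, with query $q_i$, key $k_j$, value $v_j$ and
learned relative-position tables $r^q, r^k, r^v$ (one $L \times L$ table
per head-dimension coordinate, shared across heads),

$$y_i = \sum_j \mathrm{softmax}_j\!\left(q_i^\top k_j
      + G_q\, q_i^\top r^q_{ij} + G_k\, k_j^\top r^k_{ij}\right)
      \left(G_{v1}\, v_j + G_{v2}\, r^v_{ij}\right),$$

where $G_q, G_k, G_{v1}, G_{v2}$ are learnable scalar gates. The gates let
the network modulate how much the learned positional structure contributes;
on small datasets, where positional tables are slow to become informative,
this keeps early training close to plain (or even pure-value) attention and
lets positional terms fade in as they become useful.

A TAGT layer normalizes its input, embeds queries/keys/values with
bias-free `1x1x1` projections, runs the gated attention along depth, height
and width, sums the three outputs, and squashes the sum through a logistic
into a position weight map in $(0,1)$. The map multiplies the original
input, passes through a `1x1x1` convolution plus normalization, and a
residual connection adds the input back. The branch carries a single
channel: its product with the input *is* the position-weighted image, which
is what FFM later fuses with the convolutional features. Between encoder
levels the map is downsampled by stride-2 average pooling.

Two wording ambiguities in the architecture's description were resolved as
follows, and both readings are exposed as configuration flags:

* **Weight map:** the summed axial outputs are squashed with a logistic
  and applied as an *elementwise* weight map on the input (the map
  reading); `tagt_config(weight_map = "raw")` exposes the un-squashed sum.
* **Normalization:** "data normalization" on the layer input is realized
  as group normalization with a single group (equivalently layer
  normalization over channels and space), matching the normalization used
  throughout the network.

Other defaults that the description leaves open: relative-position tables
are initialized from $\mathcal{N}(0, \sigma = d_h^{-1/2})$ with $d_h$ the
head dimension (zero-centred, small enough not to swamp the content term at
initialization); gates start at 1 so every term participates and receives
gradient from the first step; axes are evaluated depth, height, width — the
sum is order-invariant up to floating-point rounding.

## Edge feature capture

Repeated downsampling erodes exactly the boundary detail that vessel
continuity depends on. The EFC block re-weights skip-path features toward
boundaries using two sources. Path 1 upsamples the adjacent deeper layer
$F_i$ (transposed convolution, kernel 2, stride 2), reduces it to one
channel, applies ReLU then the logistic to get $\sigma_1$, and uses
$A = 1 - \sigma_1$ as an edge weight: because ReLU output is nonnegative,
$\sigma_1 \ge 0.5$ and $A \in [0, 0.5]$, so bright vessel *interiors*
(large activations) are de-weighted and the transition zone keeps weight.
The enhanced feature is $F_{i-1} + F_{i-1} \odot A$. Path 2 applies the
same reduction-gating to $F_{i-1}$ itself without upsampling:
$F_{i-1} \odot \sigma_2 + F_{i-1}$ with $\sigma_2 \in [0.5, 1)$. The block
output is the sum of the two paths; with all convolution weights zero it
reduces exactly to $3 F_{i-1}$, a property the tests pin down. The gating
nonlinearity is the logistic throughout: the alternative "softmax" wording
would be degenerate on a single channel, and the explicit algebraic
expansion of the weights is logistic. The two `1x1x1` reductions are
separate parameters by default (`share_conv1 = TRUE` shares them). EFC
applies wherever a deeper neighbour exists, i.e. on skip levels
$1 \ldots \text{levels}-1$ fed by levels $2 \ldots \text{levels}$.

## Feature fusion

**FFB** (skip/decoder fusion) concatenates the enhanced skip feature with
the upsampled decoder feature along channels, passes the concatenation
through three convolution blocks (kernels $3^3, 3^3, 1^3$, each followed by
group normalization and ReLU), squashes the final map with a logistic into
attention weights $A$, and gates the concatenation with $A$. The third
block emits a single channel by default, making $A$ a spatial saliency map
(`ffb_gate_mode = "channel"` switches to per-channel gating). Because the
surrounding network needs the decoder width back, a `1x1x1` projection
follows the gate inside the network (`project = TRUE`); the bare block
contract (gated concatenation) is the default return. Concatenation rather
than channel-wise summation was chosen where the two descriptions of the
block disagree, since selection weights computed *from* the joint feature
are the block's stated purpose.

**FFM** (parallel-branch fusion) aligns the single-channel TAGT map with
the convolutional features by broadcasting it across channels,
concatenates, and applies squeeze-excitation-style channel attention:
global average pool, a bottleneck MLP with reduction ratio 2, logistic
per-channel weights, channel-wise scaling. The two gated halves are summed
so the output keeps the convolutional branch's channel count.

## Network assembly

Widths default to 8-16-32-64 over four encoder levels with a 128-channel
bottleneck (the deepest double convolution doubles its width); crops must
be divisible by $2^{\text{levels}-1}$. The CNN branch downsamples with a
stride-2 convolution, the TAGT branch with average pooling of its map. The
decoder uses transposed convolutions (kernel 2, stride 2), EFC + FFB on
each skip, a double convolution per level, and ends in a `1x1x1`
convolution with channel softmax. Positional tables are sized to each
level's extent; for a non-default input size the tables are remapped by
nearest-offset lookup (`penet_resize_tables()`).

## Loss and metrics

Training minimizes
$$L = 0.6\,L_{CE} + 0.4\,L_{WCE} + L_{Dice},$$
cross-entropy plus class-weighted cross-entropy plus soft-Dice loss.
WCE class weights default to inverse class frequency per batch, clipped to
$[0.01, 100]$ — with foreground fractions around 1%, the foreground weight
sits near 100 and counteracts the extreme class imbalance. The Dice term is
$1 - \text{softDice}$ on the foreground probability with $\varepsilon =
10^{-5}$ smoothing in numerator and denominator; probabilities are clamped
to $[10^{-7}, 1 - 10^{-7}]$ inside logarithms. A NaN in the predictions
raises an error rather than propagating.

Evaluation is voxel-based: sensitivity $\mathrm{SEN} = TP/(TP+FN)$, Dice
$\mathrm{DSC} = 2TP/(2TP+FN+FP)$, and the average Hausdorff distance. Two
AHD variants are implemented because the printed formula is dimensionally
odd (it divides a *maximum* of minima by the set size): `"standard"` is the
conventional symmetric mean of directed mean surface distances, and
`"as-printed"` follows the literal formula. The evaluator defaults to
`"standard"` and every report carries its variant label. Distances are in
voxel units (the data model assumes isotropic $1 \times 1 \times 1$
spacing; a `spacing` argument rescales). Empty sets are a hard error for
AHD; for DSC the empty-vs-empty case is defined as 1; SEN is `NA` when the
reference is empty.

## Synthetic phantoms

The real cohorts this class of model targets are not redistributable, so
the package ships a seeded generator whose outputs mimic their statistical
structure: branching tubes swept along smooth random curves (cubic-spline
interpolated jittered directed walks) with linearly tapering radii
(emulating distal thinning), bright lumen (mean 0.8) on darker background
(mean 0.2), per-tissue noise (sd 0.05) plus global additive Gaussian noise
(sd 0.05), and nearby distractor tubes that are *not* part of the label —
thinner and dimmer (mean 0.55) than the target, as for neighbouring vessels
with weaker enhancement. Foreground fractions are validated to lie in
(0, 0.05), matching vascular sparsity. Tubes are rasterized as capped
cylinders per polyline segment (voxels whose projection falls inside the
segment and whose radial distance is at most the interpolated radius), so a
straight tube's voxel count tracks $\pi r^2 \ell$ closely.

What the phantoms deliberately do not model: CT physics (beam hardening,
streaks, partial-volume blur), anatomy around the vessel, annotation noise,
and anisotropic spacing. Passing the parameter-recovery test therefore
shows the architecture, loss, optimizer and pipeline can learn tubular
structure from realistic sparsity and contrast — it does not certify
clinical performance.

## Training recipe and desk scaling

The full-scale recipe is Adam (learning rate $10^{-3}$, weight decay
$10^{-8}$), cosine annealing with warm restarts (`eta_min` $10^{-4}$,
restart period 100 epochs — the period is a package default, chosen so a
600-epoch run sees several restarts), 600 epochs, 3-fold cross-validation,
$128^3$ crops. The desk preset used throughout the tests and the
acceptance script scales this to a single CPU: $32^3$ volumes, widths 4-8
over two levels, 2 heads of dimension 4, batch size 2, 50 epochs, 12
training phantoms and 3 held-out phantoms, validation Dice every 10
epochs with best-by-validation checkpointing. Batch size and the
validation cadence are package choices (the recipe leaves them open).
Augmentation defaults to none so runs are deterministic given the seed.
On these conditions the desk run reaches held-out Dice well above 0.9.

## Numerical choices

* All computation is double precision; the compiled kernels (3D
  convolution, transposed convolution, gated axial attention) are exact
  implementations verified against brute-force oracles and central finite
  differences in the test suite.
* Softmax uses max-subtraction; inside the attention kernels the
  exponential is a range-reduced polynomial accurate to about $10^{-13}$
  relative, which keeps attention outputs within $\sim 10^{-9}$ of a
  naive evaluation.
* Group normalization uses population variance with $\varepsilon =
  10^{-5}$.
* Convolution weights are He-initialized; `1x1x1` projections use
  $\mathcal{N}(0, 1/\sqrt{C_{in}})$; normalization affines start at
  $(\gamma, \beta) = (1, 0)$; biases at 0 except the FFM bottleneck
  bias (0.1), which keeps its narrow ReLU layer active at initialization.
* The reverse-mode engine is tape-free on plain arrays (inference) and
  records closures on wrapped parameters (training); forward passes are
  bit-deterministic, so identical seeds give identical runs.
* Large-volume TAGT layers process heads in memory-bounded blocks so a
  $128^3$ forward pass at full printed width stays within a few GiB.

## Known limitations

* Single-vessel (binary) segmentation only; no multi-class head.
* No data augmentation beyond optional flips; no sliding-window inference
  beyond pad-to-divisible.
* Training at full $128^3$ scale is possible but slow on one CPU; the
  package is CPU-only by design of its environment.
* The parameter count of the full-width model is a pure function of the
  configuration and is reported, but no published total is treated as a
  constraint, since the widths beyond level 1 are not pinned down by any
  printed table.
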
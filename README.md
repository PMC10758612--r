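# penet

Three-dimensional segmentation of sparse tubular vessels (CT angiography
and similar volumetric grayscale images) with a **parallel CNN–transformer
encoder**. Written for image-analysis researchers who want a fully
inspectable, CPU-runnable implementation of this architecture family:
every block, the training loop, and the evaluation metrics are plain R
over compiled kernels, with no deep-learning framework dependency.

## The model

The network is a U-shaped encoder–decoder whose encoder runs two branches
in parallel at every level:

* a classic **double-convolution** branch (kernels 3³, stride 1, group
  normalization + ReLU), and
* a **triple-axial gated transformer (TAGT)** branch: 1-D gated positional
  self-attention along depth, height and width,

  y_i = Σ_j softmax_j( q_iᵀk_j + G_q·q_iᵀr^q_ij + G_k·k_jᵀr^k_ij ) · (G_v1·v_j + G_v2·r^v_ij),

  with learned relative-position tables r^q, r^k, r^v and scalar gates
  G_q, G_k, G_v1, G_v2. The three axial outputs are summed and squashed
  into a position weight map that multiplies the input.

The two branches are fused per level by channel attention (**FFM**). Skip
connections pass through an **edge feature capture (EFC)** block that
up-weights boundary voxels using the current and the adjacent deeper
layer, then through an attention-gated convolutional fusion block
(**FFB**). A 1×1×1 convolution + softmax head emits per-voxel class
probabilities. Training minimizes

    L = 0.6·L_CE + 0.4·L_WCE + L_Dice

with Adam and cosine annealing with warm restarts; evaluation reports
sensitivity (SEN), Dice similarity coefficient (DSC) and average
Hausdorff distance (AHD, in two variants).

Because the clinical cohorts this architecture targets are not
redistributable, the package includes a seeded **synthetic phantom
generator** (branching bright tubes, distractor vessels, noise) so the
full train / predict / evaluate pipeline runs end-to-end on one CPU.

## Worked example

```r
library(penet)

# 1. synthetic data: 12 training + 3 held-out phantoms, 32-cube volumes
spec <- desk_phantom_spec(seed = 101)
cases   <- lapply(1:12,  function(i) { s <- spec; s$seed <- spec$seed + i; generate_phantom(s) })
holdout <- lapply(13:15, function(i) { s <- spec; s$seed <- spec$seed + i; generate_phantom(s) })

# 2. train the desk-scale model (2 levels, widths 4-8, 2 heads x 4)
res <- penet_train(cases, desk_net_config(),
                   train_config("desk", seed = 7, val_every = 10),
                   val_cases = holdout, verbose = TRUE)
#> epoch   1  lr 0.00100  loss 1.6499  val_dsc -
#> ...
#> epoch  50  lr 0.00056  loss 0.6197  val_dsc 0.980

# 3. segment a held-out phantom and score it
mask <- penet_predict(res$model, holdout[[1]]$image)
case_metrics(mask, holdout[[1]]$label)
#>         SEN       DSC        AHD  variant
#> 1 0.9779614 0.9874826 0.01242378 standard
```

The epoch lines show the composite loss falling from 1.65 to 0.62 over 50
epochs while the mean held-out Dice reaches 0.980: the model recovers the
phantom vessels nearly voxel-perfectly, and the hundredth-of-a-voxel
average Hausdorff distance says the remaining disagreement hugs the true
boundary.

Architecture bookkeeping for the full-width configuration:

```r
cfg <- net_config()                    # widths 8-16-32-64, 8 heads x 16, 128 crop
count_axial_problems(cfg, c(128, 128, 128), "depth")
#> $problems        131072       # independent depth-axis attention problems
#> $folded_leading  1024         # batch x off-axis x heads folding
penet_summary(cfg)                     # per-layer input/output dimension table
```

A thin CLI over the same functions lives at `inst/cli/penet.R`
(`make-phantoms | train | predict | evaluate | build-summary`).

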
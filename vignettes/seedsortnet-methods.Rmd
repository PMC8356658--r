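---
title: "SeedSortNet: model, budgets, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SeedSortNet: model, budgets, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedsortnet)
```

## The problem and the model

Industrial seed sorting is a two-class image problem: a camera above a
conveyor or line-scan feeder captures one small RGB frame per object, and
the sorter must decide whether the frame shows a single intact seed
("normal") or anything else — several seeds at once, broken kernels,
stones, leaves, or other impurities ("abnormal").  Because the decision
runs on embedded hardware at line rate, the classifier must be small (well
under a million parameters) and cheap (a few hundred million
multiply-accumulates per frame).

SeedSortNet is a lightweight convolutional network built for this setting
from four components:

* **Root-module** — a dual-branch stem.  A 3x3 convolution with 16 filters
  reads the `224 x 224 x 3` input; branch 1 downsamples its output with
  anti-aliased max pooling, branch 2 applies a 3x3/stride-2 convolution
  followed by a 1x1 reduction back to 16 channels.  Concatenation gives
  `112 x 112 x 32`.
* **Shield-block** — the workhorse block, a dual-branch variant of the
  inverted residual.  For a block of width $C$ with reduction rate $t$ and
  split ratio $r$: the main branch is DW3x3 (ReLU6) → PW1x1 down to
  $\mathrm{round}(C/t)$ channels (linear) → PW1x1 up to $C - \lfloor C/r
  \rfloor$ (ReLU6) → DW3x3 (linear); the sub branch is a depthwise
  separable 3x3 carrying the remaining $\lfloor C/r \rfloor$ channels.
  The branches concatenate back to exactly $C$; identity-width blocks add
  a shortcut.  Linear (non-ReLU) activations sit after the reducing
  pointwise layer and the final depthwise layer so that narrow
  representations are not rectified to death.  We use $r = 6$ throughout
  and $t = 2$ for the channel-expanding first block of each stage, $t = 6$
  otherwise.
* **MaxBlurPool** — all four downsampling stages use dense (stride-1) 2x2
  max pooling, a fixed normalized binomial blur
  $[1,2,1]^\top[1,2,1]/16$, then stride-2 subsampling.  The low-pass
  filter between max and subsampling removes the aliasing that makes
  strided max pooling shift-sensitive.
* **SFSAM** — a grouped spatial attention module.  The $C$ channels are
  split into $g$ contiguous groups ($g = 4$ by default); each group is
  summarized by per-position channel max and mean, a 7x7 convolution maps
  the 2-channel descriptor to one logit map, a softmax over all $H \times
  W$ positions turns it into a spatial probability map $M_i$, and the
  group is re-weighted residually, $\hat F_i = (M_i \otimes F_i) \oplus
  F_i$.

The full network is Root → [Shield x2 → SFSAM → pool] at 64 channels →
[Shield x4 → SFSAM → pool] at 128 → [Shield x5 → SFSAM → pool] at 192 →
[Shield x4 → SFSAM → pool] at 256 → global average pooling → channel
dropout → a 2-way fully-connected head: 15 Shield-blocks, 4 attention
sites, 4 pooling stages.

```{r topology}
net <- build_network(seedsort_config(), rng_seed = 1)
shape_trace(net)
```

## Parameter and computation budgets

`profile_network()` counts learnable parameters from the actual arrays
(convolution weights and biases, batch-norm affine pairs, attention
filters, head weights) and multiply-accumulates from the layer geometry,
one MAC per FLOP, convolution and fully-connected multiplies only.
`budget_reconciliation()` tabulates every published variant next to its
reference budget:

```{r budgets}
budget_reconciliation(input_size = 224)[, c("variant", "params_M", "macs_M",
                                            "ref_params_M", "ref_flops_M")]
```

Three realization choices were genuinely open — the original description
never states its normalization scheme, the stem's branch-2 width, or how
the bottleneck width is rounded — and we fixed them by arithmetic against
the published budget table, the same way the per-group attention filters
are pinned down by the parameter deltas across the $g \in \{1,4,8,16\}$
ablations (those deltas equal $4 \cdot g \cdot (2k^2\,{+}\,1)$ only if
each group owns its filter bank):

* every convolution is followed by batch normalization whose affine pair
  is counted, and also carries a framework-default bias.  A bias feeding a
  batch norm is mathematically redundant (the re-centering cancels it, and
  its gradient is identically zero), but the published totals are only
  reproduced when such biases are present and counted, so the network
  keeps them;
* the main-branch bottleneck is `round(C_out / t)`, read against the
  block's output width;
* the stem's branch-2 3x3/stride-2 convolution has 56 filters before its
  1x1 reduction to 16.

With these conventions the default network computes 0.399944 M parameters
(printed: 0.400 M), the no-SFSAM ablation 0.398360 M (printed 0.399 M),
and the $g = 1/8/16$ ablations 0.399/0.402/0.405 M at printed precision;
MAC totals land within about 1.1% of every printed FLOP figure.

**The 0.75x width variant cannot be reconciled.**  Its published pair
(0.23 M parameters, 338.64 M FLOPs) is internally inconsistent with the
1.0x figures under uniform width scaling: the parameter ratio
$0.23/0.40 = 0.575$ requires ~94% of parameters to scale quadratically
(pointwise-dominated), while the FLOP ratio $338.64/512.06 = 0.661$
requires ~50% of the computation to scale linearly (depthwise-dominated at
high resolution).  No network with this topology's channel counts and
resolutions has both properties — the attainable depthwise MAC share is
roughly 20–25%.  Our faithful 0.75x network (channels 24, 48, 96, 144,
192, every other rule unchanged) computes 0.243 M parameters and 313.2 M
MACs, and we report those numbers rather than tuning a second set of
conventions for one variant.  The reconciliation table keeps the
discrepancy visible.

A convention switch (`include_bias_macs`) adds one operation per output
element of biased layers for the alternative FLOP reading; it is recorded
in every report.

## Attention-module decisions

The gating axis of the softmax is not derivable from the equations alone:
for a single-channel map the only non-degenerate reading is a softmax over
the flattened $H \times W$ positions, which makes each group's map a
spatial probability distribution (non-negative, summing to one).  That is
the default; a per-position sigmoid gate is available behind
`attention_config(gate = "sigmoid")` but is not used by the published
variants.  The attention convolution carries a bias and is *not* followed
by batch normalization — it feeds the softmax directly.  Because
$\hat F = M \otimes F \oplus F$ with $M \ge 0$, the module can only
amplify non-negative activations, never attenuate them, and with $M = 0$
it is exactly the identity; both properties are enforced in the tests.

## Synthetic seed images

The package must be buildable and testable without the two proprietary
acquisition datasets, so `generate_dataset()` draws 100x100 RGB frames
that emulate the *structure* of line-scan seed sorting data: a normal
frame holds one centered, striped, seed-toned ellipse on a dark
background; an abnormal frame holds either clutter (2–4 small
seeds/impurities), a seed broken into two separated fragments, or a
stone-like irregular polygon with debris specks.  Every abnormal
composition contains at least two connected components, which gives an
independent, network-free check of separability: a hand-written rule
(`baseline_component_rule()` — gray threshold 0.18, connected components,
ignore specks under 10 px, "normal" iff exactly one component) classifies
the noiseless classes essentially perfectly, and its accuracy decays
monotonically as the additive Gaussian pixel noise `noise_sd` grows
(≈0.94 at SD 0.15, chance at 0.25 — the property the tests assert over
three seeds).

What the generator deliberately does *not* model: photorealistic seed
texture, illumination and camera effects, the haploid/diploid embryo
marks of real maize kernels, or class imbalance (the real sunflower line
data are near-balanced, and the generator keeps the classes exactly
balanced).  A network that learns these images therefore demonstrates
that the architecture, gradients, and recipe work — not that it reaches
any particular accuracy on real seed lines.

Augmentation follows the published x4 scheme — original, horizontal flip,
vertical flip, rotation — with the rotation fixed at 90 degrees so the
augmentation is exact and loss-free on square frames.

## Training recipe

`train()` implements the published recipe: mini-batch SGD with momentum
0.9 and weight decay $10^{-4}$ on a cross-entropy loss (the loss function
is not stated in the original description; cross-entropy over the raw
two-way scores is the standard choice), initial learning rate 0.001
multiplied by 0.1 every 30 epochs at the epoch boundary, batch size 16.
Inputs are standardized per channel by the training split's mean and SD;
the record is stored with the network so inference applies the same
transform.  Training, shuffling, dropout and initialization all run on a
private seeded RNG stream, so runs are exactly reproducible.

The desk-scale problem sizes used by the test-suite learning checks are a
choice of this package: images are generated at 100 px and bilinearly
resized to a 64-px network input (the architecture downsamples by 32, so
64 is the smallest power-of-two-friendly size that keeps two spatial
positions ahead of the global pool), with 64 images for the overfit check
and a 400-image 75/25 split for the generalization check.  Under the
published recipe the default network reaches 100% training accuracy on
the overfit set within ~20 epochs and ~100% held-out accuracy on the
split within ~10.

## Numerical choices

* Batch normalization uses $\varepsilon = 10^{-5}$, biased batch variance
  for both normalization and the running estimate, and running-stat
  momentum 0.1.
* "Same" spatial padding everywhere, output size $\lceil H/s \rceil$;
  when the total padding is odd the extra row/column goes to the
  bottom/right.  The blur convolution uses reflect padding; the dense max
  pooling replicates edges.  Ties in the 2x2 max resolve to the earliest
  position in (top-left, bottom-left, top-right, bottom-right) order.
* Weights use He-normal initialization (variance $2/\mathrm{fan_{in}}$);
  attention filters start near zero (SD 0.01) so the maps start near
  uniform; the head uses SD $\sqrt{1/256}$.
* The spatial softmax subtracts the per-map maximum before
  exponentiation.
* The width multiplier rounds every stage width to the nearest multiple
  of $g$ so all attention sites stay divisible, and errors out if a width
  would collapse below one group.

## Limitations

* The engine is a compact educational/reference implementation (R with
  C++ kernels), tuned to be exact rather than fast; training beyond a few
  hundred small images is impractical.
* Accuracy figures on real maize or sunflower data are out of scope: they
  require the original acquisitions and GPU-scale training.
* The 0.75x budget discrepancy above is a property of the published
  figures, not something a different implementation choice in this
  package could close while keeping the 1.0x budgets matched.
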
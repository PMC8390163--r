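---
title: "Strip pooling for variable-size ultrasound ROI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strip pooling for variable-size ultrasound ROI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripnet)
```

## The problem

Carotid plaques are graded by echogenicity — echolucent (dark,
lipid-rich, associated with instability), echo-rich (bright,
calcified/fibrotic, stable), and intermediate (mixed) — from B-mode
ultrasound ROIs. Two properties of these ROIs shape the design here.
First, they vary in size by more than an order of magnitude (observed
clinical extremes 19×29 and 134×564 pixels, h×w), so any fixed-input
CNN must crop or rescale, distorting texture. Second, plaques in the
longitudinal section are horizontally elongated strips, so the
informative context runs along the width.

Multilevel strip pooling (MSP) addresses both: an adaptive pooling head
between the convolutional backbone and the fully connected classifier
that (i) produces a fixed-length output whatever the feature-map size,
and (ii) pools with full-width strip windows, aggregating long-range
horizontal context instead of the square neighbourhoods of spatial
pyramid pooling (SPP).

## The pooling model

For a level of $a_n \times b_n$ divisions on a map of size
$m_h \times m_w$, the window and stride are

$$ s_h = \lfloor m_h / a_n \rfloor, \qquad k_h = m_h - (a_n - 1)\, s_h, $$

and analogously along the width. This is the unique choice under which
the $a_n$ equally strided windows cover the map exactly:
$(a_n - 1)s_h + k_h = m_h$, the last window flush with the edge. Windows
are average-reduced. In the default horizontal mode $b_n = 1$, so every
window spans the full width; vertical and both-dimension modes are
exposed (by transposing the level set) but unused by default, since the
horizontal direction carries the long-range structure in this imaging
geometry. A $j$-level head concatenates its levels, giving the
fixed output length

$$ v_o = k \sum_{n=1}^{j} a_n b_n $$

for $k$ feature maps — e.g. 6 per map for strip levels
$\{1{\times}1, 2{\times}1, 3{\times}1\}$, 10 for
$\{1{\times}1,\dots,4{\times}1\}$. The SPP head uses square levels with
window $\lceil m/a_n \rceil$ and stride $\lfloor m/a_n \rfloor$
(max-reduced, the original pyramid-pooling convention), giving
$k \sum a_n^2$ — 14 per map for $\{1{\times}1, 2{\times}2, 3{\times}3\}$.

```{r geometry}
pool_geometry(msp_levels(1:3), 8, 8)
output_length(spp_levels(1:3))
```

### Numerical and degenerate-case choices

* **Rounding in the window formula.** The floor stride / complementary
  kernel pair above is adopted because it is the only rounding that
  tiles the map exactly; it also matches the SPP stride convention, so
  the two heads differ only in window shape and overlap.
* **Maps smaller than a level** ($a_n > m$, e.g. a 1×1 map from a 19×29
  ROI through four pools) make the floor stride 0. Both heads then fall
  back to index-rule adaptive windows, window $i$ spanning
  $[\lfloor i m/a \rfloor, \lceil (i{+}1) m/a \rceil)$, which duplicates
  cells gracefully and preserves the output length. The fixed-length
  contract therefore holds for every valid input size.
* **Reduction.** Strip windows are averaged; pyramid windows are
  max-reduced. Both reducers are configurable, since the historical SPP
  literature uses max while average is what "adaptive average pooling"
  implies for strips.
* **Concatenation order** (maps outer, levels inner, windows row-major)
  is arbitrary — it only permutes the FC layer's input — and is fixed
  and documented so runs are reproducible.

## The network

The backbone is VGG-style: blocks of 3×3/stride-1/pad-1 convolutions
with ReLU, 2×2 stride-2 max-pools between blocks. The `"vgg16"` preset
keeps the five VGG16 blocks but removes the pool after the last block
(4 pools, $k = 512$); batch normalisation is deliberately absent (it
would also misbehave at batch size 1). The pooling head feeds one hidden
FC layer (ReLU), dropout, and a final FC + softmax over the three
classes.

* **Dropout** is read as retain-probability masking,
  $\tilde{y} = r \odot y$ with $r_j \sim \mathrm{Bernoulli}(p)$, applied
  in training only; the inverted-dropout convention (divide by $p$ at
  training time) keeps evaluation unscaled. The retain probability is
  not prescribed anywhere, so the standard default $p = 0.5$ is used,
  configurable.
* **FC head sizes** are likewise open; the default is a single hidden
  layer (512 units for the vgg16 backbone, 64 for the tiny one used in
  examples) with dropout before the last FC layer.
* **The `"tiny"` preset** (two blocks of 8 and 16 filters, final pool
  kept, so 2 pools and minimum input 4×4) exists so that CPU training
  runs in minutes; it is the default in examples and tests, while
  `"vgg16"` preserves the fidelity layout. A weight-loading hook
  (`set_weights()`) accepts externally pretrained parameters; everything
  in the package runs from seeded random initialisation.
* **Fine-tuning scope** (all layers vs frozen early blocks) is not
  prescribed; the package always trains all layers, and `set_weights()`
  leaves any freezing policy to the caller.

## Training recipe

Cross-entropy loss, SGD with momentum 0.9, base learning rate 0.001
divided by 10 every 6 epochs, 30 epochs, batch size 1. Two readings of
the recipe deserve note. "Every 6 iterations" is interpreted as every 6
*epochs*, consistent with a 30-"iteration" budget and 30-epoch accuracy
curves; the resulting schedule takes exactly the values
$10^{-3}, \dots, 10^{-7}$, six epochs each. Batch size 1 is not a
choice but a constraint: tensors of differing spatial sizes cannot be
stacked, which is precisely the regime the pooling head exists for.
Training is deterministic given the seed (shuffling and dropout both
derive from it).

## Evaluation

Stratified k-fold cross-validation (default 5): within each class,
records are shuffled and dealt round-robin, so per-fold class counts
are within one of exact proportionality. Stratification is a package
choice — it guarantees all three classes appear in every test fold even
when classes are imbalanced (the clinical class totals 335/405/723
motivate this). Patient-level grouping would be preferable when several
plaques share a patient, but requires a patient–plaque mapping the
package cannot know; `stratified_kfold()` operates on records. Each
fold re-initialises the network from `seed + fold`, so folds are
independent yet the whole procedure is reproducible.

From each fold's held-out confusion matrix (rows = truth), one-vs-rest
tallies give per-class sensitivity $TP/(TP{+}FN)$, specificity
$TN/(TN{+}FP)$, precision $TP/(TP{+}FP)$ and F1 (harmonic mean of
precision and sensitivity); macro means are unweighted over classes and
accuracy is the diagonal sum over the total. A ratio with an empty
denominator (a class never predicted on a degenerate fold) is reported
as 0 and flagged in the `undefined` column rather than as `NaN`, keeping
macro means defined.

```{r metrics}
cm <- matrix(c(50, 10, 0, 5, 40, 15, 0, 10, 90), 3, byrow = TRUE)
compute_metrics(cm)[, c("class", "sensitivity", "specificity", "precision", "f1")]
```

## The synthetic generator

The clinical images are private, so the package ships a seeded generator
of plaque-like ROIs that reproduces the structure the method exploits,
not ultrasound physics:

* **Sizes** drawn uniformly from $h \in [19, 134]$, $w \in [29, 564]$
  (the observed clinical extremes), so ROIs are horizontally elongated
  in expectation.
* **Echogenicity**: class mean intensities 0.2 (echolucent), 0.8
  (echo-rich) on $[0,1]$; the intermediate class sits at their midpoint
  and mixes alternating bright/dark horizontal bands (half-amplitude
  0.3), emulating mixed plaque composition.
* **Band texture**: 6 horizontal bands with a class-independent
  alternating amplitude of 0.08, giving the horizontal-strip head a
  genuine long-range signal.
* **Speckle**: multiplicative gamma noise with mean 1 and shape 8 — a
  standard first-order surrogate for the granular interference pattern
  of B-mode imaging after display processing; milder than raw
  fully-developed speckle, which is heavily compressed on screen.
* **Quantization**: images are clipped to $[0,1]$ and rounded to the
  8-bit grid before writing, so the PNG round trip is exact and the
  normalization path is exercised exactly as with clinical files.

A separability knob $\lambda \in [0,1]$ scales every class-dependent
term: at $\lambda = 1$ the settings above apply in full; at
$\lambda = 0$ the three class-conditional distributions are *identical*
by construction, which provides a chance-level null for the training
pipeline. All class structure passes through $\lambda$, so the knob is
monotone: a trivial per-image mean-intensity classifier's accuracy is
non-decreasing in $\lambda$.

What passing tests on this generator do **not** show: robustness to
real acoustic shadowing, anisotropic point-spread functions, vessel-wall
anatomy, operator-dependent gain, or correlated speckle. The generator
validates the *pipeline* (size handling, learnability of echogenicity
differences, chance-level honesty), not clinical performance.

## Problem sizes used in the checks

The automated checks run at sizes chosen to exercise every code path
while remaining desk-scale: pooling oracles on random stacks up to
16×16×4 against a naive double-loop implementation (relative tolerance
$10^{-9}$); window-coverage identities for all map sizes 1–128 and
levels 1–8; and the end-to-end learning check on the tiny backbone with
the MSP-123 head, 60 training and 30 test images per seed at the full
clinical size range, 10 epochs, five seeds at $\lambda = 1$ (expecting
test accuracy $\ge 0.9$ in a majority of seeds) and five at
$\lambda = 0$ (expecting chance level). Unit tests of the training loop
use a reduced ROI size range (heights 16–28, widths 24–56) purely to
keep them brisk; the acceptance checks use the full range.

## Known limitations

* Training is single-image SGD in R with C++ kernels for convolution
  and max-pooling only; it is meant for method study and small
  experiments, not large-scale training.
* The `"vgg16"` backbone is provided for structural fidelity, but
  training it from random initialisation at full ROI sizes is far
  slower than the tiny preset and benefits from pretrained weights
  supplied via `set_weights()`.
* The generator's speckle is uncorrelated pixel-to-pixel; real speckle
  has spatial correlation set by the imaging system's resolution cell.
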
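---
title: "Geometry-adaptive bandelet analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-adaptive bandelet analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bandelet)
```

## The model

Separable orthogonal wavelets are near-optimal for images that are smooth
away from point singularities, but an edge or curved contour leaves a trail
of large detail coefficients at every scale: the basis has no way to exploit
regularity *along* the contour. The bandelet transform recovers that
regularity by adapting the basis to a locally estimated geometric flow.

The construction in this package:

1. **Separable 2D DWT** (`dwt2()`): an orthonormal filter pair (Haar, 4-tap
   or 8-tap Daubechies) with periodic boundary extension, applied
   per level along rows then columns. Only the coarsest approximation is
   retained; detail subbands (LH = horizontal structure, HL = vertical,
   HH = diagonal) are kept at every level. Periodisation keeps the transform
   matrix orthogonal, so Parseval's identity holds exactly and pixel-domain
   distortion can be accounted in the coefficient domain.

2. **Quadtree best basis per detail subband** (`best_quadtree()`): each
   subband (zero-padded to a dyadic square; padding recorded and stripped on
   inversion) is recursively split into four quadrants. Each node is costed
   two ways under the Lagrangian rate–distortion objective

   \deqn{L = \|f - f_R\|^2 + \lambda T^2 (R^G + R^B)}

   directly (`L_direct`, best over the flow dictionary) and as a
   subdivision (`L_tilde`, children's optima plus a \eqn{\lambda T^2}
   overhead), keeping the cheaper: \eqn{L_0 = \min(L_{direct},
   \tilde L)}. The recursion is an exact dynamic program: the returned tree
   globally minimises \eqn{L_0} over all admissible quadtrees, which the
   test suite verifies against exhaustive enumeration.

3. **Per-leaf bandeletisation** (`bandeletize_block()`): a leaf with flow
   slope \eqn{c'} is flattened in the order of the warped coordinate
   \eqn{x_2 - c' x_1} (ties by ascending \eqn{x_1}) and transformed by a
   full-depth orthonormal 1D DWT. The warp is an exact permutation — not an
   interpolating resampling — so the composite transform stays orthonormal
   and inverts to machine precision. Leaves without significant geometry
   keep their raw (already wavelet-transformed) coefficients; that *is* the
   classical separable representation of the region.

Thresholding is never applied during analysis: the fitted `bandelet` object
is lossless, and `predict(fit, threshold = T)` performs the hard-thresholded
reconstruction whose squared error equals the discarded coefficient energy
(orthonormality; asserted in the tests).

## Why the flow helps, and when it cannot

In a decimated subband the coefficient field of an oblique edge is *not*
translation-invariant: the sub-pixel phase of the edge varies along the
contour, so coefficient values oscillate along the tangent. Two mechanisms
still make the warped 1D transform sparser than the raw block:

* for slopes \eqn{p/q} with small denominator, the decimated field is
  exactly periodic along the contour, so warped tie-groups are constant runs
  that the 1D wavelet annihilates;
* for slopes that *cross* the contour, consecutive warp keys sample the edge
  profile at finely increasing offsets, producing a smooth 1D signal.

Both effects need spatial extent. On 64-pixel images the flow's rate
overhead (`geometry_bits = 5` for the default dictionary, i.e.
\eqn{4\lambda T^2 = 3600} at the default \eqn{T = 30, \lambda = 1}) usually
exceeds the achievable saving; from about 128 pixels upward the gain is
consistent (15–20 % fewer significant coefficients on curved-boundary test
images). This is why the sparsity comparisons in the tests and the
acceptance script use 128-pixel curved-boundary images
(`curved_boundary_phantom()`), and it is a known limitation: on *speckled*
phantoms at \eqn{T = 30} the significance counts are dominated by
noise coefficients, which carry no geometry, and the bandelet/wavelet
difference shrinks to a fraction of a percent in either direction. Passing
the sparsity tests therefore demonstrates the geometric mechanism on clean
anisotropic structure, not a denoising advantage on speckle.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `wavelet` | `"db2"` | orthonormal filter pair for both the 2D DWT and the 1D bandeletisation; Haar and db4 available |
| `levels` | 2 (transform), 1 (feature tensors) | DWT depth |
| `T` | 30 | quantisation step on the 8-bit intensity scale; drives the cost and the significance rule \eqn{|c| > T} |
| `lambda` | 1 | Lagrangian multiplier trading distortion against rate |
| dictionary | 16 uniform slopes on \eqn{[-2, 2]} + 0 + NO_FLOW | the discrete flow search space; `geometry_bits = ceil(log2(18)) = 5` |
| `min_block` | 4 | smallest quadtree leaf side |

The rate proxies are declared, not estimated: \eqn{R^B} counts significant
coefficients (one unit each) and \eqn{R^G} is `geometry_bits` for a flowed
leaf and 1 (the flow/no-flow flag) otherwise. Any monotone proxy preserves
the argmin structure; counts keep every cost auditable. Ties
(`L_direct == L_tilde`, or equal flow costs) resolve to the simpler model:
DIRECT before SUBDIVIDE, NO_FLOW before any slope, smaller |slope| first,
negative sign first — making trees and flows deterministic.

A nuance worth recording: a *nonzero constant* block is cheaper under any
flowed transform than stored raw, because the full-depth 1D DWT concentrates
the DC above \eqn{T} (zero distortion at rate `geometry_bits + 1`). NO_FLOW
wins its tie only on zero blocks — which is what detail subbands of constant
regions actually are.

## The synthetic phantoms

`generate_phantom()` emulates B-mode ultrasound: a smooth background with
mild depth attenuation, an embedded hypoechoic nodule, and multiplicative
speckle \eqn{x(1 + s\eta)} with \eqn{\eta} a standardised log-normal field
(positive skew, unit variance) clipped to \eqn{[0, 255]}. Class structure
follows clinical descriptors: benign nodules are near-elliptical (boundary
modulation \eqn{\le 3\%} of the radius, \eqn{\le 2} harmonics); malignant
nodules are taller than wide with strong high-order boundary irregularity
(\eqn{\ge 12\%}, \eqn{\ge 6} harmonics). Echogenicity contrast is drawn from
\eqn{(0.3, 0.5)} for both classes so intensity alone does not separate them.
The default 14 benign / 62 malignant mirrors the class imbalance of the
public thyroid collection the generator emulates.

What the phantoms do **not** model: acoustic shadowing and enhancement,
correlated speckle (the field is i.i.d. per pixel), calcifications, probe
geometry, or operator variability. Tests passing on phantoms show that the
pipeline is correct and that its features carry the encoded geometric cues;
they do not certify clinical performance.

## Preprocessing program

The data program reproduces the study counts exactly:
14 benign → SMOTE to 28 (synthetic images are convex combinations
\eqn{x_i + u(x_{nn} - x_i)}, \eqn{u \sim U(0,1)}, \eqn{k = 5} nearest
neighbours, base images cycled round-robin) → combine with the first 28
majority images (stable input order) → augment to 2048 (originals retained;
random composition of brightness \eqn{U[0.8, 1.2]}, horizontal flip,
rotation \eqn{U[-15°, 15°]} and height scaling \eqn{U[0.9, 1.1]}, both with
nearest-neighbour fill, each op with probability 0.5, bases cycled in
class-interleaved order so any prefix is balanced within one item) →
stratified 80/20 split, \eqn{\lfloor 0.8 \cdot 2048 \rfloor = 1638} train /
410 validation.

Augmenting before splitting (the default, matching the study's order) leaks
augmented siblings across the split; `split_before_augment = TRUE` splits
the 56 base images first and augments each side independently — the
methodologically safer variant, provided as an option.

Augmented output size is a parameter (`out_size`, default 512). The count
trace is size-invariant, so the test suite and the acceptance script run it
at 128 pixels — 2048 double-precision images at 512² would occupy several
gigabytes without changing a single count.

## Feature tensors and normalisation

`extract_bandelet_tensor()` resizes the image (bilinear, default 512²),
fits the bandelet representation at level 1, and materialises four
coefficient-domain maps — approximation plus LH/HL/HH with each leaf's
bandelet coefficients placed back at their warped grid positions (maps of
coefficients, not partial reconstructions) — each resized to the tensor
size (default 224²) and stacked in order A, H, V, D. Normalisation is
z-score per channel with population statistics fitted on the training split
only; degenerate channels get \eqn{\sigma = 1}. Applying the normaliser
never re-fits, so validation means are free to differ from zero — the
leakage guard the tests assert.

## Classifier and training schedule

The test backbone is a deliberately small 3-block CNN (3×3 convolutions of
widths 8/16/32, ReLU, 2×2 max-pooling, dense softmax head on the flattened
final feature map), taking the 4-channel tensors downsampled to 32².
Training is mini-batch gradient descent on the cross-entropy with the update
\eqn{\theta \leftarrow \theta - \alpha \nabla L}; options extend it with a
per-epoch step-size decay \eqn{\alpha_e = \alpha/(1 + d(e-1))}, classical
momentum (default 0, i.e. the pure rule), and seeded restarts selected by
final *training* loss (validation data never informs the choice). The
transfer-learning schedule freezes the convolutional base for
`freeze_epochs` (bit-identical weights, asserted in the tests) and then
unfreezes at a reduced rate; the optional mixed objective
\eqn{\lambda L_S + (1-\lambda) L_T} supports training against a source task,
with \eqn{\lambda = 0} (pure fine-tuning) as the operative default. A dense
head on the flattened map was chosen over global average pooling because the
32-feature GAP bottleneck made plain SGD stall at chance on a large fraction
of random initialisations at these sample sizes.

Learnability runs (200 phantoms, 160/40 split) use 64-pixel phantoms,
32-pixel tensors, an 8-direction dictionary, \eqn{\alpha = 0.02}, decay
0.15, momentum 0.9, batch 16, 30 epochs, 3 restarts — sizes chosen so the
whole check trains on one CPU in a few minutes. A label-permutation control
trains the same architecture on shuffled labels and must stay within
\eqn{3\sigma} of chance, guarding the harness against leakage.

## Evaluation

`compute_metrics()` reports the confusion counts with malignant as the
positive class and the five percentage metrics; ratios with empty
denominators are `NA` (absent), never zero. `fold_statistics()` aggregates
per-fold values into mean, median, variance, standard deviation, quartiles
(linear interpolation, type 7), minimum and maximum;
`cross_validate()` produces the stratified repeated k-fold records. k and
the number of repeats are configuration parameters.

## Numerical choices and degenerate inputs

* Periodic extension only: symmetric extension with orthogonal filters would
  break orthonormality, which every invertibility and Parseval guarantee
  relies on. Odd lengths are periodised by replicating the last sample
  (coefficient counts then exceed the pixel count, as expected).
* `db2` filters are built from exact \eqn{(1 \pm \sqrt 3)/(4\sqrt 2)}
  expressions; round trips are exact to ~1e-12.
* The flow dictionary is built as mirrored halves so the slope multiset is
  bitwise closed under negation.
* Degenerate inputs are rejected with diagnostics: non-2D or non-finite
  images, excessive decomposition depth, non-dyadic quadtree inputs
  (with the instruction to pad), negative thresholds, empty blocks,
  mismatched coefficient lengths, re-normalising a normalised tensor.
* 1×1 blocks transform to themselves; zero representations invert to zero
  images.

## Problem sizes used by the checks

Reconstruction: 50 random 64² images. Best-basis optimality: 30 subbands of
8² against exhaustive enumeration (min_block 2). Flow recovery: 100 step-edge
blocks of 16² — at 8² the integer grid cannot resolve the 17-slope
dictionary (adjacent slopes induce identical warp orders and ties resolve to
the smaller |slope|). Sparsity: 50 curved-boundary images at 128².
Count trace: full 2048-image program at 128-pixel output size. Learnability:
200 phantoms at 64². These sizes are the package's own choices for a
single-CPU workflow; all are parameters, and larger runs only relax the
constraints discussed above.

## Known limitations

* The flow model is constant-slope per leaf; genuinely curved flows within a
  leaf rely on quadtree refinement for adaptivity.
* Vertical flows (infinite slope) are not representable; structure steeper
  than the dictionary's `max_slope` falls back to NO_FLOW or subdivision.
* Significance counting is a rate *proxy*; no entropy coding or bitstream is
  produced.
* On speckle-dominated images the sparsity advantage at clinical thresholds
  is marginal (see above); the transform's value there is the geometry-aware
  feature stack, not compression.
* The small CNN is a test backbone: it validates the training contract and
  the learnability of the features, not state-of-the-art accuracy. External
  pretrained backbones can be plugged in through `source_weights`, but are
  out of scope here.
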
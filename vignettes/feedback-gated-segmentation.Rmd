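---
title: "Feedback-gated CNNs and patch-based segmentation: models, parameters, and design choices"
author: "fbcnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-gated CNNs and patch-based segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fbcnn)
```

## The model

`fbcnn` is built around a small convolutional network whose nonlinearities
are reinterpreted as switches. The engine supports six layer kinds:
cross-correlation convolution (sum over input channels of a per-channel
`K x K` correlation, plus a per-output-channel bias), the rectifier
`max(0, x)`, max pooling over non-overlapping windows, flattening, dense
affine maps, and a softmax head. A forward pass records a full *trace*:
every layer's input and output, the binary positivity pattern of every
rectifier, and the argmax position of every pooling window.

The trace makes the gate reinterpretation concrete. A rectifier behaves as
`y = z ∘ x` with `z = 1` exactly where the pre-activation is strictly
positive, and a pooling layer behaves as a gather at its recorded argmax
switch. `gated_forward()` runs the network with *explicit* gates: the
rectifier's `max()` is realized purely by the switch (a gate forced open
passes its pre-activation even if negative), and pooling reads its frozen
switch position. With the feedforward gates this reproduces the ordinary
forward pass bit for bit; with any frozen gate state the image-to-logit map
is affine, so the first-order expansion around the anchor image is exact
(`linearize()`, tested by random probes).

## The feedback optimization

Given an input image and a target output neuron (a class logit, taken
pre-softmax so the objective stays affine under frozen switches), the
feedback problem is to choose the rectifier gates `Z` that maximize the
target. Restricted to one feedback layer the frozen-switch objective is

```
T*(I, Z) = Σ_k α_k z_k x_k + const,
```

with `x_k` the input of feedback neuron `k` (determined by the gates below
the layer) and `α_k` the *contribution weight*: the derivative of the target
logit with respect to the neuron's gated output through the gated pathways
above the layer, excluding the neuron's own gate. `contributions()`
computes `α` as a gradient query on the frozen-switch network, which is
mathematically the sum over connecting pathways of path-weight products;
the equivalence is tested against finite differences and against a
hand-built two-pathway toy.

Both greedy optimizers update one layer at a time, keeping exactly the
neurons with strictly positive contribution:

```
z_k <- 1  iff  α_k · x_k > 0 .
```

Because the objective restricted to one layer's gates is affine and
separable, this update is the *exact* per-layer argmax, so the objective
trajectory is non-decreasing and the sweeps terminate on the finite gate
lattice. **FR** (feedback recovery) visits the feedback layers top-down,
recomputing contributions under the current gates before each layer update;
**FS** (feedback selection) visits them bottom-up, computing the
coefficients once per layer visit under the state entering that visit. With
a single feedback layer the two coincide and attain the global optimum;
with several layers they are greedy and are only guaranteed to land between
the feedforward objective and the exhaustive optimum, which is how the test
suite scores them (`brute_force_gate_search()` enumerates all `2^n` gate
configurations for `n ≤ 16` with a lexicographic tie-break).

Two boundary decisions are deliberate. A zero contribution closes the gate
(`> 0` strictly): a zero-contribution neuron cannot raise the objective,
and closing it keeps the sparsity spirit of the original L1-regularized
formulation, whose weight `λ` is accepted by `feedback_problem()` but
unused by the greedy solvers (they optimize the unregularized linearized
objective). Second, the gate update uses the sign of the *contribution*
`α_k x_k`, not of `α_k` alone. The two coincide whenever the gated
quantities are nonnegative (the feedforward state, and any state reachable
from it when gates only close), but under pure-switch semantics a forced
open gate may pass a negative pre-activation; using the contribution sign
is what makes every update an exact argmax and keeps the monotonicity
guarantee unconditional.

Convergence is declared when a full sweep changes no gate, or when a sweep
improves the objective by less than `tolerance` (default `1e-9` absolute);
`max_sweeps` defaults to 10, which suffices on every seeded micro-instance
in the suite. Pooling switches stay frozen at their feedforward argmax for
the entire optimization; only rectifier layers carry feedback gates.

## Saliency

After convergence, the gradient of the target neuron is set to 1 and
backpropagated through the gated network to the image
(`gradient_map()`). The *visualization map* rescales the gradient map to
`255·(x − min)/(max − min)` with min and max taken jointly over all
channels (preserving inter-channel contrast); a constant map raises an
explicit degenerate-range error rather than producing NaN. The *energy
map* sums the absolute channel values per pixel and divides by the map's L2
norm, so it is non-negative, has unit norm, and is invariant to rescaling
of the gradient map. Both maps are kept real-valued; 8-bit quantization
(round-half-even) happens only at PNG export, so tests assert on real
values.

## The segmentation pipeline

Images are normalized to `[0, 1]` by `(f − min)/(max − min)`. A patch of
`patch_size x patch_size` pixels (default 25, odd so a center exists) is
extracted around every stride-spaced pixel, with mirror (symmetric)
padding at the borders so every pixel can be a center while keeping border
intensity statistics unbiased. The classifier labels each patch; the
center pixel inherits the label, giving the initial mask; with
`stride > 1` the remaining pixels take their nearest center's class.

Refinement has two stages. *Threshold refinement* estimates the mean and
standard deviation of the normalized intensities inside the initial mask
and removes pixels outside the closed band `μ ± k·σ` (default `k = 2`); a
`μ ± kσ` band is the simplest faithful realization of "threshold from the
foreground grayscale distribution", it never adds pixels, and the closed
interval keeps everything when `σ = 0`. Thresholding acts on the
pipeline-internal normalized intensities, not the raw gray levels, so the
band is comparable across inputs. *Morphological refinement* applies
opening then closing (that order removes specks first, then fills gaps;
the order is configurable) with a square structuring element of side
`2·morph_radius + 1` (default radius 1), delegated to EBImage. Dice, IoU
and pixel accuracy score each stage; two empty masks count as a perfect
match, and `Dice = 2·IoU/(1 + IoU)` is asserted as an identity in the
tests.

The pipeline is binary (foreground = `class_of_interest`); multi-class
masks are representable through that parameter but not exercised by the
default tests.

## Training

The default classifier is the smallest stack with two convolutional
feedback layers at patch scale: `conv(5x5, 1→8) → relu → maxpool(2) →
conv(5x5, 8→16) → relu → maxpool(2) → flatten → dense(64) → relu →
dense(n_classes) → softmax` on 25×25×1 inputs. Convolution is
cross-correlation (no kernel flip); padding is `valid` unless configured;
pooling stride equals the window (non-overlapping), dropping incomplete
trailing windows; biases exist per conv/dense output channel and are
treated as fixed inputs with gate 1 inside the feedback objective. Weights
initialize from a seeded zero-mean uniform scaled by `1/sqrt(fan_in)`;
training is plain mini-batch SGD on cross-entropy (defaults: learning rate
0.1, batch 32, 8 epochs), with seeded shuffling so runs are reproducible.

Optional greedy layer-wise pretraining (`net_pretrain()`) trains each
feature block (conv or hidden dense layer plus its rectifier) as a
denoising reconstructor: the block input is corrupted with additive
Gaussian noise, passed through the block and a temporary single linear
decoder, and the mean squared error against the clean input is minimized;
earlier blocks are frozen while later ones train, decoders are discarded,
and the classification head is left for supervised fine-tuning. The
single-linear-decoder form is a design choice; the scheme only prescribes
reconstruction against the uncorrupted input.

## The synthetic generator

`generate_scene()` emulates the statistical structure the pipeline assumes
about lesion-bearing slices: elliptical bright lesions (axis-aligned, the
simplest shape with a nontrivial boundary for morphology), a darker
background, a smooth multiplicative-free bias field (a sum of 2–3
low-frequency cosine components with seeded phases, mimicking MRI-style
intensity inhomogeneity cheaply and deterministically), and additive
Gaussian noise, clipped to `[0, 1]`. The defaults — foreground 0.75 vs
background 0.35, noise σ 0.08, inhomogeneity amplitude 0.1 — were chosen
once as a realistic desk-scale contrast: clearly separable in intensity,
but noisy and shaded enough that the classifier must use patch context.
Lesions are rejection-packed without overlap, and the mask is exactly the
union of the rasterized ellipses, so with zero noise and zero amplitude a
midpoint threshold reproduces the mask perfectly (a tested contract).

What the generator does *not* emulate: modality physics (MR sequences, CT
Hounsfield calibration), partial-volume boundary blur, anatomy-correlated
texture, multi-class tissue taxonomies, and elastic deformations —
augmentation by dense deformation fields is out of scope and was replaced
by the simpler seeded scene variety. Passing the benchmark therefore shows
that the pipeline's mechanics (patch learning, dense prediction,
refinement) work under controlled contrast/noise/inhomogeneity, not that
it reaches clinical accuracy on real data.

## The benchmark and problem sizes

`run_benchmark()` fixes the package's canonical evaluation: 20 scenes of
64×64 pixels, split 70/30 by scene (14 train / 6 test), 1500 training
patches per class sampled class-balanced from the training scenes, the
default classifier trained for 8 epochs, and every test scene segmented
with the default configuration. These sizes were chosen as the smallest
instance that exercises every stage with stable statistics while keeping a
full run (and its repetition in the determinism check) comfortable on a
single CPU. The micro-networks used to score FR/FS against the exhaustive
oracle have 12 gates (8 convolutional + 4 dense) so that the `2^n`
enumeration stays exact and fast; single-feedback-layer variants (8 gates)
provide the separable cases where the greedy optimizers must attain the
oracle optimum.

## Numerical notes and degenerate inputs

Gradient checks use central differences at `h = 1e-5` with a `1e-4`
relative tolerance across every layer kind. Monotonicity assertions allow
`-1e-10` slack for floating-point noise in recomputed objectives; the
underlying updates are exactly non-decreasing in real arithmetic. Max
pooling breaks ties toward the first window element (column-major), making
argmax records deterministic. Constant images cannot be normalized,
constant gradient maps cannot be rescaled, and identically zero gradient
maps have no energy map — all three raise explicit errors. An empty
initial mask passes through threshold refinement as an empty mask with a
warning. Labels are 0-based classes; masks are `{0, 1}` matrices;
coordinates are (row, column).

## Known limitations

- The greedy optimizers guarantee local optimality per layer, not global
  optimality; with multiple feedback layers they can and do stop below the
  exhaustive optimum on some instances.
- The engine is deliberately minimal: no GPU, no autodiff framework, no
  batch normalization or dropout; convolution is im2col + BLAS, adequate at
  patch scale only.
- Pooling switches are never revisited during feedback optimization; the
  feedback acts on rectifier gates only.
- The segmentation head is binary; the multi-class path is configuration
  only and untested at scale.
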
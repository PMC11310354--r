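---
title: "Methods: synthetic tendon deformation, the two-stage strain network, and its benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic tendon deformation, the two-stage strain network, and its benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Tendon strain during voluntary contraction can be read from ultrasound
image sequences by tracking speckle texture between frames.  Classical
texture-correlation estimators (subset-based DIC, and DDE which estimates
the deformation gradient directly) degrade under ultrasound noise and only
return estimates where subsets can be matched.  `strainkit` implements a
learning-based alternative: a two-stage convolutional pipeline that maps an
image pair directly to a dense per-pixel strain tensor field
(\(\epsilon_{xx}, \epsilon_{xy}, \epsilon_{yy}\)), together with the
synthetic data engine used to train and benchmark it, the classical
baselines, error metrics, and the downstream mechanics analysis
(bulk strain, stress, apparent modulus).

Conventions used throughout: image rows are depth \(y\) (superficial at the
top), columns are the longitudinal axis \(x\); pixels are 0-based and
pixel-centred in the compiled interpolation kernels; strain is
dimensionless.

# The synthetic deformation model

The generator plays the role of the study's ground-truth engine, so its
defaults *are* the study conditions rather than tunable knobs.

**Longitudinal strain profile.**  A horizontal tendon band (by default the
central 40% of image depth) carries a deep-edge longitudinal strain
`eps_deep`.  Across the band thickness, \(\epsilon_{xx}\) grades linearly
from `0.75 * eps_deep` at the superficial edge to `eps_deep` at the deep
edge — the 75% superficial/deep ratio reported for tendon loaded in vivo.
Outside the band the strain decays to zero over a C1 smoothstep margin of
0.15 of the image height.  The margin emulates the thin layer over which a
loaded tendon slides past surrounding tissue; it was fixed at a value that
keeps the synthetic deformation map invertible up to the largest benchmark
strain (16%), since the displacement gradient in the margin grows with both
the strain level and the inverse margin width.

**Incompressibility.**  Tendon is modelled as incompressible in-plane: the
transverse strain satisfies \(\epsilon_{yy} = 1/(1+\epsilon_{xx}) - 1\)
(stretch-ratio form), so the area stretch
\((1+\epsilon_{xx})(1+\epsilon_{yy})\) is exactly 1 at every pixel.  This
closed form is exactly testable, and the package asserts it to 1e-9 on
every generated field.

**Shear.**  The displacement field is built by integrating
\(\epsilon_{xx}\) along \(x\) from the anchor column and
\(\epsilon_{yy}\) along \(y\).  Because the longitudinal strain varies with
depth, this construction carries an unavoidable shear
\(\epsilon_{xy} = \tfrac12 (x - x_0)\,\partial_y \phi(y)\), where
\(\phi\) is the depth profile.  Inside the band the depth gradient is
shallow and this shear is below ~0.005 at the 10% level; in the decay
margin it forms a genuine shear band.  The generator stores this
kinematically consistent shear as ground truth rather than forcing
\(\epsilon_{xy}=0\), so the prescribed field and the actual image warp
agree; the trade-off is that the stored shear is only *approximately* zero
inside the tendon.  Round-trip consistency (numerical symmetric gradient of
the integrated displacement against the prescribed field) holds to 1e-3 in
the band interior and for uniform fields; in the margin the prescribed
analytic derivative and the pixel-grid difference disagree at the 1e-2
level, which is inherent to the sharp transition, not a defect of the
integrator.

**Warping.**  Images are deformed with *forward* (Lagrangian) semantics:
the texture at reference pixel \(X\) appears at \(X + U(X)\).  The inverse
map is found per pixel by damped fixed-point iteration and sampled with
bicubic (Catmull–Rom) interpolation.  This matters quantitatively: the
classical backward approximation `out(x) = img(x - u(x))` mis-states the
realised strain at second order (a 16% prescribed stretch would actually
read 19%), which would poison the baselines' ground truth.

**Noise.**  Each frame independently receives, in order, multiplicative
speckle-like noise (unit-mean gamma factor), additive Gaussian noise, and a
global gain/offset jitter, then clipping to [0, 1].  Training strengths are
sampled per frame from uniform ranges (speckle sd in [0, 0.12], additive sd
in [0, 0.04], gain in [0.92, 1.08], offset in [-0.04, 0.04]); benchmark
test cases use fixed strengths (speckle 0.08, additive 0.025, small
gain/offset jitter) scaled by a `noise_scale` argument, with 0.25 used as
the "noise-reduced" benchmark condition and 1 the noisy condition.  These
ranges were chosen once to visibly corrupt speckle correlation without
destroying it, as a stand-in for B-mode imaging noise; no physics-based
(RF/beamforming) simulation is attempted.

**Classes and ranges.**  Training pairs are tension, compression, or rigid
motion in equal proportions.  Deep strains are drawn uniformly from
[0.01, 0.16] (tension) and [-0.16, -0.01] (compression) — magnitudes below
1% are excluded because at speckle scale they are not meaningfully
distinguishable from rigid motion, and the benchmark span is 4–16%.  Rigid
pairs translate uniformly by up to 5 px per axis with no rotation.

**Benchmark test cases.**  Five sequences with maximum deep strain 4, 7,
10, 13, 16%, each following the 3 s ramp / 5 s hold / 3 s relax activation
profile at 1 frame/s (12 frames).  Ground truth per frame is cumulative
strain relative to frame 1 and is stored exactly; the peak deep-edge strain
equals the nominal level to 1e-9.

What the generator does *not* emulate: real B-mode texture statistics
(the substrate is procedural smoothed-noise speckle with a brighter band),
out-of-plane motion, probe or anatomy variability, and physiological
variation between trials.  Passing the desk-scale benchmarks therefore
demonstrates correct mechanics of the pipeline and its advantage over the
baselines *under the modelled conditions*, not clinical performance.

# The two-stage model

Stage one (`build_classifier`) is a convolutional classifier
(conv / batch-norm / ReLU / max-pool blocks, then a fully connected head)
that labels a pair as tension, compression, or rigid; ties break to the
lowest class index.  Stage two routes the pair to one of three independent
UNet-style regressors (`build_regressor`) — one per class — with a single
conv/BN/ReLU block per scale, 2×2 max-pool downsampling, nearest-neighbour
upsampling (avoids checkerboard artifacts; bilinear is the config
alternative), skip concatenations at matching resolutions, and a final
*linear* 1×1 convolution so strains can be negative.  Inputs are the two
frames, each min-max normalised, stacked as channels; frames are
reflection-padded to a multiple of \(2^{\text{depth}}\) and cropped back.

No deep-learning framework is used: convolution and pooling
forward/backward passes are compiled (RcppArmadillo, im2col + GEMM), and
batch normalisation, the dense head, and Adam are vectorised R.  The
backward passes are verified against numerical differentiation in the test
suite.

Exact layer widths are architecture choices, not reproductions.  The tiny
(CPU) profile uses depth-4 encoder widths (8, 16, 32, 48) with a
96-channel bottleneck for the regressors: the prescribed fields are
globally coherent (a depth profile scaled by one loading parameter), so
the extra pooling stage, which lets the bottleneck see most of the frame,
cuts the noisy-benchmark error substantially compared to a depth-3
variant.  The classifier uses depth-3 widths (8, 16, 32), so the
flattened feature map keeps an 8x8 spatial layout.  The spatial layout
matters: with a fourth pooling stage the classifier plateaued one
validation sample short of perfect, systematically confusing rigid pairs
with sub-pixel shifts (0.3-0.9 px) for ~1% strain, and the shallower
pyramid resolves exactly that distinction.  The `full`
profile doubles widths and trains 100 epochs; it follows the same code path
but is not exercised by the desk-scale tests.

# Training

Each stage has the loss its task calls for: the
classifier minimises cross-entropy over the three classes (probabilities
clipped at 1e-12), and each regressor minimises the mean squared mismatch
of the *full* 2×2 strain tensor, averaged over pixels and examples.
Because the stored shear channel occupies both off-diagonal tensor slots,
its squared error counts twice — a deliberate, documented consequence of
the tensor double sum; a naive "3-channel MSE" would weight shear half as
much.

The dataset splits 80/20 stratified by class (stratification guarantees
every class in both splits at tiny scale), the optimiser is Adam, batch 10 for
the regressors and for the tiny-profile classifier (100 at full scale),
30 epochs in the tiny profile.  The tiny profile trains at learning rate
2e-3 (both stages): with only ~240-720 update steps available, the
full-scale rate of 1e-3 (used by the `full` profile) leaves the networks
visibly under-converged, and the classifier in particular then fails to
separate sub-pixel rigid motion from ~1% strain.  For each subnetwork the retained
checkpoint is the epoch with the best validation metric (accuracy with
loss tiebreak for the classifier, loss for the regressors).  All
randomness — dataset, split, initialisation, shuffling — derives from one
integer seed, and retraining with the same seed reproduces the run.

# Inference over sequences

Two pairing conventions exist for sequences and both are implemented.  The
default `reference` mode pairs every frame with frame 1, so each
prediction is directly the cumulative strain relative to the start —
matching how the benchmark ground truth is defined.  The `incremental`
mode pairs consecutive frames and composes per-step strain by stretch-ratio
multiplication on the diagonal and additive shear, a small-strain
approximation that is exact for uniform uniaxial steps
(e.g. 5% then 5% compose to 10.25%).  The mode is recorded in the output.

# Baselines

DIC: per subset, an integer NCC search followed by Gauss–Newton refinement
of a 6-parameter affine (linear shape function) on the zero-mean SSD of
bicubically interpolated intensities; displacement at the subset centres is
then differentiated by least-squares plane fits over 3×3 centre
neighbourhoods (the minimal standard smoothing window).  DDE: identical
tracking, but strain is read directly from the converged affine gradient
\(F\) as \(\tfrac12(F + F^\top) - I\), with no displacement
differentiation.  Subsets with insufficient texture, failed convergence, or
final correlation below 0.5 are invalid; dense fields come from bilinear
interpolation between centres, so both baselines cover strictly less than
the full frame — unlike the network, which is dense by construction.
Defaults (subset 21 px, step 8 px, search radius 8 px, 50 iterations,
tolerance 1e-4 px) suit the 64×64 benchmark; `tune_subset_grid` performs
the grid search over subset and step sizes that stands in for per-dataset
hyperparameter tuning.

# Error metrics and statistics

The spatial strain error at a pixel is the Frobenius mismatch of the full
tensor, \(\sqrt{\sum_{ij} (\hat\epsilon_{ij} - \epsilon_{ij})^2}\) (shear
counted twice).  The per-frame error is its median over the overlap region
(pixels where *all* compared methods are valid), and the cycle-level
"median strain error" pools all (pixel, frame) samples into one median —
a single pooled median, not a median of medians, following the subscript
convention of the source metric.  Method comparisons use a two-sided
permutation test on the difference of sample medians with the add-one
estimator; pixels within a frame are spatially correlated, so the p-values are
optimistic; they are reported without a correlation correction (a
documented caveat), and the unit of permutation (pixels by default, frames by
subsampling choice) is left to the caller.

# Mechanics

Bulk longitudinal strain of a trial is the pooled median of
\(\epsilon_{xx}\) over tendon pixels and hold-phase frames (default window
3–8 s).  Grip force maps to tendon force by a configurable linear
transmission coefficient (default 0.25) — the anatomical moment-arm
relation is deliberately not hard-coded.  Stress is tendon force over
cross-sectional area (N/mm² = MPa), and the apparent modulus is the slope
of the best ordinary-least-squares line over all contiguous loading-phase
windows covering at least 40% of the points, selected by maximum \(R^2\) —
a transparent stand-in for a manual "linear region" choice.  Effort-level
relationships use OLS with subject as a fixed blocking factor when several
subjects are present.

# Numerical choices and problem sizes

* Desk-scale study conditions: 64×64 frames, 300 training pairs, 30
  epochs, benchmark at five levels × 12 frames.  These sizes make the full
  two-stage training run in minutes on one CPU core while leaving the
  learning problem non-trivial; all heavier configurations are reachable
  through `training_config`.
* Bicubic interpolation uses the Catmull–Rom kernel (a = -0.5) with edge
  replication; the warp inverse iterates at most 60 damped fixed-point
  steps to 1e-8.
* Batch-norm uses momentum 0.1 running statistics for evaluation mode;
  probability clipping at 1e-12 prevents infinite classification loss.
* Classifier ties break to the lowest class index; degenerate (zero
  variance) subsets and non-converged Gauss–Newton fits are invalid data,
  never errors.

# Known limitations

* The speckle substrate is procedural; any user-supplied grayscale image
  can substitute, but no claim is made about transfer to real B-mode data.
* The tiny model's strain-magnitude calibration depends on the input
  noise level: batch-norm inference statistics are collected on noisy
  training activations, so much cleaner inputs read 15-20% high in bulk
  strain, while inputs at the benchmark noise level are calibrated to
  within roughly 10-15%.  Mechanics round-trips are therefore evaluated
  under the benchmark imaging noise, as the median over five repeated
  trials - the same repeat count as the loading protocol this emulates.
* Only three bulk deformation modes are modelled; no rotation in the rigid
  class, no out-of-plane motion.
* The incremental composition is a small-strain approximation for shear.
* The permutation test treats pixels as exchangeable units; spatial
  correlation makes its p-values optimistic.
* The grip-to-tendon transmission and the cross-sectional area are inputs,
  not estimates.
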
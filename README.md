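# strainkit

Full-field 2D strain estimation for ultrasound-like image sequences of
tendon, using a two-stage convolutional pipeline, with a synthetic
ground-truth data engine, classical DIC/DDE baselines, error metrics, and
downstream tendon mechanics.

## The problem and who this is for

Measuring how much a tendon stretches during a voluntary contraction from
B-mode ultrasound requires tracking speckle texture between frames.
Subset-based digital image correlation (DIC) and direct deformation
estimation (DDE) do this by local template matching; both lose accuracy
under imaging noise and only cover the region where subsets can be
matched.  `strainkit` is for researchers in tissue biomechanics and
medical image analysis who want (a) a learning-based strain estimator
that returns a dense per-pixel strain tensor field, (b) a controlled
synthetic benchmark with exact ground truth to quantify estimator error,
and (c) the bulk-mechanics quantities (stress-strain curves, apparent
modulus) derived from those strains.

## The method

**Two-stage model.**  Stage one is a convolutional classifier that labels
an image pair \((I_a, I_b)\) as *tension*, *compression*, or *rigid-body
motion*.  Stage two routes the pair to a class-specific UNet-style
encoder-decoder that regresses the full strain field
\((\epsilon_{xx}, \epsilon_{xy}, \epsilon_{yy})\) at input resolution.
The classifier trains with cross-entropy
\(\mathcal{L}_{CE}(p, y) = -\sum_{i=1}^{C} y_i \log p_i\) (C = 3), each
regressor with the mean \(\ell_2\) loss over the full 2×2 strain tensor

\[
\mathcal{L}_{\ell_2} = \frac{1}{N}\frac{1}{P} \sum_{n=1}^{N} \sum_{p=1}^{P}
\sum_{i=1}^{2}\sum_{j=1}^{2}
\left|\hat\epsilon_{ij,p}^{(n)} - \epsilon_{ij,p}^{(n)}\right|^2,
\]

where the symmetric shear occupies both off-diagonal slots.  All network
primitives (conv/pool forward and backward, batch norm, Adam) are
implemented natively (RcppArmadillo); no deep-learning framework is used.

**Synthetic ground truth.**  Speckle substrates are warped by prescribed
tendon deformation fields: longitudinal strain grades from 75% of the
deep-edge value at the superficial edge to the full value at the deep
edge, transverse strain enforces in-plane incompressibility
\(\epsilon_{yy} = 1/(1+\epsilon_{xx}) - 1\), and loading follows a
3 s ramp / 5 s hold / 3 s relax activation profile.  Benchmark sequences
peak at 4, 7, 10, 13, and 16% deep strain with ultrasound-like noise
(multiplicative speckle + additive Gaussian + gain/offset jitter).

**Error metrics.**  Per-pixel spatial strain error
\(\sqrt{\sum_{ij}(\hat\epsilon_{ij}-\epsilon_{ij})^2}\), per-frame median
over the overlap region shared by all methods, and the cycle-pooled
median strain error; methods are compared with two-sided permutation
tests on the difference of medians.

**Mechanics.**  Bulk longitudinal strain is the pooled median of
\(\epsilon_{xx}\) over tendon pixels during the hold phase; grip force
maps to tendon force by a configurable transmission coefficient, stress
is force over cross-sectional area (MPa), and the apparent modulus is the
slope of the maximum-\(R^2\) window of the loading-phase stress-strain
curve.

## Worked example

Train the desk-scale (tiny) profile and score it on the synthetic
benchmark — about 8 minutes on one CPU core:

```r
library(strainkit)

samples <- generate_training_set(300, seed = 7)        # 64x64 speckle pairs
fit     <- train_all(samples, training_config("tiny", seed = 7))
fit$report$val_accuracy
#> [1] 1

models <- fit[c("classifier", "tension", "compression", "rigid")]
cases  <- generate_test_cases(seed = 7, noise_scale = 0.25)  # 5 levels
pool <- c()
for (tc in cases) {
  pred <- predict_sequence(models, tc$sequence, "reference")
  for (t in seq_along(pred$fields))
    pool <- c(pool, spatial_strain_error(pred$fields[[t]], tc$truths[[t]]))
}
median(pool)
#> [1] 0.005013043
```

The validation accuracy of 1 means every held-out training pair was
assigned its correct deformation class.  The pooled median strain error of
0.0050 (0.5% strain) says that across all five benchmark sequences and
all frames, half of all pixels are within 0.005 of the true strain
tensor — on loading levels spanning 4–16% peak strain.  For comparison, on
the *noisy* benchmark the same model's pooled median error is 0.0081
against 0.0138 for DIC and 0.0239 for DDE over the same overlap region
(the ordering the benchmark is designed to probe).

A command-line front end is available for the main steps
(`exec/strainkit generate | train | infer | baseline | evaluate |
mechanics | demo`).

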
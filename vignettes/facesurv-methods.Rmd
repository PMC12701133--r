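---
title: "Methods: multimodal seven-day survival prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal seven-day survival prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Short-horizon survival triage for critically ill patients combines two very
different kinds of evidence: a table of physiological indicators (vital
signs, blood gases, coagulation and liver panels, neurological scores) and
what a clinician reads off the patient's face. `facesurv` implements a
complete, testable version of a framework that couples a bespoke facial
landmark detector with a recurrent tabular classifier to predict a binary
outcome: death within seven days (label 1) versus survival beyond seven
days (label 0).

Cohorts of this kind are private, so the package ships a synthetic-data
module with fully known generative structure. Every claim the test suite
makes is a claim about this synthetic family, not about clinical data; the
synthetic module is first-class, seeded and itself under test.

## The detector

The feature extractor is a small convolutional network with three parts.

**Residual stem.** The input passes through two parallel 3x3 convolutions.
The first is followed by a ReLU (`G = relu(conv_c(x))`); the sum
`u = G + conv_d(x)` is then modulated channel-wise by a projection of its
own global average pooling and passed through a Softplus:

```
stem(x) = softplus(u * (W_gap %*% gap(u) + b_gap))
```

A literal global average pooling would collapse the spatial grid that the
detection head needs, so the pooled vector acts as a squeeze-excite-style
gate that preserves spatial dimensions; the Softplus keeps every stem
output strictly positive. In the assembled backbone both stem convolutions
use stride 2 and are followed by one 2x2 average pooling (total stride 4).

**Staged body.** Three stages, each a stride-2 3x3 convolution followed by
residual blocks (two 3x3 convolutions plus identity skip), with default
widths 32/64/128 and depths 1/2/2 — a deliberately light staged design. On
a 96-pixel input the bottom-up maps `C1..C3` sit at strides 8, 16, 32.

**Path-aggregated pyramid.** A top-down pass

```
P_i = Con(C_i) + H(P_{i+1})
```

where `Con` is a 1x1 lateral convolution and `H` is separable
cubic-convolution upsampling (Catmull-Rom kernel, `a = -0.5`, 4-point
support, half-pixel centers, border replication). The interpolation weights
form a partition of unity, so constants are reproduced exactly and the
operator is linear — both are tested properties. Upsampling factors 2 and 3
are supported; the factor used between adjacent levels is their spatial
ratio (2 for a halving pyramid). A second aggregation pass then runs finest
to coarsest with stride-2 3x3 convolutions,

```
F_1 = Con(P_1),   F_i = Con(P_i) + Down(F_{i-1})
```

matching the "path aggregation" reading of the second pass; a top-down
variant is available as a configuration switch. All fused maps share one
channel width.

**Head and training.** A one-stage anchor head (shared 3x3 tower, 1x1
class and box branches) rides on the fused maps. We chose the one-stage
form because no proposal stage or RoI pooling is specified anywhere for
this architecture; the anchor machinery, IoU assignment (positives at IoU
>= 0.5, negatives <= 0.4, best anchor per target force-matched), focal
classification loss, smooth-L1 box regression, per-class greedy NMS and
COCO-style evaluation exercise every component at desk scale. Focal loss
parameters default to alpha 0.5, gamma 2: with only ~15 positive anchors
per image against ~1700 negatives, the balanced alpha measurably speeds
convergence of the cross-class discrimination (eye versus lip) that
dominates the error budget late in training. The class and box branches start
near zero (weights with standard deviation 0.01, class bias at the 1%
background prior) — without this standard focal-head initialization,
training collapses on some seeds. Optimization is per-image Adam (rate
5e-3, linear warmup over the first ~200 steps, step decay by 0.3 for the
final third of the schedule, global gradient-norm clipping at 50 against
rare spike steps), fully deterministic given the seed. The training recipe is entirely this
package's choice; nothing in the model equations fixes one.

The whole network, including the interpolation, is differentiated by a
small in-package reverse-mode tape on base-R arrays (convolution as
im2col + BLAS matrix multiply); a finite-difference gradient check on a
tiny instantiation is part of the test suite.

## The tabular classifier (ETED)

The 36 indicators (plus facial features, when fused) are standardized and
partitioned in column order into `T = 6` pseudo-timesteps (zero-padded when
not divisible). The sequence construction is a design
decision: feeding tabular data to an LSTM requires one, and nothing in
the model equations prescribes it. Each
timestep passes through an elementwise affine map
`z_t = x_t * w_t + alpha_t` (the printed form; a matrix-multiply variant is
deliberately not the default), then a standard LSTM
(`f, i, o = sigmoid(W h + U x + b)`, `C_t = f C_{t-1} + i tanh(...)`,
`h_t = o tanh(C_t)`; all gates consume the same per-timestep input, reading
the one divergent gate equation as notational shorthand). Attention weights
over the hidden trajectory are `softmax(tanh(score))` with a learned linear
score per timestep; the pooled state `R = sum_t w_t h_t` is multiplied by a
sigmoid gate `sigmoid(<R, f(z)>)` (one value per sample; gating the hidden
states instead is a configuration switch), and a batch-normalized residual
branch `BN(relu(W z + b)) + B` is added before a single sigmoid output
unit. Batch normalization uses batch statistics in training (batch size
must exceed one; a single-sample training batch is an explicit error) and
running statistics (momentum 0.1) at inference.

Training minimizes binary cross-entropy with Adam (rate 1e-3 to 3e-3,
batch 32, early stopping on validation AUC with patience 10-20). The
decision threshold for hard labels is 0.5 throughout.

## Fusion

Facial features are hand-crafted summaries of the detector output per
patient: eye/lip counts, mean eye confidence, mean eye box aspect ratio,
inter-eye center distance over image width, eye box area fraction, the
across-frame aspect standard deviation (the "variability" channel, zero
for the default single frame), and two missing flags. Fusion is early
concatenation after standardization; all statistics (standardization and
imputation means) come from the training split only and are frozen — a
leakage test perturbs the test split and asserts the statistics are
unchanged. The unimodal and multimodal arms share the same split and seed
so the comparison isolates the facial channel.

## Synthetic data

**Images.** Each image is a low-frequency textured background (coarse
Gaussian grid enlarged with the package's own cubic interpolation) with
two ellipse "eyes" and one wider, flatter ellipse "lip" added at a
configured contrast, plus optional pixel noise. Ground-truth boxes are the
exact ellipse bounding boxes. The clinical facial signal is carried by the
eye aspect ratio (height/width = `0.5 + 0.45 * signal`): a single static
geometric proxy: eye-movement variability is the clinically motivated
facial signal, but no standard operationalization of it exists, so a
single static carrier keeps the fixture simple and exactly checkable. Multiple frames per
patient are supported but default to one.

**Cohort.** The 36 indicators draw from independent normal marginals with
clinically plausible means and spreads (an optional correlation matrix
knob exists because real indicators are correlated); the label follows

```
label ~ Bernoulli(plogis(intercept + beta . x_std + gamma * s)),  s ~ N(0, 1)
```

with `x_std` standardized by the stated means/SDs and `s` the latent
facial signal whose `pnorm(s)` drives the image generator. The default
`beta` places nonzero weight on the indicators the field would expect
(pressures, coma scale, coagulation panel), signed so that the died group
shows the reported directional pattern; the default intercept of -1 gives
roughly one-third label prevalence. The strong-coefficient benchmark used
by the learnability checks scales `beta` by 4 with `gamma = 0`, which puts
the Bayes-optimal AUC near 0.99 so that a competent classifier can be held
to a high bar.

What the synthetic family does *not* emulate: photorealistic faces,
disease-to-face physiology, indicator correlation (by default), missing
clinical values, and temporal measurement. Passing tests therefore
demonstrate implementation correctness and learnability on this family,
not clinical performance.

## Numerical choices and degenerate inputs

- Boxes are 0-based, half-open pixel corners; COCO `[x, y, w, h]` is
  converted at the boundary. Degenerate annotation boxes are dropped with
  a warning and counted.
- Confidence ties (NMS and AP matching) break by input order, making all
  metrics deterministic.
- AP uses all-point interpolation; the IoU grid defaults to 0.50:0.95 step
  0.05 with AP at 0.5 reported separately; AUC is the Mann-Whitney rank
  statistic with ties counted one half.
- The logistic fit is IRLS with step halving (the log-likelihood trace is
  non-decreasing, a tested invariant); separation is flagged when fitted
  log-odds exceed 25 in magnitude, and zero-variance columns are dropped
  with a warning. Wald intervals (`B +/- 1.96 SE`) match the tabular
  `B/SE/t/CI/OR` reporting convention of the field.
- Group comparisons default to Welch's t-test (robust to unequal
  variances), with a Mann-Whitney switch; p-values are reported marginally,
  with an optional Benjamini-Hochberg adjustment off by default.
- Feature impact is permutation importance (mean absolute change in
  predicted probability under within-column shuffling), chosen over
  gradient attributions because it is model-agnostic and cheap at this
  scale; a constant column has exactly zero impact.

## Problem sizes

The test suite and the acceptance script run the study conditions at desk
scale, chosen once: detector learnability uses 200 training / 50 held-out
96-pixel images over 18 epochs (3 seeds); ETED learnability uses cohorts
of 1250 (1000 train / 250 test, 5 seeds); the multimodal comparison uses
cohorts of 600 (70/30 split, so 180 test patients per seed — the AUC
difference between arms needs that many to resolve a true null below
0.03) over 10 seeds per arm with one shared small detector so that the
contrast isolates the facial channel; logistic recovery uses 100
replicates at n = 2000.

## Known limitations

- The detector is one-stage by design; the two-stage extension point is a
  configuration flag, not an implementation.
- No decoder exists despite the "encoding-decoding" name of the tabular
  model; nothing in the equations defines one.
- The pseudo-timestep partition of the indicator vector is arbitrary
  column grouping; results could depend on indicator order in principle.
- Training is single-threaded base R: adequate for the tested scales
  (minutes), not for large cohorts or high-resolution imagery.
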
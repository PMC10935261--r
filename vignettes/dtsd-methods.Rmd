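---
title: "DTSD distillation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTSD distillation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtsdistill)
```

# The model

`dtsdistill` trains a small *student* classifier against two signals: the
ground-truth labels, and a fused soft label built from two pretrained
*teacher* networks. Three pieces define the method.

## Teacher fusion (Max_out)

Each teacher's logits $z^{(m)}$ are softened by a temperature softmax
$q^{(m)} = \mathrm{softmax}(z^{(m)}/T)$. The fused label takes the
element-wise maximum and renormalizes:

$$\tilde q_j = \frac{\max(q^{(1)}_j, q^{(2)}_j)}{\sum_k \max(q^{(1)}_k, q^{(2)}_k)}.$$

The maximum keeps, per class, the more confident teacher's probability, so
two teachers with complementary strengths produce a label sharper than
their average. Two invariants are tested: fusing a teacher with itself is
the identity, and the renormalized result is always a probability vector.
Renormalization can be disabled (`renormalize = FALSE` in
`compute_distill_loss()` or the `distill:` block of a YAML run config) to
study the unnormalized variant; it is on by default because the
Jensen–Shannon soft loss assumes probability-vector arguments.

## Supervised decay schedules

Training progress $x \in [0,1]$ is the fraction of optimizer steps
completed (`progress_fraction()`). Both schedules ride one logistic curve
$\sigma(s(x - x_0))$ with steepness $s = 10$ and midpoint $x_0 = 0.5$:

- temperature $T(x) = 3\,\sigma(10(x - 0.5))$, rising from ≈0.02 to ≈2.98;
- loss weight $\lambda(x) = 1 - \sigma(10(x - 0.5))$, falling from ≈0.99 to
  ≈0.007.

The loss is $L = (1-\lambda)L_{\text{soft}} + \lambda L_{\text{hard}}$.
Early training is dominated by cross-entropy on hard labels with a
near-argmax (low-$T$) soft term; late training is dominated by matching
soft teacher distributions at high temperature. The coupling
$T/3 + \lambda = 1$ makes the soft branch's gradient prefactor
$(1-\lambda)/T = 1/3$ exactly constant over the whole run — the schedule
shifts *what* the student matches, not *how hard* it is pushed.

**Parenthesization.** The temperature formula is implemented as
$3\,\sigma\big(10(x - 0.5)\big)$ — steepness multiplying the *centered*
progress. A literal alternative reading, $3\,\sigma(10x - 0.5)$, is
available behind `schedule_params(literal_temperature = TRUE)` for
comparison; it is not the default because it starts above $T = 1$ at
$x = 0$ (no hard-label warm phase) and breaks the $T/3 + \lambda = 1$
coupling with the $\lambda$ schedule.

## Losses and gradients

$L_{\text{soft}}$ is the Jensen–Shannon divergence
$\tfrac12 KL(p\,\|\,m) + \tfrac12 KL(q\,\|\,m)$, $m = (p+q)/2$, between the
fused teacher label and the student's $T$-softened softmax. JS is
symmetric and bounded by $\log 2$, which keeps the soft loss finite even
when teacher and student disagree completely. $L_{\text{hard}}$ is
cross-entropy against the one-hot label at $T = 1$.

The backward pass is analytic: $\partial JS/\partial s_j =
\tfrac12\log(s_j/m_j)$, composed with the temperature-softmax Jacobian
$(\mathrm{diag}(s) - ss^\top)/T$ for the soft branch and the usual
$\mathrm{softmax} - \mathrm{onehot}$ for the hard branch, averaged over the
batch. The test suite verifies this against central finite differences
through the full network (tolerance $10^{-4}$ on a relative scale).

No $T^2$ scaling of the soft loss is applied by default (the constant
$1/3$ prefactor already stabilizes the gradient); the classical
$T^2$ correction is available via `t_squared_scaling = TRUE`.

# Parameter defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| `scale` | 3 | Peak temperature; 3 gives genuinely soft labels (mean max-probability ≈ 0.6 for a converged teacher here) without washing them out. |
| `steepness`, `midpoint` | 10, 0.5 | A switch-like but smooth handover centered mid-training. |
| `base_lr` | 0.0037 | Works across all three decline strategies at the default scale. |
| `lr_strategy` | `exponential_warmup` | Linear ramp over the first 10% of steps, then 0.96 per-epoch decay; `piecewise` (×0.1 at 1/3, 2/3) and `cosine` are alternatives. |
| `batch_size`, `epochs` | 16, 15 | Desk-scale defaults; the CLI `--profile full` switches to 60 epochs at 320 px. |
| `momentum` | 0.9 | Standard SGD momentum. |
| `clip_norm` | 5 | Global L2 gradient clip as a loose safety net; see design notes below. |
| `occlusion` probs | 0.15 / 0.10 / 0.05 | Cutout / random-erasing / hide-and-seek branch probabilities, mutually exclusive per image (70% of images untouched). |
| `p_sub_strategy` | 0.10 | Each transformation sub-strategy (rotation+flip, crop, jitter) fires independently. |
| `occlusion_area_range` | 0.10–0.20 | Fraction of image area removed by an occluder. |
| `expansion_factor` | 10 | `expand_dataset()` keeps the original plus 9 augmented variants. |

Numerical floors: probabilities are floored at $\varepsilon = 10^{-12}$
inside every $\log$, and the temperature at $10^{-3}$, so the $x = 0$ end
of the schedule (where $T \approx 0.02$) cannot underflow the softmax into
NaNs. The sigmoid uses the branch form
$\{1/(1+e^{-t});\ e^{t}/(1+e^{t})\}$ so it never exponentiates a large
positive argument.

# The synthetic dataset

`generate_synthetic_dataset()` produces a 10-class, 100-images-per-class,
64 px corpus (320 px supported) in which each class is a procedural
signature: a base hue, a sinusoidal texture with class-specific frequency
and orientation, and a centered blob (disk, square or ring), plus Gaussian
pixel noise (sd 0.08). It emulates the *shape* of a small fine-grained
image-classification problem — number of classes, images per class,
stratified 7:2:1 splits, image sizes — so the full pipeline runs end to
end in minutes on a CPU.

It deliberately does **not** emulate the difficulty of real photographs:
classes are separable by a nearest-centroid classifier on mean RGB (a
property the tests assert), there is no background clutter, pose or
lighting variation, and no label noise. Conclusions about *relative*
method behaviour (e.g. distilled vs. plain student under identical seeds)
transfer; absolute accuracies do not.

`stratified_split()` uses floor counts per class with remainders assigned
train-first, so a 100-image class under 0.7/0.2/0.1 gives exactly 70/20/10
— the arithmetic is re-derived independently in the tests.

# Design decisions

**Pure-R networks.** The registry (`tiny-cnn-teacher` ≈ 47k parameters,
`tiny-cnn-student` ≈ 3k) is implemented directly on BLAS: 3×3 convolutions
are im2col gathers (precomputed index maps with a zero-pad row) followed by
one GEMM; the backward scatter is a single `rowsum()`. A teacher epoch on
the 10×100×64 px corpus takes a few seconds.

**Student capacity as the pretraining stand-in.** In the full-scale
setting, students start from pretrained backbones. Desk-scale students
start from random weights, so the student must be able to converge within
the 15-epoch window *before* $\lambda$ decays away the hard-label signal —
otherwise supervision is removed mid-learning and distillation
underperforms. The two-block student converges by epoch ~7 at default
settings, comfortably before the midpoint handover; this capacity choice,
not loss tweaks, is what makes desk-scale distillation keep pace with
plain training.

**Gradient clipping (`clip_norm = 5`).** The very low temperatures early in
training can produce occasional large soft-branch gradients on a random
student. A global-norm clip at 5 never engages on well-behaved runs
(trajectories are identical to `clip_norm = Inf` at desk scale) but bounds
the damage of a pathological batch. Tighter clipping (e.g. 1) measurably
slows plain training and is not the default.

**Best-validation checkpoint selection.** When a validation partition is
present, `train_supervised()` and `distill_student()` return the weights of
the earliest epoch with the best validation accuracy (reported as
`best_epoch`), not the final-step snapshot. Late DTSD training is almost
pure soft-label matching at high temperature, and the final epoch can be a
slightly drifted snapshot of an already-converged model; selecting on
validation — the standard use of a validation split — evaluates the model
a practitioner would actually keep. Without validation data the final
weights are returned.

**Shared training loop.** `train_supervised()` and `distill_student()` run
the same loop consuming identical RNG streams, so freezing
`lambda_const = 1` makes distillation reproduce plain training *bit for
bit* — an endpoint identity the acceptance tests check with
`expect_identical()` on the final weights.

**Augmentation policy structure.** Transformation sub-strategies are
independent Bernoulli draws (an image can be rotated *and* jittered);
occlusions are one categorical draw per image because overlapping cutouts
would compound removed area past the intended 10–20% range. Every
augmented image stays in $[0,1]^{h\times w\times 3}$ and keeps its
geometry, and the empirical firing rates are verified against their
nominal probabilities at $n = 10^5$ (±0.5 percentage points).

# Problem sizes used in validation

- Unit scale: 3 classes × 12–40 images at 16 px (seconds).
- Desk scale: 10 classes × 100 images at 64 px, 7:2:1 split, two teachers
  (seeds 11, 22) trained 15 epochs to ≥ 0.95 validation accuracy, then five
  paired student seeds trained 20 epochs comparing DTSD vs. no-distillation
  test accuracy — 20 so the hard-label phase (before the λ midpoint) covers
  even slow-converging initializations (≈ 12 minutes total; run in
  `tests/testthat/test-acceptance.R`).
- Reference rates: $10^5$ Monte Carlo draws per augmentation quantity
  (`scripts/acceptance.R`).
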
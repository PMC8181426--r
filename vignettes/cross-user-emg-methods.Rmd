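---
title: "Cross-user EMG gesture recognition: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-user EMG gesture recognition: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emgadapt)
```

## The problem

Pattern-recognition myoelectric control decodes hand gestures from
multichannel surface EMG. Conventionally every user records a full
training protocol (many repetitions of every gesture) before the system
works — a major adoption barrier. Cross-user models try to reuse data
pooled from other users so that a new user supplies only a single
repetition of each gesture. The obstacle is inter-subject variability:
electrode placement, skin impedance, tissue filtering and individual
muscle-recruitment patterns all shift the signal distribution between
users, so a classifier trained on pooled users degrades badly on a new
one.

This package implements and compares, end to end, the main families of
solutions on a common synthetic testbed:

* handcrafted feature sets (TD, TDAR, TDPSD, LSF4, LSF9) with an LDA
  classifier, trained within subject (8 repetitions) or from a single
  repetition;
* CCA-style cross-user adaptation: a ridge-regression projection from
  each user's standardized feature space into an "expert" user's space,
  learned from class-paired samples, with a pooled LDA in the expert
  space; a new user is adapted from one repetition per gesture;
* a per-channel temporal CNN trained on pooled users and applied
  naively to a new user;
* ADANN: the same CNN backbone with (a) one set of batch-normalization
  running statistics per subject (shared weights) and (b)
  domain-adversarial training through a two-neuron domain head whose
  gradient is sign-flipped (scaled by $-\lambda$, $\lambda = 0.1$) into
  the convolutional trunk. A new user is adapted by forward passes over
  one repetition per gesture that update only their batch-normalization
  statistics.

## Preprocessing and features

Signals are notch filtered at 60 Hz (2nd-order RBJ biquad, Q = 30) and
high-pass filtered at 20 Hz (4th-order Butterworth). Both filters are
applied forward–backward (zero phase) by default so that windows are not
phase-shifted relative to their labels; offline analysis permits this,
and `filterSpec(causal = TRUE)` restores single-pass filtering. An
acquisition chain's analog anti-aliasing filter is a hardware property
and is not re-implemented; the synthetic generator is already
band-limited. Zero-phase filtering uses odd-reflection
padding (up to 1,000 samples per side) because the notch's long
ring-down would otherwise leak edge transients into short recordings.

Windows are 151 ms advanced by 50 ms (`round(ms * fs / 1000)` samples;
exactly 151/50 samples at 1,000 Hz), never spanning repetition
boundaries. Ramp-up windows are retained.

Feature formulas follow the canonical published definitions, frozen in
the function documentation. Points where the literature leaves room:

* Deadband thresholds for ZC, SSC and WAMP default to 0 (assumption-free
  in arbitrary amplitude units) and are configurable.
* AR coefficients (TDAR) are reported in the polynomial convention
  $A(z) = 1 + \sum_j a_j z^{-j}$ (an AR(1) process with coefficient
  0.9 yields $a_1 \approx -0.9$), estimated by Levinson–Durbin on the
  biased autocorrelation without demeaning.
* MSR (LSF4) is read as $\frac{1}{N}\left|\sum_i \mathrm{sign}(x_i)
  \sqrt{|x_i|}\right|$, a real-valued reading of the "mean of the square
  root"; WAMP counts steps strictly above the threshold, so an all-zero
  window has WAMP 0 at threshold 0.
* Logarithms of underflowing arguments are floored at a configurable
  value (−20): all-zero windows occur in rest-like classes.
* TDPSD combines the six log-moment features of the raw window and of
  its log-scaled version ($\log(x^2)$) elementwise as
  $-2ab/(a^2+b^2)$. Note that this construction is **not** exactly
  amplitude-scale invariant: only the ratio features (sparseness,
  irregularity, waveform-length ratio) are invariant on the raw branch,
  while the log-moments shift additively under scaling. The test suite
  therefore pins oracle equivalence and channel symmetry, not scale
  invariance, for TDPSD.

## LDA and CCA

The LDA uses per-class means, a pooled covariance (within-class scatter
divided by $n - C$), uniform priors (all frameworks are
class-balanced), and breaks ties toward the lowest class id. A ridge
$10^{-9}\,\mathrm{tr}(\Sigma)/d$ is added only if factorization fails,
with a message — silent shrinkage would change results invisibly.

The CCA projection solves
$\min_W \sum_i \lVert W^\top t_i - x_i \rVert_2^2 + \lambda\lVert W
\rVert^2$ in closed form, $W = (T^\top T + \lambda I)^{-1} T^\top X$,
with $\lambda = 0.04$ by default; the objective is exactly ridge
regression, so no iterative optimization is used. Features are
standardized with the population (1/n) standard deviation.
Class-pairing truncates each class to the minimum of the two per-class
counts in temporal order — deterministic and assumption-free. The
target's standardization statistics come from the single adaptation
repetition only and are reused for the test repetitions: recomputing
them on test data would leak test-set information. The expert's own
training data enter the pooled classifier unprojected (they already
live in the expert space), and because no a-priori expert choice
exists, the evaluation loops over all experts and reports the mean.

## The networks

Each convolutional block applies 64 kernels of size 1 × 21 per channel
("same" temporal padding), batch normalization, a leaky rectifier
(slope 0.1) and dropout (p = 0.35). Kernels see a single channel, so
channels mix only at the final linear layer; global average pooling
over the temporal axis produces the 64 × 10 (features × channels)
linear-layer input. Same-padding plus temporal mean pooling is the
minimal scheme consistent with that input shape.

Batch normalization carries **no** learned affine parameters: the
adaptive parameter count is exactly 128 per block (running mean and
variance for 64 maps), which is what per-subject adaptation updates.
The running-statistics blend is
`running <- (1 - m) * running + m * batch` with m = 0.99 — the
momentum weighs the *new* batch, the convention of the deep-learning
framework the method was designed in. This is what makes
single-repetition adaptation possible: one train-mode sweep over the
adaptation windows moves the running statistics almost entirely to the
new subject, while all weights stay frozen. (Under the opposite
convention a sweep would move them by 1% and adaptation would be a
no-op; we verified this numerically during development.) Dropout is
inactive during adaptation sweeps so that only clean statistics are
collected. A new subject's statistics are initialized to the average of
the training subjects' — the best prior under no data.

Training uses Adam (β₁ = 0.9, β₂ = 0.999), initial learning rate
0.04047, batch size 256, cross-entropy loss; if the monitored loss
(validation when available, else training) achieves no new minimum for
15 epochs the learning rate is divided by 5, and training is complete
below 1e-8. In ADANN each epoch has one "selected" subject, drawn from
a seeded shuffled rotation so that every subject is selected equally
often over training (the equal representation the balanced-batch scheme
is meant to ensure, which an independent draw per epoch would violate
in short runs); every
batch is half selected-subject windows (domain label 1), half others
(label 0); each window is normalized with its own subject's statistics
(the batch is grouped by subject); the domain head trains normally
while its gradient reaches the trunk multiplied by −λ. The domain head
sees the same pooled features as the gesture head.

## The synthetic testbed

The request-only human datasets are emulated by a generative model
whose default scale mirrors the acquisition protocol: 15 subjects, 7
gestures, 16 repetitions, 10 channels at 1,000 Hz, 5 s per repetition
with a 20% linear contraction ramp. Sources are band-limited
(20–450 Hz) Gaussian noise processes — matching the second-order
statistics that both the handcrafted features and the convolutional
models consume — amplitude-modulated by gesture-specific activation
patterns shared across subjects (gesture 0 is a rest-like low-drive
class; every other gesture strongly drives 3 of 8 sources), and mixed
into channels by a per-subject electrode-footprint matrix (channels and
sources on a ring).

Inter-subject variability enters through four knobs, chosen to emulate
a challenging cross-user population (the regime in which cross-user
adaptation is actually needed — naive cross-subject models well below
within-subject accuracy but above chance):

* electrode-ring rotation (placement variability), sd 0.8 source
  spacings, plus dense mixing perturbation;
* per-subject gain (skin impedance), log-sd 0.35;
* band-pass corner jitter (tissue filtering), ±15%;
* activation-pattern jitter (individual recruitment), log-sd 0.25.

Repetition-to-repetition variability is a multiplicative log-normal
jitter (sd 0.10), and a small additive sensor-noise floor (0.01) keeps
rest-class windows nonzero. One master seed determines everything; each
(subject, gesture, repetition) uses a documented derived sub-seed
(a minstd-style modular hash), so any single recording is reproducible
in isolation.

What the simulator does *not* model: motor-unit action potentials,
electrode-shift time courses within a session, inter-session drift, or
rest periods between gestures (the container stores labeled gesture
recordings only; whether rest data existed between trials is not
stated for the original protocol). Its inter-subject shift is *linear
in channel space* plus spectral/activation changes. Two consequences
for interpreting results: a linear shift is exactly the model CCA
assumes, so CCA is near-oracle here and the full-scale finding that
ADANN outperforms CCA on real data should not be expected to reproduce
at desk scale; and passing tests demonstrate that the machinery works
and preserves the qualitative orderings, not that real-data accuracies
are reproduced.

## Evaluation frameworks

Repetition-to-split assignment is by index order (the protocol
"bisected" the data without stating randomization; deterministic splits
make results reproducible):

* within-subject: repetitions 0–7 train, 8–15 test; for the CNN the
  last 2 training repetitions serve as validation;
* single-repetition: repetition 0 trains, 8–15 test (the same test half
  as within-subject, for comparability; handcrafted pipelines only —
  no repetitions remain to validate a deep model);
* cross-subject (leave-one-subject-out): trainers use repetitions 0–7
  for training and 8–15 for validation; the target's repetitions 0–7
  are untouched, 8 is the adaptation set, 9–15 the test set.

Accuracy is per window; no majority-vote smoothing. Results are
per-subject accuracies plus confusion matrices, exported in a long
format directly consumable by external repeated-measures ANOVA tooling
(no statistical tests are computed in-package).

## The desk-scale benchmark

`runSyntheticBenchmark()` reproduces the qualitative orderings on
three independent replicates of a 7-subject dataset (6 trainers + 1
target): adapted ADANN vs naive pooled CNN on the identical folds and
seeds, and within-subject vs single-repetition TD/LDA across all
subjects. Problem sizes are the package's choice for a desk-scale run:
1 s repetitions windowed at 151/100 ms, a 2-block × 8-kernel network,
and 9 training epochs — the largest epoch count whose six model
trainings fit the benchmark's intended quarter-hour footprint on one
CPU, fixed by that arithmetic before any results were compared. The
learning-rate heuristic is active but its 15-epoch plateau patience
cannot engage in so short a run; the schedule itself is exercised
separately by simulation. The full-scale architecture (6 × 64, full
schedule) is the same code path with the default configurations.

Two caveats from this reduced scale, observed during development and
worth stating plainly: domain-adversarial training converges more
slowly than plain supervised training (its gradients carry the
adversarial coupling and the per-subject sub-batch normalization adds
composition noise), so few-epoch runs understate ADANN relative to the
CNN; and run-to-run variability across dataset seeds is large relative
to the ADANN-vs-CNN gap, so single-seed comparisons are
uninformative — hence the three-replicate design. The unadapted ADANN
accuracy is reported alongside the adapted one so the contribution of
the batch-normalization adaptation itself is visible.

```{r, eval = FALSE}
bench <- runSyntheticBenchmark(seed = 1, verbose = TRUE)
bench$meanAdann > bench$meanCnn       # adaptation benefit
bench$meanCnn > 1 / 7                 # above chance
bench$meanLdaWithin > bench$meanLdaSingleRep
```

## Numerical choices and degenerate inputs

* Covariance factorization failure → explicit ridge with a message.
* Zero-variance feature columns standardize to 0 with unit divisor.
* BN variance is ε-guarded (1e-5); constant batches normalize to 0.
* Constant windows: AR coefficients are defined as 0; log-features
  floor at −20.
* Ties in argmax (LDA discriminants, class scores) break to the lowest
  class id.
* The projection system falls back to an error naming λ if singular;
  n < d pairing errors suggest more adaptation data.
* All stochastic steps (weight init, shuffling, dropout, subject
  selection, simulation) derive from explicit seeds; identical seeds
  give bit-identical models and datasets.

## Known limitations

* The deep models run on CPU in double precision; the benchmark uses a
  reduced network and few epochs, so its absolute accuracies are far
  below the full-scale results on real data and should only be read
  comparatively.
* AdaBN corrects only what is visible in per-map statistics (pooled
  over channels, time and windows). A purely channel-space shift with
  equal overall power is invisible to it; the benefit on the synthetic
  testbed comes from the gain, spectral and activation components of
  the shift.
* The single 60 Hz notch does not remove powerline harmonics; no
  artifact rejection is performed.
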
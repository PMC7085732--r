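---
title: "Peak-centered windows and a 1-D CNN for wearable fall detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-centered windows and a 1-D CNN for wearable fall detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A wearable fall-detection system (FDS) watches a triaxial accelerometer —
typically worn on the waist — and must discriminate falls from activities of
daily living (ADLs). `fallcnn` implements a detector that feeds *raw*
acceleration samples to a one-dimensional convolutional neural network,
with no hand-crafted features, no filtering and no resampling.

The only preprocessing is a reduction of each recorded movement to a
fixed-duration **observation window**. For a trace of $N$ samples the
signal magnitude vector is

$$\mathrm{SMV}_i = \sqrt{A_{x,i}^2 + A_{y,i}^2 + A_{z,i}^2} \quad
  (\text{m/s}^2),$$

and the window is centered on $t_o = \arg\max_i \mathrm{SMV}_i$: falls
produce a free-fall dip (magnitude near zero) followed by an impact spike
and an orientation change, so whatever happened, it happened around the
global magnitude peak. With half-width $T_W/2$ seconds and sampling rate
$f_s$, the per-axis window holds

$$n = 2\,\lfloor (T_W/2)\, f_s \rfloor + 1$$

samples (symmetric and peak-inclusive; at 200 Hz and $T_W/2 = 2.5$ s this
is the familiar 1001). Two input variants exist:

* **SMV** — the magnitude series over the window ($n$ features);
* **TRIAXIAL** — the three raw axis series concatenated as contiguous
  blocks $[x \,|\, y \,|\, z]$ ($3n$ features).

The classifier is a fixed four-block 1-D CNN:

| block | layer stack | filters | width after block (input $w$) |
|------|--------------|---------|-------------------------------|
| 1–3  | conv(1×5, pad 2, stride 1) → batch-norm → ReLU → max-pool(1×5, stride 5) | 16 / 32 / 64 | $\lfloor w/5 \rfloor$, $\lfloor w/25 \rfloor$, $\lfloor w/125 \rfloor$ |
| 4    | conv(1×5, pad 2, stride 1) → batch-norm → ReLU | 128 | unchanged |
| head | dropout → fully-connected(→ 2) → softmax | — | 2 probabilities |

Convolutions preserve width (kernel $= 2\cdot\mathrm{pad} + 1$, stride 1);
each pool is *down-sampling* (stride equal to its width — an overlapping
stride-1 pool would not down-sample). Three floor-mode width-5 pools imply
a **minimum input width of $5^3 = 125$ features**; `build_network()`
refuses narrower inputs and the benchmark marks such cells as skipped.

Training uses stochastic gradient descent with momentum on the
cross-entropy loss: learning rate $10^{-4}$, minibatches of 64 windows, at
most 20 epochs, validation once per epoch, and early stopping when the
validation loss fails to reach a new minimum for 3 consecutive evaluations
("validation patience"). The returned weights are those of the epoch with
minimum validation loss. Overfitting countermeasures are the held-out
validation set, L2 regularization and dropout.

## Parameters the recipe names but does not fix

Several training quantities are stated only as techniques; the package
fixes them as explicit, documented defaults in `train_config()`:

* **momentum 0.9**, **L2 coefficient $10^{-4}$**, **dropout 0.5** — the
  conventional defaults of the deep-learning toolbox family this
  architecture originates from. All three are user-settable.
* **pool stride = pool width (5)** — the only reading under which the
  pooling layer down-samples.
* **one dropout layer**, placed immediately before the fully-connected
  head, active only in training (inverted scaling).
* **weight initialization** — He scaling for the convolution layers (they
  feed ReLUs), seeded. The softmax head is **zero-initialized**: the
  untrained network is then exactly class-indifferent, so the first
  gradient steps move along the class-separating direction rather than
  first unlearning a random initial bias. With small training sets (one
  minibatch per epoch, hence only `max_epochs` gradient steps) this
  materially stabilizes the outcome.
* **batch-norm statistics** — during training, running estimates start as
  a copy of the first batch and continue as an EMA (momentum 0.1); after
  training the statistics are *finalized* by a pass over the full training
  set at the selected weights, mirroring the batch-norm finalization of
  the reference toolbox. Inference always uses the finalized statistics.
* **partial minibatches are kept.** The reference toolbox discards them,
  but with fewer training windows than the 64-window minibatch that would
  mean zero gradient steps; at realistic dataset sizes the difference is
  negligible.
* **ties** — the SMV peak takes the earliest index on exact ties; an exact
  0.5/0.5 softmax tie classifies as FALL (in a detector the costlier error
  is the missed fall). Indices are 1-based throughout, the R convention.
* **boundary windows replicate the edge sample** rather than zero-fill:
  zero acceleration *is* the free-fall signature, so zero-padding would
  inject a synthetic fall cue into ADL windows.

## Evaluation protocol

Datasets are split 60/20/20 into train/validation/test with class
proportions preserved: within each class the subset sizes are assigned by
largest-remainder allocation (ties favour train, then validation), which
keeps every subset within one trace of its exact proportional share; the
assignment itself is a seeded random shuffle. Quality metrics, with FALL
as the positive class:

$$Se = 100\,\frac{TP}{FN+TP}, \qquad
  Sp = 100\,\frac{TN}{FP+TN}, \qquad
  Acc = 100\,\frac{TP+TN}{TP+TN+FP+FN}.$$

`run_benchmark()` reproduces the per-dataset protocol: for every
(dataset × half-width ∈ {0.5, 1, 1.5, 2.5} s × variant) cell it extracts
windows at the dataset's *own* sampling rate (input width therefore varies
per dataset — measurements are never resampled), builds a fresh network at
that width, trains it on the stratified split and evaluates on the test
subset. Each cell derives an independent seed from
(master seed, dataset id, half-width, variant), so any cell is
reproducible in isolation, and each cell is a single training run by
default (a `repeats` argument can average). A cell is **SKIPPED** when the
window is longer than some trace (`window_too_long` — short-sample
repositories genuinely cannot support wide windows) or narrower than the
network minimum of 125 features (`input_too_narrow`, e.g. an SMV window of
±0.5 s below 125 Hz); other failures are recorded per cell without
aborting the grid. Training and testing always come from the same dataset;
cross-dataset transfer is out of scope.

## What the synthetic generator emulates — and what it does not

`generate_fall_trace()` concatenates the canonical fall phases: a walking
prefix around 1 g, a free-fall dip (default 0.4 s at 0.2 g), a half-sine
impact burst rescaled so the trace's global SMV maximum lies inside it
(magnitude drawn around `impact_peak_g`, default 4 g, SD 10%, truncated at
±30%), and post-impact rest at 1 g under a rotated orientation (the
gravity direction is swung by 60–120°). `generate_adl_trace()` produces
gait (fundamental plus first harmonic plus perpendicular sway around 1 g)
or a smooth postural-transition bump; its magnitude never approaches
either the free-fall floor or impact levels. Independent Gaussian noise
(default 0.05 g per axis) is added everywhere.

Defaults describe a SisFall-like recording: 200 Hz, 12 s traces, 60 ADLs
and 40 falls. They make the two classes *strongly separable* by
construction — that is deliberate, so that end-to-end tests have a known
answer. `hard = TRUE` narrows the margin (impact 1.8 g, noise 0.15 g) to
exercise the imperfect-classifier paths. Passing tests on these traces
demonstrates that the pipeline is wired correctly and can recover planted
structure; it says nothing about performance on real falls, where impact
magnitudes, pre-impact dynamics and sensor artifacts are far more diverse
(that question is exactly what the multi-repository benchmark protocol is
for). The generator makes no claim of biomechanical fidelity.

Per-trace seeds are derived from the master seed by a string hash, so
regenerating a dataset is byte-identical and every trace is individually
reproducible.

## Numerical choices and degenerate inputs

* All computation is double precision through BLAS matrix products
  (im2col convolutions); no compiled code.
* Validation-loss "improvement" means strictly smaller than the running
  minimum; patience counts consecutive non-improvements.
* `compute_metrics()` refuses confusion tables with an empty class and
  names the zero denominator; `split_dataset()` requires at least five
  traces per class; `train_network()` rejects single-class training sets.
* Canonical trace files are written with 12 significant digits, so a
  write/read round trip is exact to ~1e-10 relative error.
* Problem sizes in the test-suite and acceptance script (100-trace
  datasets, 30-trace hard grids, 6-trace protocol fixtures) are the
  package's chosen demonstration scales: large enough for the planted
  structure to be recovered and the protocol rules to bind, small enough
  to re-run routinely.

## Known limitations

* With one minibatch per epoch the recipe allows at most 20 gradient
  steps; real repositories (thousands of traces) provide dozens of steps
  per epoch, which is the regime these hyper-parameter defaults were tuned
  for. The package keeps the recipe literal rather than compensating.
* The TRIAXIAL layout concatenates per-axis blocks; an interleaved layout
  is equally consistent with a flat "1 × width image" input and was not
  explored.
* Sampling jitter is ignored: the manifest's nominal rate dimensions the
  network input regardless of per-file timestamps.
* Unit conversion is a single multiplicative factor per dataset; affine
  (offset) calibrations are out of scope.
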
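---
title: "Classifying motor-imagery EEG with a network kernel map and a large-margin-distribution SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying motor-imagery EEG with a network kernel map and a large-margin-distribution SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcidnn)
```

## The decoding problem and its assumptions

A cue-paced motor-imagery trial lasts 9 s: 2 s of rest, a fixation cross
at second 3, a directional cue at second 4, then sustained imagery of a
left- or right-hand movement until second 9, recorded at 128 Hz over the
sensorimotor channels C3, Cz, C4. The physiological signature this
package assumes is event-related desynchronization (ERD): during
imagery, the mu rhythm (8–12 Hz, with a beta companion at 18–26 Hz)
loses amplitude over the hemisphere *contralateral* to the imagined
hand. The decoding model is therefore built on three assumptions: the
class signal lives in band power rather than phase; it is lateralized
(C3 vs C4); and it is stationary within the analysis window. Nothing in
the pipeline exploits cross-trial temporal structure.

Labels are coded left = +1, right = −1 throughout. The SVM formulation
needs ±1 labels and data sources differ in their conventions (the
competition `.mat` layout codes 1 = left, 2 = right, which the loader
remaps), so the package fixes one convention and documents it.

## The classifier

### The large-margin-distribution head

The head is a linear SVM with squared-hinge slacks whose objective also
rewards the *mean* functional margin
$\bar\gamma = \tfrac1N\sum_i y_i(\varphi(x_i)^\top w + b)$:

$$\min_{w,b}\ \tfrac12\lVert w\rVert^2 + C\sum_i \xi_i^2 - \lambda\bar\gamma,
\qquad y_i(\varphi(x_i)^\top w + b) \ge 1 - \xi_i,\ \ \xi_i \ge 0 .$$

Classic SVMs optimize only the minimum margin; pushing a first-order
statistic of the whole margin distribution instead is what helps on
heavily overlapping ("high-aliasing") classes such as patient EEG. Only
the margin *mean* enters the objective; a margin-variance term is a
conceivable extension but is deliberately not part of the fitted
objective.

Two structural facts make the implementation clean:

* With a quadratic slack penalty, the optimal slack for any $(w,b)$ is
  $\xi_i = \max(0,\, 1 - y_i f(x_i))$, which is automatically
  non-negative. Substituting it turns the constrained program into a
  smooth unconstrained convex one, minimized in `lmsvm()` by BFGS with
  the analytic gradient (`optim`, relative tolerance $10^{-14}$, one
  polish restart, convergence asserted via the gradient norm).
* On any fixed guess of which samples have positive slack, the objective
  is purely quadratic, so its minimizer solves one linear system.
  `lmsvm_qp()` iterates that active-set solve until the set is
  self-consistent — an exact reference solver used throughout the tests
  to cross-check the BFGS route, and the two agree to ~$10^{-13}$ in
  objective value on random instances.

A useful analytic anchor is the two-point problem $x = \pm1$,
$y = \pm1$: symmetry pins $b = 0$ and stationarity of
$\tfrac12 w^2 + 2C(1-w)^2 - \lambda w$ gives
$w = (4C+\lambda)/(1+4C)$ while the hinge is active ($\lambda < 1$),
and $w = \lambda$ beyond. Both solvers are tested against both branches.

The bias is not regularized (standard SVM convention). Decision scores
of exactly zero map to +1, a documented tie-break so predictions are a
total function.

### The network as an explicit kernel map

Rather than pick a kernel, a small fully connected network
$a^h = \sigma(W^h a^{h-1} + b^h)$ is used as an explicit map $\varphi$.
The backpropagation recurrences are the textbook ones for the MSE loss
$J = \tfrac12\lVert a^H - y\rVert^2$: the output error is
$\delta^H = (a^H - y)\odot\sigma'(z^H)$, it propagates as
$\delta^h = (W^{h+1})^\top\delta^{h+1}\odot\sigma'(z^h)$, and the layer
gradients are $\partial J/\partial W^h = \delta^h (a^{h-1})^\top$,
$\partial J/\partial b^h = \delta^h$. (Some presentations drop the
derivative prime from the output-layer formula; calculus requires it,
and the finite-difference tests would catch its absence.) Batch
gradients are means over per-sample gradients, and every gradient is
verified against central finite differences to relative error below
$10^{-6}$ on randomized shapes and activations.

Training is staged:

* **Stage A** — the hidden stack plus a temporary two-unit output head
  is trained by full-batch gradient descent on one-hot MSE targets.
  One-hot targets with MSE were chosen because the head is temporary
  and only shapes the hidden representation; relu and identity
  activations are available alongside the default sigmoid.
* **Stage B** — the head is discarded, training inputs are mapped
  through the hidden stack, and the LM-SVM is fitted on the mapped
  features.
* **Stage C** (optional, `joint_finetune = TRUE`) — subgradient steps on
  the combined SVM primal are chained through the map. How the two
  pieces are co-trained is genuinely open; the staged path is the
  default because it is reproducible, fast and easy to reason about,
  and both paths share the prediction code.

Weights initialize uniformly on $(-1,1)/\sqrt{\text{fan-in}}$ from a
seed; biases start at zero. Every fit is a pure function of its
configuration and seed — run-to-run determinism is asserted at byte
level in the tests. A non-finite training loss aborts with the
iteration number rather than silently producing NaN parameters.

With `hidden = integer(0)` the map is the identity and the model reduces
exactly to the linear L2-slack SVM, which is how the composite model is
anchored to the `lmsvm_qp()` reference in the tests.

## Preprocessing and features

The trial paradigm fixes the defaults: band-pass 0.5–30 Hz (order-5
Butterworth applied forward–backward, so zero phase and no group
delay — latency matters when a window is cut afterwards), epoch to the
4–9 s imagery window (640 samples at 128 Hz), then one feature per
channel × band: the natural log of the within-window variance after
band-passing to mu (8–12 Hz) and beta (18–26 Hz). Log band-power is the
standard discriminative statistic for ERD; the log makes the
multiplicative amplitude suppression additive and symmetrizes the
variance ratio. A `flatten` mode (optionally decimated raw samples) is
provided for experiments that want to hand the network the waveform.
The original experimental description leaves the feature representation
open, so neither mode is claimed to be canonical — `bandpower` is simply
the field's default.

Feature normalization is z-scoring with *training-half* statistics only;
the held-out half never touches the scaler, keeping the random split
leakage-free. Zero-variance features get scale 1 (centred only) rather
than a division by zero.

## Model selection

Evaluation uses the exact accuracy ratio (TP+TN)/(TP+TN+FP+FN) computed
from integer counts, and a stratified random 50/50 split whose training
half is exactly class-balanced (odd samples go to the test half).
`grid_search()` crosses architectures × learning rates × λ, trains one
model per cell on the training half at fixed iterations, and scores the
test half; accuracies are test-half values. Ties break toward fewer
layers, then fewer total units, then lower learning rate, then lower λ —
i.e. toward the cheaper model. `layer_width_search()` implements the
greedy protocol of growing one layer at a time, sweeping the newest
layer's width (default 5–12) while earlier layers keep their selected
widths; this interpretation (rather than exhaustively re-sweeping all
layers at every depth) matches how such depth-by-depth tables are
usually produced and keeps the search linear in depth. Single-split
selection mirrors the underlying experimental protocol; k-fold wrappers
can be built from `split_half()` if wanted.

Default operating point: hidden layers (11, 6), learning rate 0.07,
2500 iterations, λ = 0.1, C = 1. The first four are the selected values
of the underlying study's sweeps (learning-rate grid 0.05–0.14 in steps
of 0.01; λ grid 0.01–100). C is never specified there, so the package
uses the conventional C = 1 and exposes it.

## What the synthetic generator does and does not emulate

`generate_mi_trials()` writes each trial as white Gaussian noise
(`noise_sd`, default 4 µV) on all channels plus a constant-amplitude mu
oscillation (default 10 Hz, 10 µV) with a per-trial random phase on C3
and C4. During the imagery window the mu amplitude on the channel
contralateral to the imagined hand (left hand → C4, right hand → C3) is
multiplied by `1 - erd_depth`. Defaults — 140 trials per class, 3
channels, 128 Hz, 9-s trials, imagery 4–9 s — mirror the cue-paced
paradigm; `erd_depth = 0.5` is a moderate, realistic suppression, and
the amplitude/noise levels put single-trial band-power contrasts in the
range where the classifier is challenged but not defeated.

The generator creates exactly the statistical structure the method
assumes — a lateralized band-limited amplitude contrast — and nothing
else. It has no 1/f background (available as an option but off, to keep
the analytic band-power checks exact), no volume conduction, no
artifacts, no nonstationarity, no subject variability. Passing the
synthetic pipeline therefore demonstrates that the implementation
recovers the signal class it is designed for; it does not certify
performance on real recordings, where spatial filtering and artifact
handling (deliberately out of scope here) usually matter. The
`erd_depth = 0` control, whose held-out accuracy must stay inside the
99% binomial band around 0.5, guards against information leaking through
the pipeline plumbing rather than the signal.

## Numerical and I/O choices

* Portable trial storage is a documented flat little-endian binary
  container (magic, dims, fs, t0, labels, channel names, IEEE-754
  doubles), written with base R connections: lossless, byte-
  deterministic (write–read–write is asserted byte-identical), and
  trivially parseable from any language.
* The competition `.mat` loader implements the minimal MATLAB v5 subset
  needed (numeric arrays, compressed elements); it is validated against
  `scipy.io` in both directions in the tests. Best-effort variable
  discovery (named `x_train`/`y_train` or the unique 3-d array plus
  matching label vector) is used because the container layout is
  conventional rather than specified.
* Fitted models serialize with `saveRDS`, the native R idiom for model
  objects; round-trips are asserted to predict identically.
* Metric JSON files contain no timestamps (those go to the run log), so
  identical configurations produce byte-identical reports.

Test and acceptance problem sizes — networks up to a few dozen units,
SVM instances with N ≤ 50, d ≤ 5 for solver cross-checks, synthetic
sessions of 100 trials per class for the pipeline checks — were chosen
so the whole suite exercises every code path at full fidelity (2500
iterations, the default architecture) while remaining a desk-scale
computation.

## Known limitations

* Binary classification only; one-vs-rest plumbing would be needed for
  multi-class imagery.
* No spatial filtering (CSP, Laplacian), artifact rejection or ICA —
  real-data performance will typically be limited by their absence.
* The exact label-flip symmetry of the SVM head extends to the full
  model only with an identity map: with a trained map, flipping labels
  swaps the one-hot targets but not the shared random initialization,
  so symmetry holds only approximately. The tests assert the exact
  version where it exactly holds.
* The greedy width search is an interpretation of an ambiguous
  tabulated protocol, not the only possible reading.
* Offline, trial-based operation only; no online/asynchronous decoding.
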
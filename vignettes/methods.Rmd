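---
title: "Models and methods behind respsound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind respsound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`respsound` classifies lung sounds at the level of the respiratory
cycle: one inhalation-plus-exhalation segment, labelled by the presence
of crackles (brief damped transients) and/or wheezes (sustained musical
tones). This vignette describes the models, the tunable parameters, the
synthetic data the package tests itself on, and the design decisions
taken where the methods were genuinely open. It states no empirical
result that the test suite does not itself compute.

## Class schemes and data model

An annotated recording is a mono waveform plus a whitespace-delimited
text file of rows `start_s end_s crackle(0/1) wheeze(0/1)`. Cycles are
cut on half-open intervals `[start, end)` and labelled under one of
three schemes: two-class (normal vs abnormal), three-class
(normal/crackle/wheeze, both-present cycles excluded), or four-class
(plus "both"). Recordings can be resampled (default target 4000 Hz, the
lowest rate common in clinical lung-sound collections) and cycles
padded/truncated to a fixed analysis length so feature vectors are
commensurate.

## The synthetic generator: what it emulates, and what it does not

`synthesize_cycle()` builds each class from three acoustic archetypes:

* **normal** — Gaussian noise band-limited to 100–1000 Hz (the
  vesicular-sound band), unit power;
* **wheeze** — adds a sinusoid at a seeded frequency in 100–1000 Hz,
  amplitude-modulated at 1–4 Hz (breath-borne modulation), scaled so
  its average power sits `snr_db` above the background (default 10 dB);
* **crackle** — adds Poisson-placed damped oscillatory transients of
  5–10 ms (default 8 events/s), the burst train scaled to the same SNR;
* **both** — wheeze and crackle components together.

Defaults: 1 s cycles at 4000 Hz (Nyquist comfortably above the upper
wheeze frequency), 10 dB SNR. Seeding is counter-split from one master
seed, so datasets are bit-reproducible regardless of generation order.

This generator reproduces the *spectral and temporal signatures* that
the published methods exploit — tonal peaks, heavy-tailed transient
statistics, broadband background — but none of the confounders of real
auscultation: heart sounds, device transfer functions, subject
variability, label noise, or class imbalance. A green end-to-end test
therefore establishes that the pipelines are wired correctly and can
separate well-posed classes; it does not establish clinical-grade
accuracy, which in the source literature is measured on a large
multi-site database.

## Decomposition

**Ensemble EMD with paired noise.** Standard cubic-spline sifting
(envelope mean subtraction, Cauchy stop criterion 0.2, at most 12 sifts
per mode) decomposes a signal into intrinsic mode functions ordered
high-to-low frequency; by construction modes plus residual reconstruct
the input to machine precision. The ensemble variant draws `q` white
noise realizations with standard deviation `noise_std_fraction` times
the signal's (default 0.4, the published operating point; the usual
range is 0.02–0.4), decomposes `signal + N_i` and `signal - N_i` for
each, and averages matching modes over all `2q` members. Because every
noise realization enters with both signs, the injected noise cancels
exactly in the mean of the inputs. Members can yield different mode
counts; we truncate to the minimum count and fold the surplus into the
residual, preserving exact reconstruction of the clean signal.

**VMD.** K band-limited modes are extracted concurrently by ADMM on the
augmented Lagrangian of the bandwidth-minimization problem: a spectral
Wiener-filter update per mode, a center-of-gravity update of each
center frequency, and dual ascent on the reconstruction multiplier.
Defaults follow the published settings: bandwidth penalty
`alpha = 300`, dual step `tau = 0.5`, tolerance `1e-3`. The tolerance
is applied to the canonical criterion — the total time-domain squared
change of the modes between iterations — because a per-mode *relative*
criterion stops during the slow multiplier phase and leaves ~10%
reconstruction error on a unit tone. Center frequencies are computed in
cycles/sample and reported in Hz; the input is mirror-extended by half
its length at each end. Initialization spreads the K starting
frequencies uniformly over (0, Nyquist).

**Distance-metric mode-number selection.** For trial K = 2, 3, ... the
signal is decomposed, reconstructed as the sum of modes, and compared to
the original with one of five bounded similarities: `1 - d` for the
per-sample-normalized Euclidean (RMS), Manhattan (mean absolute) and
Chebyshev (max absolute) distances, and the fuzzy-set Jaccard
(`sum min / sum max`) and Dice (`2 sum min / (sum x + sum y)`) overlap
forms. The metric distances are computed after *jointly* min-max
normalizing the pair — a shared affine map, so identical inputs remain
identical, differences are bounded by 1, and already-scaled inputs are
untouched (per-sequence normalization would declare any two constant
sequences identical). The smallest K whose similarity reaches the
threshold (default 0.99) is selected.

One subtlety is load-bearing: with `tau > 0` the multiplier enforces
near-exact reconstruction at *every* trial K, so the similarity trace
saturates immediately and the selection is vacuous. The K scan
therefore runs with the multiplier disabled (`scan_tau = 0`, the usual
practice for noisy signals, where exact reconstruction is undesirable
anyway); the decomposition returned at the selected K is recomputed
with the configured `tau`. Relatedly, under-decomposition is only
detectable when components are spaced more widely than the Wiener
filter's bandwidth, roughly `1/sqrt(2 * alpha)` in normalized
frequency (about 0.03 cycles/sample at `alpha = 300`); the package's
k-tone test signals are drawn with that spacing, which is the stated
world of the selection benchmark, not a tuned quantity.

## Granger (MVAR) features

A lag-`l` multivariate autoregression over `p` channels is fit by least
squares on the lagged design matrix (descending-lag blocks per
channel); when the normal equations are singular (reciprocal condition
number below 1e-10) the Moore-Penrose pseudo-inverse branch is used.
For a single-channel sound the *channels are the decomposition modes* —
the source method never specifies the multichannel construction, and
using the ensemble-EMD modes is what makes combining the
autoregressive and per-mode feature blocks coherent. The feature vector
concatenates all `p^2 l` coefficients and the `p` residual variances;
the per-mode block adds six descriptors per mode (energy, variance,
skewness, kurtosis, zero-crossing rate, spectral centroid). Default
order 4 at library level; the pipelines use order 2 with 4 modes at
desk scale.

## Feature selection

SVM-RFE trains a linear SVM, scores each surviving feature by its
squared weight, removes the lowest-scoring features, and repeats;
ranking is the reverse elimination order. Features are z-scored
internally, making the ranking scale-invariant; constant features are
eliminated first by convention and criterion ties break toward the
lower index. Multiclass problems use one-vs-rest with summed squared
weights. The printed cost-function formula in the source is not usable
as written; the squared-weight criterion is exactly its own Step-5
description. Because no SVM library ships in this environment, the
linear SVM is a small in-package squared-hinge classifier solved by
BFGS — deterministic, which the tests rely on.

## Metaheuristics

All five optimizers minimize a box-constrained objective, clip
candidates after every update, and are bit-reproducible under a seed.

* **Harris hawks** (default 50 hawks, 500 iterations): linear
  escape-energy decay `E = 2 E0 (1 - t/T)`; exploration while
  `|E| >= 1`; four exploitation branches (soft/hard besiege, each with
  a greedy rapid-dive variant using Mantegna Levy flights, stability
  index 1.5).
* **Adaptive DE** (default NP = 100, 1000 generations, CR = 0.7): each
  individual's mutation scale is `S = 1/(1 + tanh(2 CP))` where CP is
  its fitness position between the population's worst (0) and best (1);
  S is guaranteed in (0.5, 1], large for stragglers (exploration) and
  small near the best (exploitation). Mutant `X_q + S_q (X_q1 - X_q2)`,
  binomial crossover with a forced coordinate, greedy selection (the
  published selection rule is written for maximization and is oriented
  by sense here). A converged population (all fitness equal) gets
  CP = 1. The "single-generation error < 1e-8" stop is applied over a
  trailing 50-generation window: under greedy selection the population
  best improves in jumps, and a literal per-generation test fires
  spuriously mid-run.
* **Binary mode** thresholds candidates through the sigmoid rule
  (bit = 1 when `rand < sigm(x)`) for feature-mask search.
* **Nested tuner**: an outer hawks swarm searches the DE controls — CR
  in [0.1, 0.95] and a scale-modulation multiplier in [0.5, 1.5] (the
  source says only "controlling parameters"; this pair is our choice) —
  with each hawk scored by the best value of an inner DE run (published
  inner settings NP = 75, 500 iterations).
* **Grey wolf** (50 agents) and **grasshopper** (60 agents, 400
  iterations): standard formulations; the grasshopper social function
  is used but never defined in the source, so the canonical
  `s(r) = f e^{-r/l} - e^{-r}` with f = 0.5, l = 1.5 is adopted, with
  `s(0) = 0` for coincident agents and pairwise distances mapped into
  [1, 4] as is conventional.
* Constraints are handled by penalty: an infeasible candidate's
  effective fitness must exceed every feasible one's.

## Classifiers

**ELM**: random uniform [-1, 1] input weights and biases (seeded),
sigmoid hidden layer (default 30 neurons), one-hot targets, output
weights by pseudo-inverse. Prediction is arg-max with ties toward the
lower class index.

**K-SVD / SRC**: orthogonal matching pursuit codes each sample with at
most `l0` atoms; each atom and its active coefficients are then updated
by a rank-1 SVD of the restricted residual; unused atoms are reseeded
from the worst-represented sample. The Frobenius objective is recorded
per sweep and kept monotone by retaining a column's previous code
whenever a fresh OMP pass would worsen it. Class-tagged dictionaries
train one sub-dictionary per class. Classification ridge-codes the
query over the full dictionary and picks the class minimizing
`||z - D phi_i||^2 / ||phi_i||^2`. That coefficient-norm-normalized
ratio is sensitive to near-collinear intra-class atom blocks, which at
small ridge levels acquire large opposing coefficients and artificially
deflate their class's ratio; the default `mu = 1` (the source leaves mu
unspecified) stabilizes this, and the ratio's invariance to positive
scaling of the query is preserved exactly.

**Realm revamping (domain adaptation)**: the label-rich source realm
gets a Gaussian-kernel KNN similarity graph (kernel width defaulting to
the median pairwise squared distance; edges below 0.6 pruned — the
published "threshold parameter 0.6" is applied here, the source not
saying what it thresholds); the few labelled target samples get a
same-class indicator graph. Each realm's projection is the
`d_sub`-smallest-eigenvalue eigenbasis of `Z (L - alpha I) Z'`,
balancing local-structure preservation against an (uncentered) PCA
variance term under row orthonormality. Two additions proved necessary
and are deliberate design choices: (1) eigenbases are determined only
up to sign and order, so the target projection is rotated onto the
source coordinates by an orthogonal Procrustes fit on the labelled
class means — without it the shared dictionary mixes incompatible
coordinate systems and adaptation fails; (2) when the labelled target
samples cannot span `d_sub` dimensions the target eigenproblem is
rank-deficient and its trailing eigenvectors arbitrary, so the source
projection is reused (`Mt = Ms`). A shared class-tagged K-SVD
dictionary is then learned on the projected labelled samples of both
realms; queries are projected with the target projection (they are
target-realm by assumption) and classified by the residual ratio.

**Sparse autoencoder**: one sigmoid hidden layer (KL divergence needs
activations in (0, 1)), ReLU output (the source names ReLU as the
output activation; using it at the hidden layer would invalidate the KL
term — an inconsistency resolved in the output layer's favor), loss =
half mean squared reconstruction error plus `beta_sp` times the summed
`KL(rho || rho_hat)` over hidden units, minibatch gradient descent.
Published training settings are the defaults: learning rate 0.04, 200
epochs, batch 64; sparsity target 0.05 and penalty weight 0.1 are our
choices (unspecified in the source). The decoder bias starts at 0.5 so
ReLU outputs begin in their active region.

**Tuned Gaussian SVC**: the grey wolf searches `log10(c)` and
`log10(g)` in [-3, 3] (the published grid range) with inner 3-fold CV
error as fitness; the SVC core is an in-package least-squares SVM with
an RBF kernel (one-vs-rest, closed-form solve), again because no SVM
library is available in the environment.

**Metrics**: per-class one-vs-rest sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)` and accuracy `(TP+TN)/n`, as percentages, plus
macro averages and plain overall accuracy. Multiclass single-number
summaries are macro averages (the averaging is unstated in the source).

## Pipelines and cross-validation

Six strategies run under seeded stratified 10-fold CV. Per-cycle
feature extraction (decompositions, descriptors) is unsupervised and
sample-local, so it is computed once and cached; everything
label-dependent — z-scoring statistics, RFE, mode-number selection,
metaheuristic fitness, realm splits, classifier training — is fit
inside the training fold only. The mode number for the VMD-ELM
strategy is selected on a seeded handful of training cycles per fold
and frozen. Its error-compensation stage is implemented as three
successive regression-mode ELMs fitted to the running one-hot score
residual, their outputs summed into the final score before arg-max —
the only reading consistent with "E = E1 + E2 + E3" and
"Ppre = Q* + E" in the source. The realm split for the SRC strategy
takes 70% of each training fold as the source realm and 3 labelled
cycles per class from the remainder as the target realm (at full scale
the two collection sites of a clinical database would serve as natural
realms). CV is cycle-level; subject-level grouping is the documented
alternative when real recordings with subject identifiers are used.

Pipeline option defaults are desk-scale (ensemble q = 3, inner
optimizer budgets of tens of evaluations, SAE 60 epochs) so the full
six-strategy acceptance run finishes in minutes on one CPU; the
published full-scale settings remain the defaults of the underlying
building blocks and can be restored through `opts`.

## Numerical choices and degenerate inputs

Min-max normalization rejects constant signals (zero denominator); EMD
of a constant returns zero modes; VMD of a zero signal returns zero
modes with center frequencies at initialization; non-convergence is
reported in the result, never raised; coincident grasshoppers exert no
force; an all-equal DE population gets CP = 1; RFE ties break toward
the lower index; ELM arg-max ties toward the lower class index; the
Jaccard/Dice similarities reject negative or all-zero inputs (0/0).

## Known limitations

No heart-sound removal, device calibration or real-time streaming; ICA
preprocessing is omitted (mentioned once in the source with no
configuration, and no implementation is available here); the linear and
kernel SVM stand-ins are not libsvm and their decision values differ in
scale from it; the synthetic benchmark's caveats are described above.
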
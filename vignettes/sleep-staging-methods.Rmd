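---
title: "Multi-view spatial-temporal graph convolution for sleep staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view spatial-temporal graph convolution for sleep staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepgcn)
```

## The problem

Overnight polysomnography (PSG) is scored in 30-second epochs, each assigned
one of the five AASM stages: Wake, N1, N2, N3, REM. Two properties of the
data shape the model in this package:

* **Brain topology matters.** The EEG channels sit on a scalp; both their
  physical proximity and their statistical coupling (functional
  connectivity) carry information. Channels are therefore treated as nodes
  of a graph rather than rows of a grid image.
* **Subjects differ.** The marginal distribution of EEG features varies
  strongly across people. A classifier trained on some subjects and applied
  to a new one faces a domain shift; clinically useful stagers must
  generalize to unseen subjects without fine-tuning.

`sleepgcn` addresses both with a two-view spatial-temporal graph
convolutional network trained adversarially for subject invariance.

## From signal to model input

Each recording is an array of `N` channels by `Ts = 30 * fs` samples by `L`
epochs. `extract_de_features()` reduces each epoch to an `N x Fd` matrix of
**differential entropy** (DE) band features,
\[
\mathrm{DE}_{n,b} = \tfrac12 \log\bigl(2\pi e\, \sigma^2_{n,b}\bigr),
\]
where \(\sigma^2_{n,b}\) is the variance of channel \(n\) after zero-phase
Butterworth band-pass filtering in band \(b\). The default six bands are
delta (0.5-4 Hz), theta (4-8), alpha (8-13), sigma (13-16), beta (16-30)
and gamma (30-45), so `Fd = 6`. DE under a Gaussian assumption is a
standard EEG feature: it is a monotone function of log band power with a
clean closed form, which also makes it desk-checkable (unit-variance white
noise gives \(0.5\log 2\pi e \approx 1.419\)).

Stages are judged in context: `build_context_windows()` presents each epoch
together with its `d` predecessors and `d` successors (`Tn = 2d + 1`
epochs, default `d = 2`). The first and last `d` epochs of a recording are
dropped rather than padded -- fabricating context at recording boundaries
would feed the model epochs that never happened, and dropping keeps the
window count exactly `L - 2d`.

Features are standardized per (channel, band) cell to zero mean and unit
variance, with the statistics estimated **only on training subjects** and
the same affine map applied to held-out windows. Constant cells are left
unscaled with a warning rather than divided by zero.

## Two views of the brain graph

**Learned functional connectivity.** The adjacency between channels is a
one-layer network of the absolute feature difference,
\[
A^{FC}_{mn} = \frac{\exp\bigl(\mathrm{ReLU}(w^\top |x_m - x_n|)\bigr)}
                   {\sum_{n'} \exp\bigl(\mathrm{ReLU}(w^\top |x_m - x_{n'}|)\bigr)},
\]
row-normalized by softmax, with `w` learned jointly with the classifier.
The accompanying graph-learning loss
\(\sum_{mn} \lVert x_m - x_n\rVert_2^2 A^{FC}_{mn} + \lambda \lVert A^{FC}\rVert_F^2\)
(default \(\lambda = 0.001\)) acts as a regularizer of the total objective:
it favours adjacencies that connect similar channels and penalizes dense
graphs. It is evaluated on the center epoch of every context window and
averaged over the minibatch, weighted by `gamma` (default `1e-4`) in the
total loss.

**Physical distance.** The second view is fixed:
\(A^{DC}_{mn} = \exp(-\lVert c_m - c_n \rVert^2 / 2\sigma^2)\) on unit-sphere
electrode coordinates, thresholded at 0.1, zero diagonal. The kernel width
defaults to the mean pairwise electrode distance, giving a smooth,
bounded-in-(0,1] decay with no singularities at zero distance. Distance
weights are rotation invariant by construction.

**Spectral filtering.** Graph convolution uses the Chebyshev expansion of
the scaled Laplacian \(\tilde L = (2/\lambda_{max})(D - A) - I\), whose
spectrum lies in \([-1, 1]\): \(T_0 = I\), \(T_1 = \tilde L\),
\(T_k = 2\tilde L T_{k-1} - T_{k-2}\), aggregating 0..K-1-hop neighbours
(default `K = 3`). Three numerical choices deserve note:

* The learned \(A^{FC}\) is row-stochastic and therefore asymmetric; it is
  symmetrized as \((A + A^\top)/2\) before the Laplacian, since the
  spectral theory behind the Chebyshev filter assumes symmetry.
* \(\lambda_{max}\) is recomputed per window by dense eigendecomposition
  (`N` is at most a few tens of channels) and differentiated exactly
  through its top eigenvector (\(\partial\lambda_{max}/\partial L = vv^\top\));
  the degenerate all-zero graph falls back to \(\lambda_{max} = 2\),
  i.e. \(\tilde L = -I\), with a warning.
* The ReLU non-differentiability is handled with the usual subgradient
  \( \mathrm{ReLU}'(0) = 0\); conv biases initialize slightly away from zero
  so no pre-activation sits exactly on the kink at the start.

## Attention and the spatial-temporal block

Each view owns a spatial attention map
\(P' = \mathrm{rowsoftmax}\bigl(V_p\,\sigma((X Z_1) Z_2 (Z_3 X)^\top + b_p)\bigr)\)
over channels and a temporal map
\(Q' = \mathrm{rowsoftmax}\bigl(V_q\,\sigma((X^\top M_1) M_2 (M_3 X) + b_q)\bigr)\)
over the `Tn` context epochs. The block applies, in order: temporal mixing
\(\hat X = X \times_T Q'\); spatial attention computed on \(\hat X\);
Chebyshev convolution with each \(T_k(\tilde L)\) modulated elementwise by
\(P'\) (so attention re-weights neighbour contributions without changing
which neighbours are reachable); then a same-padded temporal convolution
(`k_t = 3`) with ReLU. The per-view outputs are concatenated along the
channel axis and flattened into the fused feature vector.

Attention parameters initialize uniformly in ±0.01 so the initial maps are
close to uniform and the sigmoids unsaturated. Both maps are exactly
row-stochastic by construction, which the test suite checks as an
invariant, and with `Vp = 0` the map is input-independent. Whether the two
views should share attention was genuinely open; here each view owns its
parameters (the spatial statistics of the two graphs differ, and sharing
saves little).

## Adversarial domain generalization

On top of the fused features sit two heads: the label head (affine +
softmax over 5 stages) and the domain head (one 64-unit ReLU hidden layer,
then affine + softmax over the `R_d` training subjects). A **gradient
reversal layer** (GRL) connects the features to the domain head: identity
forward, gradient scaled by \(-\beta\) backward. Both heads minimize
cross-entropy; the reversal alone realizes the saddle objective in which
the feature extractor maximizes domain confusion while minimizing staging
error. The total reported loss is
`loss_y + loss_d + gamma * loss_graph`; \(\beta\) never appears in the
scalar, only in the gradient path, which keeps the bookkeeping unambiguous.

Adversarial training of this kind is a saddle-point problem and needs
care; five stabilizers, all configurable, were found necessary:

* **Warm-up** (`beta_warmup`): \(\beta\) ramps from 0 with the sigmoid
  schedule \(2/(1+e^{-10p}) - 1\) of training progress \(p\), so the
  staging task establishes before adversarial pressure peaks. The ramp is
  not cosmetic: applying full pressure from the first epoch collapses the
  representation before class structure can form, while a slow linear
  ramp never escapes the supervised solution at all (the head simply
  tracks the drifting features and no subject information is removed).
* **Domain label smoothing** (`domain_smooth = 0.1`): with hard targets the
  domain head saturates early, its gradient vanishes, and the reversed
  signal dies; smoothing keeps the head's optimum away from saturation so
  the pressure on the features persists.
* **Adversary refits on a replay buffer** (`domain_steps`,
  `domain_replay`): after each joint update the domain head alone is
  refit on a buffer of the last several minibatches' frozen features. A
  lagging adversary produces a misleading equilibrium -- the online head
  sits at chance while a freshly fitted probe still identifies subjects
  perfectly -- and a head refit on a single 64-window batch is too noisy;
  the buffer makes its estimate of the subject-discriminative directions
  close to what a fresh probe would find.
* **Post-ramp iterate averaging** (`average_after`): the raw min--max
  iterates oscillate; classic saddle-point theory says the *averaged*
  iterates converge even when the iterates themselves cycle. Epoch-end
  parameter snapshots from the last 40% of training are averaged into the
  returned model, which stabilizes both the staging accuracy and the
  residual subject decodability.
* **Label-head refit** (`head_refit`): the averaged extractor and the
  averaged affine stage readout are slightly misaligned; after averaging,
  the label head alone is refit on the frozen fused features. The
  extractor is untouched, so the representation -- and any subject
  information it lacks -- is unchanged.

With `beta = 0` the reversal path is skipped exactly, the domain head
trains as an independent probe, and the label-side trajectory is
bit-identical to a run with domain generalization disabled (verified in
the tests; parameter initialization draws the domain head from its own RNG
stream so ablating it does not disturb the rest).

Subject-invariance is *measured*, not assumed: `domain_probe()` fits a
fresh softmax regression on frozen fused features and reports held-out
accuracy against chance `1/R_d`.

## Training, evaluation, ablations

Training uses minibatch Adam (lr `1e-3`, batch 64) with optional early
stopping on a validation split. All randomness derives from one seed split
into independent streams (shared init, domain init, shuffling, validation
split), so runs are exactly reproducible and component ablations compare
cleanly. Adam's bias-correction counter is tracked per parameter so extra
head-only refits cannot perturb untouched parameters.

Evaluation is **subject-independent**: `subject_kfold()` deals whole
subjects into folds (shuffled by seed, round-robin, sizes within one
subject), and `cross_validate()` standardizes on the training subjects of
each fold before fitting. Metrics are accuracy, per-class and macro F1,
and Cohen's kappa; the headline numbers pool the concatenated fold
predictions (micro pooling), with per-fold mean and sd also reported,
since pooling conventions differ across the literature and both are cheap
to emit.

The ablation ladder of `sg_variant()` stacks components cumulatively:
(a) distance-view graph convolution only, (b) + temporal convolution,
(c) + attention, (d) + the learned view and fusion, (e) + domain
generalization.

## What the synthetic cohorts emulate

`generate_cohort()` produces feature-space cohorts with three controlled
ingredients: class mean patterns shared by all subjects (effect size
`delta`, in within-class sd units), subject-specific constant offsets
(`eta`) that a subject-invariant representation must ignore, and noise
coloured through a known ground-truth channel graph (default ring lattice)
so neighbouring channels correlate. Stage labels follow a first-order
Markov chain with stay-probability `rho`, emulating stage persistence.
`generate_raw_cohort()` additionally produces time-domain recordings in
which each stage carries an oscillation in its characteristic band
(Wake→beta, N1→theta, N2→sigma, N3→delta, REM→alpha), exercising the DE
extractor end-to-end.

The default cohort — 8 subjects × 400 epochs, N = 8 channels, Fd = 6,
`delta = 2.0`, `eta = 1.5`, `rho = 0.7`, seed 20240101 — is the package's
standard testbed: a class signal strong enough that a competent model
should exceed 0.9 held-out accuracy, and a subject nuisance strong enough
that a probe reads subject identity essentially perfectly from raw
features. What these cohorts deliberately do **not** model: real spindle /
K-complex morphology, artifacts, class imbalance of clinical hypnograms
(the stationary stage distribution here is uniform), inter-channel
physiology beyond second-order correlation, and non-stationarity within a
night. Passing the synthetic recovery tests therefore demonstrates that
the machinery optimizes and generalizes as designed — not that clinical
accuracy on real PSG is guaranteed.

The configuration used for the package's standard benchmark experiment is
frozen in `sg_reference_config()`: 4 channels per block, K = 3, 32
domain-hidden units, reversal strength 1.2 under the sigmoid warm-up, two
replay refits per batch, averaging and head refit over the last 40% of
100 epochs. The reduced capacity relative to the general defaults
(`channels = 10`) is deliberate: a leaner fused representation leaves the
adversary fewer places for subject information to hide and trains several
times faster. The test suite and the acceptance script run
leave-one-subject-out folds of this configuration on the default cohort,
and the ablation ladder on a reduced cohort (4 subjects × 150 epochs,
N = 6, `delta = 1.0`, `eta = 1.5`, 5 seeds); these sizes are the
package's own choices and are stated here so readers can scale them up.

A candid note on the adversarial trade-off: on cohorts with strong
subject nuisance the min--max game buys subject invariance at a real cost
in held-out-subject accuracy, and the size of that cost varies noticeably
with the training seed -- individual leave-one-subject-out folds range
from the high 0.70s to the high 0.90s under identical settings. The
stabilizers above shrink but do not eliminate this variance; it is the
main known limitation of the training procedure.

## Known limitations

* The N1 stage is intrinsically transitional; on real data it is the
  weakest class for all published stagers, and nothing in the synthetic
  cohorts reproduces that difficulty. Inverse-frequency class weights are
  available (`class_weights = "inverse"`) but off by default.
* The adversarial game reduces, but does not provably eliminate,
  linearly decodable subject information; `domain_probe()` should be run
  rather than trusted.
* The engine is pure R; it is comfortable at montage sizes of tens of
  channels and cohort sizes of a few thousand windows, not at
  whole-database scale.
* Only undirected (symmetrized) graphs are supported; directed spectral
  variants are out of scope.
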
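---
title: "Graph-signal processing and spectral graph convolution for event-related EEG: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-signal processing and spectral graph convolution for event-related EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(erpgraph)
```

# The problem

During vocal production with frequency-altered auditory feedback, a brief
downward pitch shift in the heard voice evokes a stereotyped ERP with
P1, N1 and P2 components; the P2 response (roughly 200–300 ms after the
perturbation) is enhanced in Parkinson's disease, particularly over left
fronto-temporal scalp regions involved in speech motor control. This
package implements a graph-learning pipeline that turns multi-trial
64-channel ERP epochs into subject-level functional-connectivity graphs,
reorganizes those graphs to emphasize group-discriminative structure, and
classifies subjects with a Chebyshev spectral graph-convolutional network
(GCN). Two interpretation layers accompany the classifier:
guided-backpropagation saliency over the input graph, and ERP microstate
analysis of the grand-average topographies. A trial-level voting rule
provides a posterior check that per-trial decisions aggregate into stable
subject-level decisions.

The clinical data that motivated the design are not redistributable, so
the package ships a synthetic cohort generator that reproduces the
statistical structure the pipeline assumes. Every stage is validated
against that generator's ground truth.

# Pipeline stages and their models

## Preprocessing

The ERP chain is fixed: zero-phase Butterworth band-pass (1–20 Hz),
epoching (−200…+500 ms around the perturbation onset; 700 samples at
1 kHz; windows are half-open `[start, end)`), peak-to-peak artifact
rejection, re-referencing to the mastoid average, baseline correction
over the full pre-stimulus segment, and trial averaging.

Numerical choices:

* The filter is applied forward and backward with odd-reflection padding
  and steady-state initial conditions (the standard `filtfilt`
  transient-suppression schedule), so it has exactly zero phase, no group
  delay, and negligible edge transients — a DC offset is removed to
  machine precision even in short epochs. The ERP band filter is a
  4th-order Butterworth band-pass; the connectivity band
  ([narrowband()], 4–12 Hz) uses a steeper order-3-per-edge design whose
  flatter passband makes re-filtering change the signal by less than
  0.1%. The multichannel application is a compiled
  direct-form-II-transposed kernel, validated bit-for-bit against an
  independent reference implementation of the same schedule on a frozen
  fixture.
* The artifact rule drops a trial iff any channel's peak-to-peak
  amplitude exceeds a threshold; the default threshold is 6 times the
  median (over trials) of the per-trial maximum absolute amplitude, a
  robust scale chosen because the detector used on the original data is
  not documented. The threshold is exposed.
* Baseline window −200…0 ms: the full pre-stimulus segment.

## Connectivity graphs

Connectivity is computed in the 4–12 Hz band. The Pearson option
z-scores each channel per trial (population normalization), so the
average cross-moment `(1/N_s) Σ_k r_i(k) r_j(k)` *is* the Pearson
correlation — the unnormalized cross-moment printed in some method
descriptions is only a correlation for standardized signals, and bounded
weights are required downstream. The phase-locking value (PLV) uses the
instantaneous phase of the analytic signal (FFT Hilbert construction)
with unit exponent on the phase difference. Per-trial matrices are
averaged across artifact-free trials to one matrix per subject; the
aggregation level is a package decision (the alternative — concatenating
trials — mixes trial-boundary discontinuities into the estimate).

From the weight matrix `W`, two k-nearest-neighbour graphs are built:
single-hop `A1` (k = 1) and multi-hop `A2` (k = 8). "k" is read as the
neighbour count of the k-NN rule, not as an adjacency power; each node
keeps its k largest-|W| neighbours (ties to the lower channel index) and
the edge set is symmetrized by union, keeping the original weights.

## Network alignment (the random-walk similarity stage)

The alignment stage relates the nodes of `A1` and `A2` through a
similarity matrix `S` solving the random-walk fixed point

S = α (A1 ⊗ A2) S + (1 − α) h,

with `h` a prior over node pairs and α = 0.5 by default. Three design
points matter:

* **Convergence.** The fixed point contracts only if α times the
  spectral radius of `A1 ⊗ A2` is below 1; both adjacencies are
  row-normalized (random-walk form) before iterating, which guarantees a
  spectral radius of at most 1. The iteration runs to a sup-norm
  residual of 1e-8 (cap 10 000 iterations) and is verified against a
  dense `(I − α A1⊗A2)⁻¹` solve on small graphs.
* **Implicit Kronecker algebra.** The n²×n² operator is never formed;
  `(A1 ⊗ A2) vec(X) = vec(A2 X A1ᵀ)` keeps every step at two n×n
  multiplications.
* **The prior.** The prior couples the subject to the two groups: `H_ij`
  is a sine-warped, clipped cosine similarity between node i's row in
  the group-0 mean adjacency and node j's row in the group-1 mean
  adjacency, normalized to sum 1. The precise functional form of this
  "sine-of-similarity" prior is one concrete reading of an
  under-determined description; it is isolated behind `build_prior()` so
  it can be swapped. Group means are computed on the **training split
  only**, so no test-subject label ever enters the stage.

A hard permutation is extracted from `S` by maximum-weight linear
assignment (a Jonker–Volgenant shortest-augmenting-path solver written
for this package and brute-force-verified for n ≤ 5) and applied
channel-wise to the subject's signals and connectivity. Similarity is
computed subject-versus-group-template, giving one permutation per
subject. Aligning a graph with itself under the diagonal-dominant prior
returns the identity, so on homogeneous data the stage is a no-op — the
reorganization only acts where single- and multi-hop structure disagree.

## Sparse self-expressive graph

For every electrode e, the trial-averaged signal `x_i^e` of subject i is
reconstructed from the remaining electrodes `X_i^e` with weights `w_i^e`,
with four penalties: row-wise ℓ2,1 sparsity across subjects (twice, with
separate weight matrices `B_g`, `B_t`) and two quadratic smoothness terms
that pull reconstruction weights together across similar subjects. The
package reads the group/trial split as: group-smoothness runs over
within-group subject pairs (similarities clipped to [0, 1] and masked
across groups), trial-smoothness over within-subject replicate pairs
(empty when fitting trial averages); both index sets are configurable
because the published notation does not pin them down. `B_g` and `B_t`
default to all-ones; the proximal step is exact for any row-constant
weighting, which the defaults satisfy.

The solver is proximal gradient (ISTA) with backtracking line search:
smooth terms by gradient, ℓ2,1 terms by row-wise group soft-threshold.
The objective is non-increasing by construction and the λ = 0 fit matches
per-subject least squares to 1e-6; a BFGS/Nelder–Mead polish on tiny
instances confirms the optimum within 1e-4. Defaults
λ = (0.1, 0.01, 0.1, 0.01).

The fitted weights reweight the graph: edge (e, e′) receives the
symmetrized absolute reconstruction mass
`½(|W^e[e′]| + |W^{e′}[e]|)` averaged over the fitted (training)
subjects. Zero rows prune edges. In the pipeline this reweighted graph —
fitted per fold on the training split of the aligned ERPs — becomes the
shared convolution graph of the classifier, while each subject's node
features stay individual.

## The classifier

Node features are the subject's 64-dimensional reorganized connectivity
rows (consistent with the 64-wide first convolution). The network is:
Chebyshev convolution (order K1, 64→64 features), node-coarsening pool
(½), Chebyshev convolution (K2, 64→32), pool (½), global mean over
nodes, fully connected 32→32, softmax output 32→M. Parameter counts are
audited in the tests: `4096·K1 + 64`, `2048·K2 + 32`, `1056`, plus
`32·M + M` for the output head, which is required by the softmax output
although the published layer table stops at the fully connected layer.
The table's "4 parameters" per pooling row is treated as a table
artifact: the pools here are parameter-free halvings of the node set by
greedy heaviest-edge pairing (leftover nodes paired by index so the node
count halves exactly), with mean pooling and summed inter-cluster
weights as the coarse adjacency.

Chebyshev filtering uses the scaled Laplacian `L̃ = 2L/λ_max − I`
(normalized Laplacian; λ_max by deterministic power iteration, tolerance
1e-6) and the three-term recursion — never an eigendecomposition; the
spectral form `U g(Λ) Uᵀ x` exists in the package only as the test
oracle. Training is full-batch Adam on cross-entropy with dropout 0.35
on the fully connected activations, early stopping on a training-loss
plateau (patience 20), and 5-fold cross-validation split **by subject**,
stratified by group, so no subject contributes to both sides of a fold.
Backpropagation is hand-rolled (needed anyway for guided backprop) and
verified against central finite differences at 1e-6.

On the optimization schedule: the architecture records the published
learning rate 1e-5, which belongs to a per-trial mini-batch regime with
thousands of optimizer steps. This package trains one full batch of
subjects per epoch — a few hundred steps — so `gcn_fit()` defaults to
1e-3 over 200 epochs, which moves the parameters by a comparable total
amount. Both are plain arguments.

## Interpretation

*Guided backprop*: gradients of a class logit are chained from the
output to the input features, overwritten at every ReLU so that only
units with positive activation *and* positive upstream gradient pass
gradient. Node saliency is the L2 norm of the input-gradient row, edge
saliency `|g_i||g_j|A_ij`, both max-normalized. Per-subject maps are
computed on the trial-averaged input, mapped back through the subject's
alignment permutation to montage channels, and averaged over correctly
classified subjects of the target class (the aggregation across
subjects is a package decision; the activation nonlinearity must be
ReLU-family for the masks to be meaningful, which holds here).

*Microstates*: global field power is the per-sample population standard
deviation across channels. Topographies at GFP local maxima of the two
group grand averages are unit-normalized and clustered jointly with
k-means (50 seeded restarts), **polarity-sensitive** — these are ERP
topographies with meaningful sign, unlike resting-state microstate
practice. The class count is chosen by the Krzanowski–Lai criterion,
`KL(k) = |DIFF(k)|/|DIFF(k+1)|` with
`DIFF(k) = (k−1)^{2/p} W_{k−1} − k^{2/p} W_k` on the within-cluster
dispersion `W_k` (p = number of channels); k = 1 is excluded by
construction. Templates are back-fitted per group by maximal spatial
correlation; runs shorter than 10 ms merge into the neighbour with the
stronger boundary correlation. The five states and the 205–315 ms window
reported on the clinical data are outcomes, not constants, and are not
hard-coded anywhere.

*Trial voting*: for each subject, 10 of the per-trial predicted labels
are drawn without replacement; the majority decides, and a 5–5 tie is
broken by counting equal consecutive pairs (an equal pair increments
that label's counter, an unequal pair cancels) — the worked contract is
`{0,1,1,0,1,0,0,1,1,0} → BM0 = 1, BM1 = 2 → healthy`. A double tie
(e.g. a strictly alternating draw) is possible and undefined in the
source procedure; the package decides "healthy" (the benign default) and
flags the event. The draw-vote cycle repeats 100 times and the mean and
population variance of accuracy are reported.

# The synthetic cohort generator

The generator emulates the study conditions: two groups of subjects,
100 trials each, 64 channels at 1 kHz, −200…+500 ms epochs. Each trial
is a sum of component topographies times temporal Gaussians:

| component | latency | width | amplitude | topography |
|---|---|---|---|---|
| P1 | 80 ms | 20 ms | +1.0 | fronto-central Gaussian |
| N1 | 150 ms | 30 ms | −1.6 | fronto-central Gaussian |
| P2 | 260 ms | 45 ms | +1.4 | left fronto-temporal (between F7/FT7) + fronto-central |

Group 0 ("patients") receives `p2_effect` times the P2 amplitude;
`p2_effect = 1` is the exact null (groups identically distributed) and
the default 2.5 represents the clearly enhanced P2 the paradigm is known
for. Topographies are Gaussians in angular distance on the electrode
sphere — a deliberate stand-in for source projection, not a forward head
model. Background noise is spatially correlated 1/f noise (16 smoothly
mixed sources), a 10 Hz oscillation with random phase per trial and a
posterior topography, and white sensor noise; subject-level amplitude
and latency variability and trial-level jitter all scale with
`noise_scale`, so `noise_scale = 0` is exactly deterministic and the
trial-averaged ERP then peaks exactly at `p2_latency`. Amplitudes are
arbitrary z-like units; no µV calibration is attempted, because the
source description gives no amplitude or SNR figures — the scales are
free parameters chosen once to give single-trial SNR below 0 dB in the
4–12 Hz band, and exposed in the config. Artifacts are amplitude
steps-plus-drifts injected with a known mask, used as ground truth for
the rejection tests.

What the generator does *not* emulate — volume-conducted source
geometry, non-stationary artifacts (ocular, muscular), medication or
severity gradients, electrode impedance drift — bounds what passing
tests show: they validate the pipeline's statistical machinery, not
clinical performance.

The generator reports its planted ground truth: the P2 topography, the
three strongest-loading electrodes (the "planted focus": FT7, F7, F5 on
the 64-channel montage), and the component latencies. The saliency
recovery checks ask that this focus appear among the top-5 salient
channels.

# Validation scales and what is computed where

The test suite validates each operation against independent oracles
(dense Kronecker solves, permutation enumeration, spectral filtering,
textbook Pearson, least squares, finite-difference gradients, exhaustive
vote enumeration) and runs the pipeline end to end at these scales,
chosen as reduced but faithful study sizes:

* strong-effect cohort: 20 subjects per group, 100 trials, p2_effect
  2.5, full pipeline with 5-fold CV — the headline recovery check
  (cross-validated accuracy ≥ 0.90);
* null cohort: 10 subjects per group, p2_effect 1.0 — accuracy must fall
  inside the binomial 95% CI of chance;
* effect monotonicity: 6 subjects per group, 30 trials, effects
  {1.0, 1.5, 2.5} × 3 seeds on the PCC+GCN path;
* saliency localization: three seeds (one study-scale, two at 6 subjects
  per group, 40 trials), majority vote;
* determinism: the full pipeline run twice at 5 subjects per group must
  produce byte-identical stage manifests.

`scripts/acceptance.R` recomputes the in-text exact quantity (the
consecutive-pair tie-break count of the worked voting example) directly
through `bm_counts()`.

# Known limitations

* Electrode-space analysis only; no source localization, by design.
* The sparse-graph trial block is inert when fitting trial averages; it
  activates only when replicate columns are supplied.
* The prior of the alignment stage and the `B` weighting matrices of the
  sparse graph are under-determined in the source description; the
  implemented forms are documented defaults behind stable interfaces.
* The greedy pooling pairing is deterministic but tie-broken by node
  index; graphs with many exactly-equal weights can coarsen differently
  after relabeling.
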
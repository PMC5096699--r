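---
title: "Space-by-time decompositions of population spike trains: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-by-time decompositions of population spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poptensor)
```

## The problem and the models

A population of `N` neurons responds to repeated stimulus presentations.
Binning each trial's spikes into `T` short intervals (10 ms by default)
gives a non-negative count matrix `R^s` of size `T x N` per trial `s`; the
full dataset is the trial tensor `S x T x N`. The package decomposes these
single-trial responses into *trial-invariant firing modules* and
*trial-dependent activation coefficients*, in three flavors:

* **Spatiotemporal (matrix) decomposition** — `r^s(t) = sum_k h_k^s b_k(t)`:
  each module `b_k` is a full `T x N` firing pattern; a trial is a weighted
  sum of `K` such patterns. Computed on the `S x (T*N)` matricization
  (time-major flattening) as `R = H B`.
* **Space-only decomposition** — `r^s(t) = sum_k h_k^s(t) b_k`: modules are
  vectors over neurons only, with time-resolved coefficients; computed on the
  `(S*T) x N` matricization.
* **Space-by-time (Tucker-2) decomposition** — `R^s = B^tem H^s B^spa`:
  `P` temporal modules (columns of `B^tem`, `T x P`) and `L` spatial modules
  (rows of `B^spa`, `L x N`) shared by all trials, with a per-trial `P x L`
  coefficient matrix `H^s`. This assumes every firing pattern factorizes into
  "which neurons fire together" times "when they are activated"; the payoff
  is far fewer parameters (`T*P + L*N` instead of `K*T*N`), which makes the
  fit markedly more robust to noise and small sample sizes.

Constraints select the algorithm. Non-negativity gives spatiotemporal NMF
(Lee–Seung multiplicative updates on the Euclidean objective) and
space-by-time NMF (non-negative Tucker-2, alternating multiplicative updates
of `B^spa`, `B^tem` and the per-trial core slices; every update is
non-increasing in the summed Frobenius objective). Orthogonality gives PCA
and orthogonal Tucker-2 (higher-order orthogonal iteration with HOSVD
initialization); statistical independence gives ICA (Hyvärinen's fixed-point
iteration with a logcosh contrast, symmetric decorrelation); a Gaussian
latent-variable model gives FA (EM with per-variable noise). For ICA the
independence assumption is placed on the *modules* (as functions over the
`T*N` cells), not on the activations: the modules are the sources and trials
are their mixtures. This matters for interpretation — overlapping ground-truth
patterns are dependent as sources, which is exactly why ICA (like PCA's
orthogonality and FA's Gaussianity) cannot fully recover them, while NMF can.

## Tunable parameters

* `bin_width` (ms; default 10) and `window` (default 0–300 ms): the temporal
  discretization. Bins are half-open `[t, t+Δ)`; a spike exactly at the
  window end is out of window. The half-open convention is ours — the edge
  rule has no observable consequence for Poisson simulations and real data
  at reasonable bin widths.
* Module counts `K` or `(P, L)`: either fixed or selected by leave-one-out
  validation (below).
* NMF controls: `tol = 1e-6` relative objective decrease per sweep,
  `max_iter = 500`, `n_restarts = 5`, uniform(0,1) initialization,
  denominators floored at machine epsilon. These defaults favor well-converged
  fits; module-count selection uses looser fits (`tol = 1e-4`,
  `max_iter = 150`, one restart) because selection only compares candidates'
  decoding accuracy, which stabilizes long before the objective does.
* LDA ridge: the pooled within-class covariance receives a ridge of
  `1e-6 * trace/d` (escalated 100-fold while singular) whenever Cholesky
  fails or is ill-conditioned — necessary for raw LDA on `T*N` correlated
  count features, harmless otherwise.

## Decoding and module-count selection

`decode_pipeline()` splits trials per stimulus, fits modules on training
trials only, infers test-trial coefficients with modules frozen (closed-form
projection for orthogonal/linear fits; coefficient-only multiplicative
updates for NMF), removes zero-variance coefficients, and scores a
pooled-covariance multiclass LDA on the test set. No quantity derived from
test trials enters fitting, selection, or classifier training; a test
asserts the test tensor is byte-identical before and after.

`select_module_numbers()` implements leave-one-out selection on the training
set: one trial per stimulus forms the validation fold; modules are refit on
the rest; fold-averaged validation accuracy drives the choice. Ties go to
the smallest total module count, then smallest `P`, then `L` — so in the
regime where decoding saturates, the most compact adequate model wins.

## The simulator and what it does (not) emulate

`make_block_patterns()` + `generate_trials()` produce inhomogeneous-Poisson
population responses from rectangular "block" firing patterns on a canonical
geometry of 20 neurons and 30 bins (10 ms): two 6-neuron groups and two 8-bin
windows, whose four group-by-window combinations form partly overlapping,
space-time-separable blocks (adjacent groups share 2 neurons, adjacent
windows 2 bins). Presets cover: the separable four-block mixture (each block
independently present with probability 0.5); a non-separable variant whose
blocks are staircases of 2-neuron pairs advancing in 6-bin steps from the
same anchors (8-bin steps cannot fit two staircases in a 30-bin window); an
overlap series (levels 0–3) that shifts group/window sharing at constant
block area, calibrated in closed form so the mean pairwise geodesic overlap
spans ~9.8%–32.2%; disjoint base blocks with four mixing tables; and an
information-structure set with pattern pairs differing only in space, only
in time, or in both.

Superposition of co-active patterns is **additive** on top of the 2 Hz
background: the rate is `background + sum of active patterns`. We provide an
element-wise `max` rule as an option but do not use it by default, because
under `max` the blocks are genuinely not the additive parts of the data —
even a perfectly converged noiseless non-negative fit then assigns half
weight to shared cells and caps recovery around 85%, contradicting the
near-perfect recovery non-negative factorization demonstrably achieves on
this design. Counts are drawn directly as Poisson(rate × Δ) per bin, which
is equal in distribution to generating event times and binning, at a
fraction of the cost.

What the simulator does *not* emulate: refractoriness or any non-Poisson
spiking statistics, trial-to-trial gain fluctuations, noise correlations
between neurons, and receptive-field structure. Passing the validation suite
therefore demonstrates correctness of the algorithms and their comparative
behavior on Poisson data with known ground truth — not that real recordings
meet the factorization assumptions.

## Quantifying recovery

Module similarity is the geodesic similarity
`sim(u, v) = 1 − (2/π)·arccos(cos∠(u, v))` — 1 for identical directions, 0
for orthogonal vectors, scale-invariant. Module-set recovery is the mean over
the one-to-one assignment maximizing total similarity (exhaustive enumeration
up to 6 modules, Hungarian assignment beyond; the two routes are
cross-checked in tests). Space-by-time fits are first expanded to their
`P*L` outer-product modules. Sign-indeterminate methods (PCA/ICA/FA/
orthogonal Tucker-2) are compared up to sign. Note that components from
centered methods are mean-removed, which depresses their uncentered cosine
against non-negative ground truth; this penalty is part of the measure, and
is one reason orthogonality/independence-constrained methods score low on
non-negative block patterns even when they span the right subspace.

## Study sizes and numerical choices

The packaged validation studies use 900-trial mixtures for module recovery
(five simulations per estimate; across-simulation standard deviations
are a few tenths of a percentage point for the non-negative fits) and ten
30-trial-per-stimulus datasets for the selection study. The selection study
runs at overlap level 1 with SNR 50, the regime in which decoding at the
ground-truth counts saturates — the operating characteristic reported for
this procedure's validation — so that the minimum-count tie-break is
exercised; at lower SNR the additive background itself becomes a legitimate
extra spatiotemporal component and the procedure (correctly, but
uninformatively for validation) selects K = 5.

Degenerate inputs are handled explicitly: all-zero tensors are rejected by
the NMF fits (multiplicative updates are scale-free), zero modules are left
unnormalized, zero validation variance removes a coefficient, and an
all-silent trial in the rank-order decoder correlates equally with every
template and falls to the deterministic smallest-label tie-break.

## Known limitations

* Non-negative fits find local minima; restarts mitigate but do not remove
  this. Reported similarities are single-run values by design, mirroring how
  such results are usually quoted.
* The geodesic-similarity normalization (arc length scaled by π/2) is one of
  several monotone transforms of the principal angle in use; recovery
  percentages are sensitive to this choice, so cross-study comparisons of
  absolute percentages should be made with care.
* The FA fit monitors a partial convergence criterion (noise-variance
  trace) rather than the full marginal likelihood; for the small factor
  counts used here this is adequate but not a general-purpose FA.
* Orthogonal Tucker-2's fit is guaranteed non-decreasing but, like all HOOI
  schemes, not globally optimal.
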
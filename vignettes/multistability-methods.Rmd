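---
title: "Counting stable synchronisation states on structural brain networks"
author: "strobosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting stable synchronisation states on structural brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strobosync)
```

## The question

A structural brain network — regions joined by white-matter tracts with
measurable strengths and lengths — constrains the dynamics that can unfold
on it. `strobosync` asks a specific question about that constraint: does a
given network let its dynamics settle into *several* distinct stable
synchronisation patterns, or only one? A repertoire of stable states is a
candidate substrate for flexible function: the same anatomy can host
different coordination regimes depending on where the dynamics start.

The package answers by brute sampling. Noise-free oscillator dynamics are
integrated from many random initial conditions; each run is summarised by a
vector of pairwise synchronisation indices (its *pattern*); the patterns are
clustered; the number of clusters is the number of stable synchronisation
states reachable in practice. Because the dynamics carry no noise, a run's
pattern is a deterministic function of its initial phases, so distinct
patterns witness distinct attractors rather than stochastic wandering.

## The dynamical model

Each node `n` is a phase oscillator with intrinsic frequency `f_n` drawn
uniformly from the gamma band (25–75 Hz by default), coupled through the
weighted network with transmission delays. One Euler step of duration `dt`
(default 1 ms) advances the unwrapped phase as

    theta_n(t+1) = theta_n(t) + omega_n + sum_p K_np sin(theta_p(t - tau_np) - theta_n(t))

with `omega_n = 2*pi*f_n*dt`, coupling gains `K_np = k * C_np * dt` built
from the structural weight matrix `C` (GFA-scale, dimensionless) and the
global factor `k` (default 1000), and integer delays
`tau_np = round(L_np / 20)` from the tract-length matrix `L` in mm. With
`dt` = 1 ms the delay rule corresponds to a 20 m/s conduction velocity and a
2000-step run spans 2 s of activity. There is no noise term: stabilisation
at an attractor is the point of the protocol, and noise would blur the
mapping from initial condition to reached state.

Two choices here deserve justification:

* **Coupling normalisation.** The classical mean-field Kuramoto form divides
  the coupling by `N`. On GFA-scale weights (median ≈ 0.05) with `k = 1000`
  and `dt` = 1 ms, dividing by `N = 34` leaves per-step coupling increments
  near 1.5e-3 rad against intrinsic increments of ~0.3 rad — effectively
  uncoupled, and no synchronisation of any kind emerges. Without the `1/N`
  factor the per-edge gain is `C_np` ≈ 0.05 rad/step, and node-level
  coupling becomes comparable to the dispersion of intrinsic frequencies —
  an intermediate synchronisation regime in which partial locking, and hence
  a meaningful pattern repertoire, exists. The package therefore defaults to
  `normalise_by_n = FALSE`; the mean-field variant remains one flag away.
* **Delay history.** For `t <= 0` each node's history is its constant
  initial phase (`history = "constant"`). A random-history alternative is
  available; the constant convention keeps a run a deterministic function of
  its `N` initial phases alone.

The integrator is validated against the limits that admit closed forms: at
zero coupling every node advances at exactly `omega_n` (Euler is exact for
constant phase velocity); two identical-frequency nodes with zero delay
contract onto the zero-lag fixed point of the update map; and adding a
common constant to all initial phases translates the whole trajectory
rigidly.

## The stroboscopic synchronisation index

Pairwise synchronisation is scored stroboscopically: every time the
*reference* oscillator of a pair completes a cycle — its unwrapped phase has
advanced by another multiple of 2π since the start of the analysis window —
the partner's concurrent phase is recorded. The modulus of the mean of the
unit vectors `exp(i * (theta_other - theta_ref))` over those instants is the
directional index; the roles are then reversed and the two directional
indices averaged. The first 100 steps of every run are discarded as
pre-stabilisation transient.

A locked pair samples a constant phase difference, giving an index of 1
*regardless of the lag* — anti-phase locking scores exactly as high as
in-phase locking. This is deliberate: a large phase lag may reflect strong
but distant coupling, so lag-penalising indices (such as the cosine-of-lag
family) understate synchronisation through long tracts. Uncorrelated
oscillators scatter their sampled differences around the circle and the
index decays to 0 at the usual `1/sqrt(M)` Monte-Carlo rate in the number
`M` of wrap events (~95 events in a 1.9 s window at gamma frequencies).

Numerical details that matter:

* **Interpolated wrap instants.** On a discrete time grid a gamma cycle
  spans only ~13–40 steps, so taking the nearest sample to each cycle
  completion quantises the sampling instants noticeably. The crossing time
  is therefore located by linear interpolation of the reference phase, and
  the partner phase is interpolated to the same instant. A nearest-sample
  mode exists behind the `interpolate` flag.
* **Phase-origin invariance.** Cycle completions are counted from the phase
  at the start of the analysis window rather than from absolute zero. The
  event set is then exactly invariant under a global phase shift of the
  trajectory, and so is every index.
* **Phase source.** Indices are computed directly from the integrator's
  phases by default. A fidelity mode (`mode = "signal"`) renders each node
  as `sin(theta)`, maps it back to phase through the analytic signal
  (FFT-based Hilbert construction) and proceeds identically, emulating a
  pipeline that only observes oscillatory signals; the two routes agree to
  within 0.02 on 34-node fixtures, the discrepancy coming from analytic-
  signal edge effects.

For an `N`-node run the indices are packed in fixed row-major upper-triangle
order into a pattern of length `N(N-1)/2` — 561 pairwise indices for a
34-node network.

## Counting states

One *dynamical system* — a network plus one draw of intrinsic frequencies —
is assessed by `assess_multistability()`:

1. simulate `n_runs` (default 100) runs from independent uniform random
   initial phases;
2. standardise the `n_runs x N(N-1)/2` pattern matrix column-wise;
3. choose the cluster count `k` by the gap statistic over `k = 1..6`;
4. refit k-means at the optimum, sort runs by cluster, and cross-correlate
   the sorted raw patterns into a run-by-run Pearson matrix in which
   multistability appears as diagonal blocks.

The gap statistic compares `log W_k` — `W_k` the sum over clusters of
`D_r / (2 n_r)`, with `D_r` the within-cluster sum of pairwise squared
distances, equal to the total within-cluster sum of squares — against its
Monte-Carlo expectation under a structureless reference distribution,
uniform over each column's range (50 reference datasets by default).
`k` is selected by the one-standard-error rule: the smallest `k` with
`Gap(k) >= Gap(k+1) - SE(k+1)`; a global-maximum rule is available behind
the `rule` flag. Evaluation starts at `k = 1`, so "no multistability" is an
explicit outcome rather than a failure mode. k-means uses the standard
Hartigan–Wong algorithm with 20 random restarts per `k`; on the planted
blob benchmarks used in the tests this selection reproduces the independent
`cluster::clusGap` implementation decision-for-decision.

Two degeneracy rules keep the count honest:

* columns with exactly zero variance standardise to zero columns (pair
  order and dimensionality are preserved);
* columns whose across-run standard deviation falls below an
  `index_resolution` floor (default 0.01) are also treated as constant.
  An index estimated from ~100 wrap events carries sampling error of that
  order, and column standardisation would otherwise inflate sub-resolution
  jitter — runs that reached the *same* attractor up to estimation noise —
  into well-separated spurious clusters. Setting the floor to 0 recovers
  plain standardisation.

## Null networks and comparisons

Whether a multistability level is attributable to network *structure* is
judged against rewired surrogates: connected double-edge swaps (the
classical degree-preserving rewiring with a connectedness check) that move
each edge's (weight, length) attribute pair with it. A null network thus
preserves node count, edge count, the degree sequence, the exact multiset of
edge attributes, and connectedness — everything except the wiring pattern.
The default protocol builds 15 nulls and surveys 40 frequency draws on each,
against 200 draws on the real network (100 runs each; 20,000 simulations per
network at full scale).

Surveys are compared three ways: the distributions of per-system state
counts via the two-sided two-sample Kolmogorov–Smirnov test (asymptotic
p-values, since counts in 1..6 are heavily tied); the element-wise contrast
between averaged run-by-run pattern-correlation matrices, where
real-specific multistability aggregates positive values near the main
diagonal (summarised here by a near-diagonal band mean, a diagnostic of this
package's own construction); and the Pearson correlation between the
grand-average synchronisation matrix and the structural weight matrix over
upper-triangle entries, the structure–function coupling.

## The synthetic generator

No imaging data ship with the package; `generate_network()` produces
networks with the statistical signature the pipeline cares about: sparse
symmetric non-negative weights, planted modular structure
(`p_within >= p_between`), log-normal weights on the GFA scale (median 0.05,
sdlog 0.5 by default), and tract lengths taken from a random 3-D spatial
embedding (100 mm per unit distance, floored at 20 mm, matching the minimum
fibre length of typical tractography), so that lengths respect the
triangle-inequality-like geometry of real tracts. `between_weight_factor`
attenuates inter-module weights, emulating the weaker anisotropy of
long-range association tracts. `generate_partitioned_variant()` splits each
node of a network into several child segments while keeping the parent-level
edge structure — the construction used to test whether a network's dynamics
change when its landmarks are subdivided without changing its white-matter
skeleton.

What the generator does *not* emulate: empirical degree and weight
distributions of DSI-derived matrices beyond the qualitative features above,
hemispheric symmetry, distance-dependent connection probability, or any
voxel-level property. Conclusions from synthetic fixtures are statements
about the method's behaviour in a controlled regime, not about any real
anatomical network.

## Problem sizes and regime choices in the shipped checks

The test suite runs the complete pipeline at *smoke scale*: an 8-node
fixture of two complete modules (log-normal weights, median 0.1, between-
module weights attenuated ×0.3), 20 frequency draws of 20 runs on the real
network and 10 draws on each of 3 nulls, 25 gap references. Module-level
locking then stabilises well inside the 2000-step window — the regime the
protocol assumes — while inter-module locking sits near threshold, so
initial conditions genuinely select among cluster-synchronisation states on
the modular network but not on its rewired nulls, which homogenise into a
single global state. At the default 34-node generator settings the same
coupling scale produces near-global locking (predominantly single-state
systems); both regimes are exercised in the tests. Full paper-scale surveys
(200×100 plus 15×40×100 simulations) run with the same code path via
`run_config()` defaults; only wall-clock time separates them from the smoke
preset.

## Known limitations

* Euler integration with `dt` = 1 ms is the protocol, not a convergence
  choice; the update *map* (not its continuum limit) defines the dynamics
  whose attractors are counted.
* The stroboscopic index is undefined for a reference that never completes
  a cycle in the window (an error, not a silent 0), and near-zero-frequency
  oscillators would need longer windows.
* The gap statistic is evaluated at most at `k_max = 6`; a system with more
  attractors than that is reported as 6.
* State counting is resolution-limited: attractors whose patterns differ by
  less than `index_resolution` in every pair are merged.
* KS p-values are asymptotic under heavy ties; an exact or permutation
  alternative is not implemented.
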
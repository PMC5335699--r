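# strobosync

Multistability analysis of delayed Kuramoto dynamics on weighted structural
brain networks.

A structural brain network — regions connected by white-matter tracts with
coupling strengths (GFA-scale) and lengths (mm) — may let neural dynamics
settle into one, or into several, distinct stable synchronisation patterns.
`strobosync` measures which, and whether the answer is attributable to the
network's wiring rather than to its degree sequence and edge attributes
alone.

The pipeline:

1. **Dynamics.** Noise-free delayed Kuramoto oscillators, one per node, with
   Euler updates

   `θ_n(t+1) = θ_n(t) + ω_n + Σ_p K_np sin(θ_p(t − τ_np) − θ_n(t))`

   where `ω_n = 2π f_n dt` with `f_n` drawn from the gamma band (25–75 Hz),
   `K_np = k C_np dt` from the weight matrix `C` (`k = 1000`, `dt` = 1 ms),
   and integer delays `τ_np = round(L_np / 20)` from tract lengths `L`
   (a 20 m/s conduction velocity). 2000 steps per run, the first 100
   discarded as transient.
2. **Stroboscopic index.** Each node pair is scored in [0, 1] by sampling
   one oscillator's phase whenever the other completes a cycle and taking
   the circular mean resultant length of the sampled phase differences,
   averaged over the two role assignments. Any fixed lag — including
   anti-phase — scores 1; uncorrelated oscillators score 0.
3. **State counting.** Each network+frequency combination is simulated from
   100 random initial conditions; the 100 patterns (561 pairwise indices for
   34 nodes) are standardised column-wise and clustered by k-means with the
   gap statistic (k = 1…6, one-standard-error rule). k ≥ 2 means the system
   is multistable.
4. **Null comparison.** The same survey runs on rewired networks built by
   connected double-edge swaps that preserve degrees and carry each edge's
   (weight, length) pair along — state-count distributions are compared by
   two-sided two-sample KS tests, pattern-correlation contrast matrices, and
   structure–function correlation.

A seeded synthetic generator (modular planted-partition topology, log-normal
GFA-scale weights, lengths from a 3-D spatial embedding) makes the whole
pipeline runnable and testable without imaging data.

## Worked example

```r
library(strobosync)

net <- generate_network(synthetic_network_spec(
  n_nodes = 8, n_modules = 2, p_within = 1.0, p_between = 0.15,
  weight_meanlog = log(0.1), between_weight_factor = 0.3, seed = 1))
net
#> structural_network: 8 nodes, 14 edges
#>   weights: [ 0.028 , 0.24 ]  lengths (mm): [ 20 , 91 ]

sys <- build_system(net, sample_frequencies(8, band_hz = c(25, 75), seed = 5))
sys
#> dynamical_system: 8 nodes, k = 1000 , dt = 0.001 s, delays 1 - 5 steps

res <- assess_multistability(sys, n_runs = 20, n_reference = 25, seed = 105)
res
#> multistability_result: optimal_k = 6 (multistable)
#>   cluster sizes: 1, 1, 3, 10, 1, 4
```

This dynamical system reaches at least six distinct stable synchronisation
patterns from random initial phases: the gap curve keeps widening up to the
evaluation cap (`gap` rises from 0.36 at k = 1 to 7.31 at k = 6), and the
sorted run-by-run Pearson matrix `res$pattern_correlation` shows
perfectly correlated runs within each cluster block. A different frequency
draw on the same network (`seed = 4`) yields `optimal_k = 1` — a single
state — which is how the per-network state-count distribution arises.

The full survey, including nulls, runs through one call:

```r
out <- run_pipeline(smoke_config(seed = 1), out_dir = "runs/smoke")
out$real_survey$distribution
#> state_count_distribution over 20 systems
#>  1  2  3  4  5  6
#>  9  0  0  0  1 10
#>   non-multistable (k = 1): 45.0%
out$null_distribution
#> state_count_distribution over 30 systems
#>  1  2  3  4  5  6
#> 30  0  0  0  0  0
#>   non-multistable (k = 1): 100.0%
out$ks
#> two-sided two-sample KS: D = 0.55 , p = 0.001406  (n = 20 vs 30 )
out$structure_function_r
#> [1] 0.7932108
```

Here the modular 8-node fixture is multistable in 55 % of frequency draws
while its degree-, strength- and length-preserving rewirings never are
(KS p ≈ 0.0014), and average synchronisation correlates positively
(r ≈ 0.79) with the structural weights. A command-line wrapper for the same
pipeline lives at `inst/scripts/run_pipeline.R`.

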
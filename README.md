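# monoconn

Monotone trends in graph-theoretic summaries of task fMRI.

## What this package is for

During associative learning, behavioral proficiency typically improves
monotonically across task repetitions. Whether *connectomic* summaries of
fMRI acquired during the same task — a node's importance in the functional
network, or the network's overall efficiency — change monotonically too is
an open empirical question. `monoconn` implements the full analysis
pipeline for asking it, aimed at researchers working with block-design
task fMRI who have parcellated regional time series in hand:

1. **Epoch segmentation.** Each acquisition is cut into (condition,
   iteration) windows — at the defaults, 8 iterations × 4 conditions
   (Encoding, Post-Encoding Rest, Retrieval, Post-Retrieval Rest) × 9
   volumes (27 s at TR = 3 s), 288 volumes in all.
2. **Full weighted connectivity graphs.** Per epoch, the zero-lag Pearson
   correlation between every pair of regional series, Fisher-Z
   transformed. All n(n−1)/2 edges are kept (30,135 at 246 regions) —
   no thresholding.
3. **Graph metrics.** Weighted betweenness centrality per node,

       BC_i = 1/((n−1)(n−2)) · Σ_{h≠j; h,j≠i} sp_hj(i) / sp_hj

   computed on inverted edge weights (stronger coupling = shorter path),
   then converted to a rank order BC_RO ∈ [1, n] (1 = most central); and
   the average shortest path length

       ASPL = 1/(n(n−1)) · Σ_{i≠j} d(v_i, v_j)

   by Dijkstra on the same distances.
4. **Monotonicity statistics.** Every 8-point trajectory is classified
   for weak monotonicity (D₁ ≤ … ≤ D₈ with D₁ ≠ D₈, or the reverse),
   with a one-violation relaxation; group-averaged rank trajectories are
   screened with Spearman's ρ against iteration number, using the exact
   permutation distribution over all 8! orderings for the p-value.
5. **Group inference.** A three-way mixed ANOVA of ASPL (Group between;
   Condition and Time within), Fisher's exact test on behavioral
   monotone proportions, and pooled edge-weight distribution summaries
   per group.

A first-class synthetic cohort generator (`synth_config()`,
`generate_cohort()`) simulates the whole design under an epoch-wise latent
factor model with *planted*, ground-truth-known structure — monotone
"hubness" drift in chosen nodes, reduced coupling and lower learning
asymptote in a patient-like group — so every stage of the pipeline can be
validated against known truth. See the vignette
(`vignettes/monotone-connectomics.Rmd`) for the model and all numerical
choices.

## Worked example

Simulate a small cohort with three hub nodes whose coupling grows by
+0.06 per iteration (so their betweenness rank should fall monotonically),
run the pipeline, and compare the screen's calls with the planted truth:

```r
library(monoconn)

cfg <- synth_config(
  n_regions = 24, n_participants_per_group = 20,
  hub_nodes = 1:3, drift_per_iteration = 0.06,
  base_coupling = 0.35, coupling_spread = 0.3,
  group_coupling_offset = 0.04, noise_sd = 0.25, seed = 101)

cohort <- generate_cohort(cfg)
res <- run_cohort_analysis(cohort)
res
#> monoconn cohort analysis
#>   40 participants, 24 nodes, policy 'exclude_nonpositive'
#>   group trend screen: 38/192 trajectories significant at alpha = 0.05
#>   behavioral monotone proportions: Fisher exact p = 0.03095

trend_recovery(res$screen, cohort$manifest$hub_nodes,
               cohort$manifest$expected_bcro_direction)
#> $hub_rate
#> [1] 0.9583333
#> $nonhub_rate
#> [1] 0.08928571
#> $n_hub_tests
#> [1] 24
#> $n_nonhub_tests
#> [1] 168
```

96% of the planted hub trajectories (3 hubs × 4 conditions × 2 groups)
are flagged significant in the expected (decreasing-rank) direction,
against a 9% false-positive rate among the 21 non-hub nodes — the planted
monotone hubness drift is recovered, and under a no-drift configuration
the significant fraction sits at the nominal 5% level (see
`tests/testthat/test-acceptance.R`).

The step-by-step version of the same analysis — simulation, graph
metrics, monotonicity screening, group statistics — lives in the numbered
scripts under `analysis/`, which write their tables to `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_graph_metrics.R
Rscript analysis/03_monotonicity.R
Rscript analysis/04_group_stats.R
```

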
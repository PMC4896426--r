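# netdyn

Dynamic functional-network analysis for multivariate time series:
sliding-window connectivity with exponentially decaying weights, signed
weighted community detection, temporal co-occurrence matrices, node-level
dynamics metrics, surrogate and random-graph null models, and
cross-validated brain–behavior association with permutation inference.

## The scientific problem

Parcellated resting-state recordings give one time series per brain node.
Static network analysis summarizes the whole scan in one connectivity
matrix; it cannot see nodes whose community affiliation *changes* over
time. netdyn characterizes that temporal reorganization:

1. **Windowed connectivity.** Within sliding windows of length *T* frames,
   connectivity is the weighted Pearson correlation with exponentially
   decaying weights `w_t = w0 * exp((t - T) / theta)`,
   `w0 = (1 - e^(-1/theta)) / (1 - e^(-T/theta))`, Fisher z-transformed.
2. **Signed communities.** Each window's complete signed weighted matrix is
   partitioned by Louvain-style optimization of the asymmetric signed
   quality Q\* (positive weights rewarded within communities against a
   configuration-model expectation; intramodular negative weights
   penalized, down-weighted by total negative strength). The best of
   `n_init` seeded restarts is kept.
3. **Temporal co-occurrence.** `C_ij` is the fraction of windows in which
   nodes i and j share a community. Against a reference partition (static
   group connectivity), each node gets: temporal **flexibility**
   `f_i = sum_{j not in u_i} C_ij / sum_{j != i} C_ij`, spatiotemporal
   **diversity** `h_i` (normalized entropy of co-occurrence strength over
   communities), and within-community **centrality** `z_i` (z-score of
   within-community strength).
4. **Null models.** Phase-randomized surrogates (exact per-node spectra,
   destroyed cross-correlations) ablate the dynamics; degree- and
   strength-preserving random graphs calibrate a first-principal-component
   structure test on C.
5. **Behavior.** A cross-validated canonical correlation links a scalar
   brain summary to a behavioral battery, with a fold-regenerating
   permutation test.

A seeded synthetic generator with planted community structure and planted
flexible nodes is first-class, tested code: every estimator above is
validated against ground truth it controls.

## Worked example

```r
library(netdyn)

# a compact synthetic cohort: 20 nodes in 4 planted communities, one
# flexible node per community, 8 subjects, windows stepping by 5 frames
spec <- sim_spec(n_nodes = 20, n_communities = 4,
                 community_sizes = rep(5L, 4), n_frames = 1200,
                 flexible_nodes = c(1L, 6L, 11L, 16L), seed = 7)
cfg <- run_config(sim = spec, n_subjects = 8, n_init = 20,
                  step_frames = 5, seed = 7)
run <- run_pipeline(cfg)

print(run$reference)
#> <partition> 20 nodes in 4 communities, Q* = 0.3529
head(run$node_table[, c("subject", "node_id", "community",
                        "flexibility", "diversity", "centrality")], 5)
#>   subject node_id community flexibility diversity centrality
#> 1  sub001    n001         1   0.7073171 0.9258458 -1.7879145
#> 2  sub001    n002         2   0.4288194 0.8111176  0.7833495
#> 3  sub001    n003         2   0.4250657 0.8085580 -0.2611165
#> 4  sub001    n004         2   0.4317984 0.8187185 -1.3055824
#> 5  sub001    n005         2   0.4238179 0.8111210  0.7833495
run$cluster$nodes
#> [1] "n001" "n006" "n011" "n016"
```

The high-flexibility cluster recovers exactly the four planted flexible
nodes, whose flexibility (0.71 for `n001`) stands well apart from their
stable neighbors (≈ 0.43).

```r
# behavioral association at a planted coupling of 0.45 (60 subjects)
set.seed(1)
brain <- rnorm(60)
behavior <- simulate_behavior(behavior_spec(coupling_r = 0.45, seed = 2),
                              brain)
res <- permutation_p(brain, behavior, k = 4, n_perm = 1999, seed = 3)
print(res)
#> <cca_result> held-out Spearman rho = 0.384, permutation p = 0.007 (1999 permutations)
```

The whole example runs in about 10 seconds.

## Analysis workflow

Numbered drivers under `analysis/` run the full study-sized workflow over
the package, writing tables under `results/`:

- `01_simulate.R` — synthetic cohort (20 subjects, two sessions) + atlas
- `02_preprocess.R` — frame discard and 0.008 Hz high-pass
- `03_connectivity_communities.R` — static + windowed connectivity,
  reference partition, per-subject co-occurrence matrices
- `04_metrics.R` — node metrics, network aggregation, high-flex cluster
- `05_null_models.R` — phase-randomization ablation, structure tests
- `06_behavior_cca.R` — cross-validated CCA with permutation inference
- `07_compare_sessions.R` — twin-session replication

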
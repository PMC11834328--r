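# retscn

Structural covariance network (SCN) analysis of macular retinal layer
thickness, for researchers studying how the retina's laminar architecture
reorganizes in early (pre-clinical) diabetic retinal disease.

Optical coherence tomography reports the thickness of seven retinal layers
(RNFL, GCL, IPL, INL, OPL, ONL, RPE) in the nine sectors of the ETDRS
macular grid. Across a cohort, the correlation of these 63 regional
measurements defines a group-level graph — a structural covariance network —
whose community structure summarizes which retinal regions thicken and thin
together. `retscn` implements the full analysis chain:

1. **Cohort model** — eye-level tables (CSV/TSV, `LAYER_SECTOR` columns),
   ring averages (`Avg_I`, `Avg_O`) and configurable composite layers
   (IR/OR/TRT).
2. **Network construction** — per-node least-squares residualization on age
   followed by Pearson correlation (equivalently, first-order partial
   correlation given age), absolute value, zero diagonal:
   `w_ij = |corr(resid_i, resid_j)|`.
3. **Community detection** — weighted Newman–Girvan modularity with
   resolution parameter γ,

   Q = (1/2m) Σ_ij (A_ij − γ k_i k_j / 2m) δ(c_i, c_j),

   maximized by a from-scratch two-phase Louvain optimizer; 50 seeded runs
   per network, label alignment to the best run, per-node mode as the
   consensus partition ("mode of Ci"), mean Q as the group's modularity.
4. **Group comparison** — Welch t-test on the run-level Q values of the two
   groups (healthy controls, HC, versus diabetics without retinopathy,
   DWOR).
5. **Age trajectories** — per layer × region least-squares regressions of
   thickness on age in each group, Fisher r-to-z comparison of the
   age correlations between groups, Benjamini–Hochberg FDR over the family.
6. **Synthetic cohorts** — a generator with planted block-covariance
   structure (5 blocks in the HC-like group, 4 tighter blocks in the
   DWOR-like group), group mean offsets and linear age effects, so every
   stage is testable end to end without patient data.

## Worked example

```r
library(retscn)

res <- run_pipeline(run_config(seed = 1, out_dir = "runs/demo"))
print(res)
```

```
Retinal covariance-network pipeline run
  seed 1, gamma 1.00, 50 Louvain runs per group
  HC: mean Q 0.1042, 5 consensus communities, negative fraction 0.000
  DWOR: mean Q 0.2903, 4 consensus communities, negative fraction 0.024
  modularity comparison: t = -Inf, p = 0
  trajectories: 110 tests, 0 with q < 0.05
```

Reading the output: the HC-like network splits into 5 communities and the
DWOR-like network into 4 with markedly higher modularity — the planted
"more homogeneous, more modular" diabetic covariance structure is
recovered. (At this seed every Louvain run converged to the same partition
within each group, so the two Q samples have zero variance and the Welch
test degenerates to t = ±Inf, p = 0; with run-to-run variability a finite
t and a small p are reported instead.)
`negative fraction` is the share of negative correlations observed before
taking absolute values — a data-quality indicator that should stay below
5%. All intermediates (cohort CSV, SCN TSVs with JSON sidecars, per-run Q
tables, consensus partitions, trajectory table, report JSON) are persisted
in `runs/demo/`.

Individual stages are available as functions (`generate_cohort`,
`build_scn`, `run_ensemble`, `compare_modularity`, `trajectory_report`,
...) and as subcommands of the thin CLI wrapper in `inst/cli/retscn.R`.

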
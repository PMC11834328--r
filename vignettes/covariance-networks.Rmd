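---
title: "Structural covariance networks of retinal layer thickness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks of retinal layer thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retscn)
```

## The analysis

Macular OCT segmentations report the thickness of seven retinal layers
(RNFL, GCL, IPL, INL, OPL, ONL, RPE) in the nine ETDRS sectors — the central
subfield, four inner-ring sectors at 1–3 mm from the fovea and four
outer-ring sectors at 3–6 mm. Treating each (layer, sector) measurement as
a node, the cross-eye correlation of these 63 regional thicknesses defines
a group-level structural covariance network (SCN). Its community structure —
groups of regions whose thickness co-varies — provides a systems-level view
of how laminar architecture organizes, and how that organization changes in
diabetics before any retinopathy is clinically visible.

`retscn` builds the two group networks (healthy controls, HC; diabetics
without retinopathy, DWOR), detects their communities by modularity
maximization with a run-consensus, compares modularity between groups, and
runs the age-trajectory arm (per-region regressions of thickness on age,
compared across groups). Because no eye-level clinical dataset is publicly
deposited for this design, the package ships a synthetic-cohort generator
that reproduces the *statistical structure* the analysis assumes, making
every stage testable end to end.

## Network construction

For each group separately, each node's thickness vector across the group's
eyes is residualized on age by ordinary least squares (intercept included),
and the edge weight is the absolute Pearson correlation of the residuals:

$$ w_{ij} \;=\; \bigl| \operatorname{corr}(r_i, r_j) \bigr|, \qquad
   r_v = t_v - \hat\alpha_v - \hat\beta_v \,\mathrm{age}. $$

Residualizing both variables on a single shared covariate is algebraically
identical to the textbook first-order partial correlation
$r_{ij\cdot a} = (r_{ij} - r_{ia} r_{ja}) / \sqrt{(1-r_{ia}^2)(1-r_{ja}^2)}$;
the test suite asserts this equivalence to $10^{-10}$. Since the mechanism
behind "age as a covariate" admits several readings, this equivalence means
the standard ones coincide here.

Negative correlations are **kept in absolute value**, never zeroed: a
negative covariance still carries structural information even though the
meaning of its sign in a covariance graph is unclear. The share of negative
off-diagonal pairs is recorded as `negative_fraction` before the absolute
value is taken, and a warning is raised when it reaches 5% — in healthy
covariance data negatives should be rare. The matrices stay dense (63
nodes); no thresholding or sparsification is applied.

Eyes are the sampling unit, so fellow eyes of one subject enter as two
observations. This mirrors the design the cohort sizes imply (156 and 78
eyes from half as many subjects), but it does overstate the effective
sample size; `average_eyes()` collapses to one record per subject as a
sensitivity analysis, off by default.

## Modularity and the Louvain ensemble

Communities are found by maximizing weighted Newman–Girvan modularity with
a resolution parameter $\gamma$ (default 1):

$$ Q \;=\; \frac{1}{2m} \sum_{ij}
   \Bigl( A_{ij} - \gamma \frac{k_i k_j}{2m} \Bigr)\,
   \delta(c_i, c_j), $$

with node strengths $k_i = \sum_j A_{ij}$ and $2m = \sum_{ij} A_{ij}$, in
the doubled-sum convention (both orientations of each edge counted) so that
$Q$ values are comparable across implementations. The general multilayer
form of this quality function adds an inter-layer coupling term; with a
single covariance matrix per group that coupling has no second layer to
act on, so the single-layer form above is the exact specialization used.

The optimizer is a from-scratch two-phase Louvain: repeated single-node
moves to the neighboring community with the largest positive gain
(gain $> 10^{-12}$, to avoid floating-point livelock), then aggregation of
communities into super-nodes, iterated to a fixed point. The node sweep
order is randomized from a seed that fully determines the run; equal-gain
ties resolve deterministically (lowest community id among the maxima). On
graphs of up to 10 nodes an exhaustive search over all set partitions
(`brute_force_optimal`) serves as the oracle; on 100 random 7-node graphs,
the best of 50 seeded runs matches the exhaustive optimum within $10^{-9}$
in at least 95 cases (it is a heuristic, so occasional misses on
adversarial weights are expected and tolerated).

Louvain is stochastic, so each group's network is analyzed as an ensemble
of 50 runs. Community ids are arbitrary per run; to make the per-node
"mode of assignments" well defined, every run is first relabeled to
maximally overlap the highest-Q run (optimal assignment on the k×k
contingency table — exhaustive for k ≤ 8, greedy beyond). The consensus
assigns each node its most frequent aligned id, breaking ties toward the
best run's id (and toward the smallest tied id otherwise) for determinism.
The group's modularity is the arithmetic mean of the run-level Q values.

Modularity is compared between groups by a two-sample t-test on the two
sets of 50 run-level Q values (Welch by default; pooled via
`var_equal = TRUE`). Two caveats are deliberate: run-level Q values are
algorithm restarts, not data resamples, so the p-value quantifies
optimizer variability rather than sampling uncertainty — it is reproduced
because it is the analysis this pipeline implements, and it should be read
with that caveat. When every run converges to the same partition in both
groups the test degenerates (t = 0, p = 1 if the means agree; t = ±Inf,
p = 0 otherwise).

## Age trajectories

For every layer × region (9 sectors plus the two ring averages; 7 primary
plus 3 composite layers, 110 tests by default), thickness is regressed on
age within each group by least squares. The between-group comparison uses
Fisher's r-to-z transform on the per-group age–thickness correlations,

$$ z = \frac{\operatorname{atanh}(r_1) - \operatorname{atanh}(r_2)}
            {\sqrt{1/(n_1-3) + 1/(n_2-3)}}, $$

with the per-group eye counts as $n$ — the correlation-based reading of a
"slope comparison", which is what the transform actually tests. A direct
normal-theory test on the slope difference is available behind
`slope_test = TRUE` as a sensitivity analysis. Benjamini–Hochberg FDR is
applied over the whole family of comparisons as a single family (the
family boundary is configurable; nothing in the design dictates it).

## The synthetic generator

`generate_cohort()` draws, for each eye in group $g$ with age $a$ drawn
from the group's truncated normal age model (minimum 18 years, by
rejection),

$$ t_v = \mu_v + \delta_{gv} + \beta_{gv}\,(a - \bar a_g)
  + \sigma\bigl( \sqrt{\rho_b}\, G + \sqrt{\rho_w - \rho_b}\, F_{b(v)}
  + \sqrt{1-\rho_w}\, \varepsilon_v \bigr), $$

with a global factor $G$, one latent factor $F_b$ per planted block and
unit noise $\varepsilon_v$, all iid standard normal per eye. This
latent-factor construction (rather than an explicit 63×63 covariance) is
positive semi-definite by construction and gives direct control of the
age-residualized correlations: $\rho_w$ within a block, $\rho_b$ between
blocks.

Defaults encode the study conditions: 156 HC-like and 78 DWOR-like eyes;
ages N(46.06, 13.06²) and N(50.8, 8.6²); 5 planted blocks with
$\rho_w = 0.5$ for HC and 4 blocks with $\rho_w = 0.7$ for DWOR — the
tighter, coarser diabetic structure makes the planted DWOR network more
modular, the direction of effect under study. Design choices made where
the design was genuinely open:

* **Background correlation** $\rho_b = 0.25$ for both groups. Regional
  retinal thicknesses share strong global covariance, and the observable
  consequence — negative sample correlations in fewer than 5% of node
  pairs — pins the scale: the expected negative share is
  $\Phi(-\operatorname{atanh}(\rho_b)\sqrt{n-3})$, which at the group
  sizes here is ≈ 0.1% (n = 156) and ≈ 1.4% (n = 78). A background of 0.1
  would instead force 11–19% negative edges, contradicting that
  observation.
* **Block layout.** Only the block *counts* are dictated; membership is
  contiguous near-equal blocks in layer-major node order (13/13/13/12/12
  and 16/16/16/15), so blocks span anatomically adjacent nodes while
  staying balanced enough to be recoverable at γ = 1.
* **Noise scale** $\sigma = 2.4\,\mu m$ (the total age-residual SD per
  node), anchored to the central-subfield RNFL standard deviations
  (2.48/2.23 µm), the only single-sector SDs available to anchor to.
  Correlations are scale-free in $\sigma$; it matters only for
  mean-difference power.
* **Baselines and effects.** RNFL_C baseline 10.16 µm with a +0.69 µm DWOR
  offset; +1.0 µm DWOR offset on the INL inner ring; thinner DWOR outer
  retina via ONL offsets; small HC age slopes (0.02–0.07 µm/year)
  concentrated in the central subfield, GCL/IPL ring thinning, RPE
  inner-ring thickening, and a nearly flat DWOR profile. Remaining
  baselines are plausible normative values, documented as placeholders —
  the generator emulates covariance structure, not a normative database.
* **Positivity.** Thickness is floored at 0.5 µm; at the default scales
  this triggers only in ≈ 4σ tails and does not measurably distort the
  correlations.

What the generator does **not** emulate: inter-eye correlation within
subjects, spatial autocorrelation beyond the planted blocks, missing data,
device segmentation error, and non-Gaussian tails. Passing tests therefore
demonstrate that the pipeline recovers the structure it assumes, at the
stated sample sizes — not that clinical data satisfy those assumptions.

## Numerical and testing choices

* All randomness flows from one master seed through named substreams
  (generator, per-group ensembles); a pipeline run is reproducible byte
  for byte, and per-run Louvain seeds keep every restart independently
  replayable.
* Planted-structure recovery is asserted over 20 replicates at the default
  conditions: consensus community counts equal the planted 5/4 in at least
  90% of replicates, and the DWOR-like network's mean Q exceeds the
  HC-like network's with Welch p < 0.05 in at least 18 of 20. With n = 78
  eyes the DWOR sample correlation matrix occasionally favors a coarser
  merge than the planted blocks (the optimizer is then *correctly*
  reporting a different optimum), which is why the bound is 90% rather
  than 100%.
* False-discovery control of the trajectory report is verified on null
  cohorts (no offsets, no slopes; block covariance retained) over 200
  replicates: since every discovery is false under the null, the empirical
  FDR is the fraction of replicates reporting anything at q < 0.05, and
  must stay within Monte-Carlo error of the nominal 0.05.
* Problem sizes in the routine test suite are deliberately modest — 63-node
  networks, 7-node oracle graphs (877 partitions each), 20-replicate
  recovery and 200-replicate FDR simulations — chosen so the full suite
  exercises every guarantee in a few minutes on a single core.
* Degenerate inputs have defined behavior: constant ages fall back to
  mean-centering with a warning; a zero-variance node is an error naming
  the node; an empty-weight graph is an undefined-modularity error; BH
  adjustment rejects p-values outside [0, 1].

## Limitations

The run-level t-test inherits the interpretational caveat above. The
composite-layer boundaries (IR/OR) are a configurable scheme because the
anatomical boundaries behind published composite thicknesses are not
standardized across devices; results for composites should be read
relative to the scheme recorded in the run report. Reported z-values for
correlation differences use eye-level n, which overstates independence for
fellow eyes; the per-subject averaging mode quantifies the sensitivity.
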
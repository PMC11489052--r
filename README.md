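# cohortpbn

Cohort-specific probabilistic Boolean network (PBN) analysis for molecular
pathway models. `cohortpbn` is aimed at systems-biology and biomedical-data
analysts who want to ask: *given cohort-level expression differences between
patient subgroups, how do the dynamics of a disease pathway model differ
between those subgroups — and how does a comorbidity perturbation change
them?*

The package implements the full analysis chain:

1. **Cohort statistics.** From a two-group miRNA count matrix it computes
   median-of-ratios–normalized log2 fold changes, per-miRNA paired t-tests
   with Benjamini–Hochberg FDR control, Cohen's *d*, and the
   common-language effect size
   `CL = Φ(d / √2)` — the probability that a random case observation
   exceeds a random control observation under the two-independent-normals
   model. Target assignments are filtered by experimental evidence level,
   cross-database consensus, tissue expression and literature-reported
   direction.
2. **Parameterization.** Each pathway node targeted by a retained miRNA
   receives that miRNA's CL as its ON-probability at step 0; comorbidity
   differential-expression tables become permanent point mutations
   (knockout = pinned to 0, overexpression = pinned to 1).
3. **Simulation.** A compiled asynchronous Monte-Carlo engine runs the PBN:
   each repetition samples a random initial state, then repeatedly flips
   one uniformly chosen node whose Boolean rule disagrees with its current
   value (fixed points persist). The per-step ON-probability of every node
   is estimated across repetitions (defaults: 100 steps, 1000 repetitions).
   An exact jump-chain oracle and attractor enumeration (terminal strongly
   connected components) are available for networks with ≤ 12 free nodes.
4. **Stratification.** Endpoint trajectories are split into early/mid/late
   stages and compared across conditions by dynamic time warping
   (`D[i,j] = |a_i − b_j| + min(D[i−1,j−1], D[i−1,j], D[i,j−1])`); Pearson
   correlation of DTW score profiles flags condition pairs with highly
   similar endpoint dynamics (r ≥ 0.98). Piecewise-linear change-point
   regression (BIC-selected) localizes trend shifts in trajectories.

Boolean models are read and written as BoolNet-style `.bnet` rule files and
a strict Boolean subset of SBML-qual; networks export to SIF and can be
structurally verified against a signed-interaction reference table. A
seeded synthetic-data module generates every input the pipeline needs —
multi-cohort negative-binomial count matrices with planted standardized
effects, interaction/evidence tables, literature directions, DEG tables and
a catalogue of toy networks — so the whole analysis runs end-to-end without
any external data.

## Worked example

A complete small analysis — synthesize a cohort, profile it, parameterize a
mitophagy-pathway-shaped model, add a comorbidity knockout set, simulate,
and score staged DTW against an unparameterized baseline:

```r
library(cohortpbn)

sc      <- synthetic_scenario(seed = 42, cohort_sizes = c(clinical = 80, swedd = 80))
profile <- cohort_profile(gen_counts(sc)$swedd)
head(dplyr::arrange(profile, q_value), 3)
#>   mirna   log2fc  p_value  q_value cohens_d    cl mean_case mean_control
#> 1 mir-020  0.525 4.72e-19 2.36e-16     1.22 0.806      294.         204.
#> 2 mir-012  0.564 2.12e-18 5.29e-16     1.44 0.846      294.         199.
#> 3 mir-016  0.605 3.44e-18 5.73e-16     1.49 0.853      287.         188.
```

The planted miRNAs (standardized effect d = 1.2, i.e. CL ≈ 0.80) surface
with q-values far below 0.05 and CL estimates near 0.8. Filtering targets
and assigning CLs to model nodes:

```r
tabs    <- gen_interactions(sc)
de      <- profile$mirna[!is.na(profile$q_value) & profile$q_value <= 0.05]
kept    <- filter_mirna_targets(tabs$primary, tabs$secondary, tabs$tissue_genes, de)
net     <- gen_toy_network("prkn_shape")
spec    <- build_initial_spec(net, profile_targets(profile, kept))
round(spec$probabilities, 4)
#>   BAG4   BCL2  BNIP3  FBXW7   SNCA TIMM17A   ULK1
#> 0.7784 0.7571 0.8248 0.7273 0.7349  0.8248 0.7349

forced <- deg_to_forced(net, gen_deg_table(sc))   # SNCA, BCL2, BNIP3 knockouts
cond   <- merge_parameterizations(spec, forced, "swedd", "T2DM")
traj   <- simulate_condition(net, cond, n_steps = 100, n_reps = 1000, seed = 7)
base   <- simulate_ensemble(net, 0.5, NULL, 100, 1000, seed = 7, label = "baseline")
stage_dtw_table(list(baseline = base, `swedd+T2DM` = traj),
                reference = "baseline",
                endpoints = identify_terminals(net)$outputs)
#>    endpoint           condition  stage   dtw
#>  1 Apoptosis          swedd+T2DM early 7.17
#>  2 Mitophagy          swedd+T2DM early 0.615
#>  ...
#>  9 Apoptosis          swedd+T2DM late  8.68
```

Low DTW scores (Mitophagy, PRKN_ubiquitinated) mean the condition's
endpoint dynamics track the baseline closely; the large Apoptosis score
reflects the knockout-driven divergence (BCL2 pinned off removes the
apoptosis brake). `run_pipeline(pipeline_config(...), outdir = "run/")`
executes the same chain for every cohort plus comorbidity twins and writes
profiles, conditions, trajectories, DTW and correlation tables with a
digest manifest; re-running a config reproduces byte-identical outputs.

Plots: `autoplot()` on trajectory ensembles, DTW tables and change-point
fits; `plot_cohort_profile()` for volcano-style profile views; `tidy()` /
`glance()` on networks, trajectories, change-point fits and verification
reports.

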
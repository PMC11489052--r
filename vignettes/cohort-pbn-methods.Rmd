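---
title: "Cohort-specific probabilistic Boolean network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-specific probabilistic Boolean network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortpbn)
```

# The problem

Patient cohorts defined by clinical criteria — for instance subgroups of a
neurodegenerative disease distinguished by imaging and symptom profiles —
often differ in the expression of regulatory molecules such as miRNAs. A
static differential-expression table, however, says little about how those
differences play out in the *dynamics* of the pathways the miRNAs regulate.
`cohortpbn` closes that gap: it converts cohort-level expression statistics
into parameters of a probabilistic Boolean network (PBN) model of a pathway,
simulates each cohort's model stochastically, optionally superimposes a
comorbidity as permanent point mutations, and quantifies how the phenotype
endpoints (output nodes such as apoptosis or mitophagy readouts) diverge
between cohorts over simulated time.

# The model

## Boolean networks and the asynchronous jump chain

A Boolean network assigns every biomolecule a binary state and one update
rule over the other nodes using NOT/AND/OR. We simulate the *asynchronous*
stochastic semantics: from state $s$, let $U(s)$ be the set of non-forced
nodes whose rule output disagrees with their current value. One node of
$U(s)$ is chosen uniformly at random and flipped; if $U(s)$ is empty, $s$
is a fixed point and persists. This is the embedded jump chain of the
continuous-time Markov process with unit transition rates: with equal
rates, the CTMC's jump skeleton chooses uniformly among enabled
transitions, and reporting per-step trajectories matches the discrete
"one biomolecule per iteration step" convention. We deliberately do not
implement rate-heterogeneous CTMC simulation or synchronous updating.

Fixed points persist (self-loop) rather than terminating a repetition, so
all repetitions share a common step axis and per-step ensemble frequencies
are well defined.

The probabilistic part enters through the initial state: each node is ON at
step 0 independently with a specified probability. `simulate_ensemble()`
estimates $P(\text{node } v \text{ ON at step } t)$ as the fraction of
repetitions with $v$ ON at $t$.

## Exact oracle and attractors

For networks with at most 12 non-forced nodes, `exact_state_distribution()`
builds the jump chain's transition matrix over the enumerated state space
and propagates the exact product-Bernoulli initial distribution; it is the
reference against which the Monte-Carlo engine is tested (agreement within
a four-standard-error band plus 0.004 at 20,000 repetitions).
`enumerate_attractors()` returns the terminal strongly connected components
of the asynchronous transition digraph; singletons with empty update sets
are fixed points, larger components complex attractors. The test suite
checks this against an independent transitive-closure brute force.

## Cohort parameterization

For each cohort (cases) versus the clinical reference (controls):

* counts are normalized by median-of-ratios size factors (geometric-mean
  reference over features with all-positive counts) — implemented directly
  so the package is self-contained;
* log2 fold change is descriptive:
  $\log_2\!\big(\tfrac{\bar{x}_{\text{case}} + c}{\bar{x}_{\text{ctrl}} + c}\big)$
  with pseudocount $c = 0.5$;
* significance comes from the per-feature paired t-test on
  log2-normalized counts with Benjamini–Hochberg FDR control (a Welch
  fallback is used when pairing metadata is absent). We intentionally do
  not re-implement negative-binomial Wald machinery; the paired-t path is
  the significance route, a deliberate simplification;
* the standardized effect is Cohen's $d$ with $(n-1)$-weighted pooled SD,
  converted to the common-language effect size
  $CL = \Phi(d/\sqrt{2})$ (two-independent-normals form). The one-sample
  variant $\Phi(d)$ exists behind `cl_variant = "one_sample"` because the
  literature sometimes means that form; the two-group form is the default
  since the design is a two-group comparison. `cl_empirical()` provides the
  distribution-free probability of superiority as a cross-check.

Target assignments pass an evidence filter (strongest experimental evidence
level in the primary database, or at least two supporting studies in a
secondary one; optionally cross-table consensus), a tissue-expression
filter, and a literature-direction screen: miRNAs whose fold-change sign
contradicts the reported direction are flagged and excluded from
parameterization.

`build_initial_spec()` then assigns each targeted node its miRNA's CL as
the ON-probability at step 0. **Design choice:** CL is assigned *directly*
by default, because the parameter tables this workflow produces list CL
values as the node parameters verbatim; the biologically motivated
alternative — high miRNA activity represses the target, suggesting
$1 - CL$ — is available as `invert_repression = TRUE`. When several miRNAs
target one node the default combination is the mean (max and min
available); nothing in the workflow's conventions dictates a rule, and the
mean is the neutral choice. Untargeted nodes get `default_p = 0.5`
(maximum entropy).

## Comorbidity point mutations

A differential-expression table of a comorbidity maps to a forced-node
set: downregulated genes are knocked out (pinned to 0), upregulated genes
overexpressed (pinned to 1). Forced nodes are set at initialization and
excluded from the update set for the entire walk — permanent changes, not
transient perturbations. In a merged condition the forced value takes
precedence over any initial probability.

## Staged DTW stratification

Each endpoint's trajectory is split into contiguous stages — equal thirds
labelled early/mid/late by default, remainder to the last stage; detected
change points may replace the equal split. Dynamic time warping with local
cost $|a_i - b_j|$ and step pattern {match, insert, delete},
boundary-aligned, scores each condition's stage sub-series against a
comparator; lower is more similar. **Design choice:** the source workflow
computes per-condition scores but never names the comparator, so both
interpretations are implemented — a named reference condition (the
pipeline uses an unparameterized *baseline*: all initial probabilities 0.5,
no forced nodes) and an all-pairs mode (`reference = "pairwise"`). Neither
is presented as canonical. No warping window is applied by default because
stage sub-series are short (~33 points); a Sakoe–Chiba band is available
for long series.

Pearson correlation of two conditions' DTW score vectors across endpoints
at one stage flags *highly similar* pairs at $r \ge 0.98$ — the threshold
mirrors the "98–100%" convention for calling strong correlation; how that
threshold should interact with stage pooling is unspecified upstream, so
the package reports per-stage correlations and leaves pooling to the user.

## Change-point detection

`detect_change_points()` fits piecewise-linear least squares with
$0..k_{\max}$ breakpoints by exact dynamic programming (O(1) segment RSS
from cumulative sums) and selects the segment count by BIC with
$2m + (m-1)$ parameters for $m$ segments. This deterministic, desk-scale
construction approximates Bayesian multiple-change-point regression while
remaining exactly testable; posterior sampling is out of scope. Minimum
segment length is 3 points to keep the per-segment fit identified.

# Simulation parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n_steps` | 100 | iteration steps per repetition; the standard operating point |
| `n_reps` | 1000 | repetitions per ensemble; a 100-repetition preset is the lighter figure-style variant (both conventions are in circulation; neither is assumed canonical) |
| `seed` | — | master seed; per-repetition streams are derived by a SplitMix64 counter scheme, so results are platform-independent and growing `n_reps` never reshuffles earlier repetitions |
| `default_p` | 0.5 | ON-probability of unparameterized nodes (maximum entropy) |
| `fdr_level` | 0.05 | q-value threshold for calling a miRNA differentially expressed |
| `correlation_threshold` | 0.98 | high-similarity flag on DTW profile correlation |
| `n_stages` | 3 | early/mid/late split |
| `max_breaks` | 3 | change-point model order cap |

# The synthetic-data generator

The generator emulates the structure of a multi-cohort whole-blood miRNA
study so every stage of the pipeline is testable without access-controlled
data. Its defaults are the study conditions: four cohorts (clinical
reference n = 1430, prodromal n = 223, SWEDD n = 187, parkinsonism n = 81);
500 miRNAs (the order of distinct miRNAs such an assay detects);
negative-binomial counts with baseline mean 200 and dispersion 0.05;
log-normal per-sample size factors (sd 0.15); a paired design in which each
case shares a log2-scale subject effect (sd 0.25) with its matched control;
planted standardized effects d = +1.2 in 20 miRNAs per case cohort
(positive, so planted CLs fall in the 0.57–0.98 range the parameter tables
exhibit); evidence tables with 70% strongest-level pairs and 70%
multi-study pairs, 80% tissue overlap, 80% literature agreement; and a
comorbidity DEG plan of three knockouts (SNCA, BCL2, BNIP3).

Effects are *realized*, not merely injected: the case log2-mean shift is
calibrated so that Cohen's d measured on log2-normalized counts equals the
planted value, using the exact NB log2-standard deviation (computed by
summing the pmf — the delta-method approximation is visibly biased at
these means) plus the subject-effect variance. One caveat is documented
rather than corrected: when a large *fraction* of features is planted in
one direction, median-of-ratios size factors absorb part of the shift
(composition bias) and measured effects attenuate; at the default planted
fraction (20/500) this is negligible.

What the generator does **not** emulate: real miRNA sequence biology or
target specificity, zero inflation and dropout, batch effects, outlier
samples, correlated miRNA co-regulation, and — most importantly — the real
Boolean rules of curated pathway models, which are not published as rule
files. The `prkn_shape` fixture reproduces only the *interface* of a
mitophagy pathway model (its seven canonical regulator inputs and four
phenotype outputs, with comorbidity-perturbable internal nodes) over
synthetic internal logic. Passing tests therefore demonstrate that the
machinery is correct and calibrated under its stated statistical model,
not that any biological conclusion transfers to real cohort data.

# Numerical choices and degenerate inputs

* Exact-oracle and attractor methods refuse networks with more than 12
  non-forced nodes (4096 states) instead of silently degrading.
* Exact marginals are clamped to $[0,1]$ to absorb sparse-arithmetic
  round-off.
* Per-feature degeneracies (zero-variance paired differences, zero pooled
  variance) are flagged `NA` in profiles rather than aborting the cohort.
* Size-factor estimation errors out on matrices with no all-positive
  feature (no reference exists).
* Rule parsing is case-preserving and does **no** identifier
  normalization: gene/node naming discrepancies between data sources must
  surface in mapping reports (`build_initial_spec()` reports unmatched
  genes; `deg_to_forced()` reports genes absent from the model) rather
  than be papered over.
* SBML-qual support is a strict Boolean subset (max level 1;
  and/or/not and threshold-to-1 comparisons). Anything else — multi-level
  species, arithmetic MathML — fails loudly with the construct named.
* Mixed-sign regulators (a node appearing both plain and negated in one
  rule) produce two SIF rows rather than an "unknown" sign.
* DTW of a condition with itself is exactly 0; zero-variance DTW profiles
  give an undefined correlation, flagged rather than coerced.

# Verification scale

The test suite and `scripts/acceptance.R` exercise the package at the
scale it documents: 50 seeded random networks (≤ 8 nodes) × 20,000
repetitions against the exact oracle at steps {1, 5, 25, 50}; 100 networks
for attractor agreement; 10,000-sample empirical CL checks at
d ∈ {0, 0.5, 1, 2}; 500 replicates of planted-d recovery; 2,000 null
features for type-I error; exhaustive DTW enumeration for all series pairs
of length ≤ 5; 200 seeded change-point runs; and an end-to-end synthetic
run at 80 samples per group. These sizes were chosen so the whole
verification runs comfortably on a single CPU while keeping every
statistical bound sharp enough to be meaningful.

# Known limitations

* The paired t-test on log2-normalized counts is an approximation for
  small counts; the package targets moderately expressed features (the
  generator's baseline mean is 200).
* Attractor enumeration is exact only up to 12 free nodes; beyond that,
  Monte-Carlo exploration is the only option and complex attractors are
  not enumerated.
* Stage-wise DTW discards cross-stage warping: an alignment cannot cross a
  stage boundary, which is the point of staging but can split a single
  slow transition across two stages.
* The change-point selector assumes roughly homoscedastic noise; strongly
  step-dependent ensemble noise (early steps of a 100-repetition ensemble)
  can bias the BIC toward extra segments.
* `run_pipeline()` currently drives the synthetic generator; file-based
  inputs are supported through the reader functions
  (`read_counts_matrix()`, `read_sample_sheet()`,
  `read_interaction_table()`, `read_deg_table()`, `read_bnet()`,
  `parse_sbml_qual()`) and the same stage functions, composed manually as
  in the README's worked example.

# A minimal run

```{r example, eval = FALSE}
res <- run_pipeline(pipeline_config(
  seed = 1,
  scenario = list(cohort_sizes = c(clinical = 60, swedd = 60,
                                   prodromal = 60), n_mirna = 200),
  n_steps = 100, n_reps = 1000
), outdir = "run1")

res$dtw            # staged DTW table across conditions
res$correlations   # per-pair, per-stage Pearson r with similarity flags
autoplot(res$trajectories[["swedd+T2DM"]])
```
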
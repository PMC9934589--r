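---
title: "Methods: task scoring, context extraction, and comparison statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task scoring, context extraction, and comparison statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidegem)
```

This vignette is the package's account of its models and numerical choices:
what each stage assumes, which parameters matter and why their defaults are
what they are, what the synthetic generators do and do not emulate, and
where the design was genuinely open.

## The model container and solver

A `metabolic_model` holds metabolites, reactions (stoichiometry, finite flux
bounds in mmol/gDW/h, subsystem label), GPR rule trees, and one objective
reaction. I/O supports SBML Level 3 with the `fbc` package (GPRs as
`geneProductAssociation`, bounds as parameters, subsystems via the `groups`
extension, conventional `M_`/`R_`/`G_` prefixes) and a flat JSON dialect
mirroring the container fields, used for fixtures and pipeline outputs.

All flux analyses go through one internal linear-programming contract:
build, set sense, solve, query the primal. The backend is a dense two-phase
primal simplex written for this package (Dantzig pricing, Bland anti-cycling
fallback, pivot tolerance 1e-9). Two considerations drove this choice: toy
models stay below a few hundred variables, where a dense tableau is fast and
easy to audit; and the contract keeps the backend swappable for a sparse
solver at reconstruction scale. Every optimal flux vector is asserted
against steady state at 1e-6 max-norm. The test suite checks the solver
against a brute-force enumeration of basic feasible solutions on random toy
problems, and the weighted flux-sum minimizer against an independent LP with
a different variable encoding (explicit `t >= |v|` rows instead of split
forward/reverse variables).

Reversible reactions enter the flux-sum objective as split nonnegative
halves sharing the reaction's weight, so "sum of fluxes" always means
`sum w_r |v_r|`.

## GPR rules

The grammar is `and`-over-`or` precedence with case-insensitive keywords and
parentheses; gene tokens are maximal runs of non-space, non-parenthesis
characters, matching SBML `fbc` conventions. Numeric evaluation takes the
maximum over `or` children (isozymes: the best available alternative) and
the minimum over `and` children (complexes: the scarcest subunit). The
default missing-gene policy is `skip` — genes absent from a weight or
abundance vector are dropped from their node, and a node with no surviving
children propagates as missing — because expression platforms never cover
every model gene; erroring would make real inputs unusable, and zeroing
would bias complex (`AND`) rules downward.

## TIDEs: permutation task scoring

Weights are per-gene log2 fold changes (male minus female), zeroed where the
Benjamini–Hochberg FDR is at or above 0.1. The male-minus-female sign
convention makes male-biased tasks positive; it is verified end to end by a
planted male-up subsystem producing a positive, significant score.

Reactions with an empty GPR, or whose genes are all missing, are *excluded*
from task scores rather than counted as 0: zero-filling would shrink
transport- and exchange-heavy tasks toward the null, whereas exclusion
scores only evidence-bearing reactions. Skipped tasks are reported.

The null for a task of size `k` draws `k` weights uniformly without
replacement from all weighted reactions outside the task (pool ordered by
reaction id, so results are invariant to reaction and task ordering), 1000
times by default. Empirical tails use the add-one estimator
`(1 + #{null >= score}) / (1 + n_perm)`, which never returns 0. Each tail is
tested at `alpha_per_tail = 0.025` and the doubled smaller tail is reported,
i.e. a two-sided test at 0.05 overall; the method's significance rule
("p < 0.025 because the test is two-sided") is ambiguous between testing
each tail at 0.025 and comparing the doubled p to 0.025 — this package does
the former and records the doubled p so either reading can be applied
downstream.

**Calibration is measured on unfiltered weights.** Under a global null the
FDR filter zeroes every weight; all scores and null scores are then exactly
0 and every p is 1, so the filtered pipeline trivially never rejects and its
"type-I error" is undefined rather than controlled. The calibration test
therefore sets `fdr_threshold = 1` (raw fold changes, exchangeable across
reactions under the null) and observes the significant-task fraction across
200 simulated null datasets; it lands near the nominal 0.05 (inside
[0.02, 0.09]). With the FDR filter on, sparse nonzero weights concentrate
the null pool near zero, which is what gives the method its sensitivity —
and also means a task containing the few surviving genes is easily called;
the false-call rate per non-planted task stays below 10% in the recovery
study.

## Context extraction and flux sampling

Per sample, linear-scale abundances (`2^log2`) are propagated through the
GPRs and converted to weights by *rank*: the highest-abundance reaction gets
0, the lowest 1, ties share their ranks' mean weight, and no-GPR reactions
get the median weight. "Linearly distributed weights between 0 and 1" is
ambiguous between value-linear and rank-linear maps; rank-linear is adopted
because it is invariant to the abundance scale (counts, intensities,
TPM-like units all give the same weights), at the cost of discarding
magnitude information — a recorded interpretation risk.

Pruning minimizes the weighted flux sum subject to the objective holding at
least `min_fraction = 0.40` of the FBA optimum, then removes reactions with
`|v| <= 1e-6` (a tolerance comfortably above LP noise at the 1e-9 pivot
tolerance) and orphaned metabolites, never the objective reaction. Because
the LP itself enforces the fraction, a solved sample always passes the
post-hoc 40% filter up to numerics; in this package exclusions arise from
per-sample failures (e.g. expression that yields no usable abundance). At
reconstruction scale the filter would also catch solver failures and
degenerate samples.

For sampling, reaction directions are fixed to the signs of the parsimonious
solution, the inverted-weight (`w' = 1 - w`) flux sum is maximized on the
directed model, and the polytope `{S v = 0, directed bounds,
v_obj >= min_fraction * Z_pruned}` is sampled by hit-and-run: directions are
standard-normal draws in the null space of `S`, steps are uniform on the
feasible segment, every 100th point is recorded (thinning 100), and the walk
starts from the centroid of three known-feasible vertices (parsimonious,
FBA-optimal, inverted-weight-optimal). How the "constrained flux
distributions" should bound the polytope after the maximization step was an
open design point; this package constrains only the direction fixing and the
objective fraction, referenced to the pruned model's own optimum so the
parsimonious point is always feasible. The default of 110 samples per model
matches the study conditions; uniformity of the sampler is checked exactly
on a one-dimensional polytope, and every recorded sample is verified
feasible to 1e-6.

## Comparison statistics

Presence proportions divide, per reaction and sex, the number of retained
models containing the reaction by the retained-model count of that sex.
"Unique" follows the strict-zero reading — at least 10% prevalence in the
own sex and *zero* presence in the other — with the alternative (allowing a
small other-sex proportion) exposed as `other_max`. Mann–Whitney U tests use
the exact distribution when both sides have at most 20 tie-free values and
the tie-corrected normal approximation otherwise (without continuity
correction, which keeps null p-values closer to uniform at the sample sizes
used here); the statistic and exact p are checked against brute-force pair
counting and exhaustive relabeling. Exchange-flux comparisons pool all flux
samples per sex and let models lacking the reaction contribute zero flux —
absence *is* evidence about import capacity — with dropping exposed as an
option.

The adverse-event stage computes per-quarter, per-sex proportions of
liver-flagged reports (quarters with zero reports for either sex are
dropped with a warning) and compares the two quarterly proportion vectors
with a two-sided Mann–Whitney U test; per-drug female report fractions
exclude drugs below 100,000 total reports by default.

## What the synthetic generators emulate — and what they do not

`build_toy_gem` builds one linear pathway per subsystem, each importing
through its own exchange and feeding a shared currency metabolite consumed
by a biomass-like sink, plus a parallel alternative first step and a
dead-end branch per subsystem (so parsimony pruning always has redundant and
impossible routes to remove), AND/OR GPRs on a configured fraction of
reactions, and optionally a conjugated/deconjugated bile-acid analog pair:
direct cholate-analog import, and glycocholate-analog import followed by a
deconjugation reaction. When the pair is present the objective also consumes
a small amount of the cholate analog, so every context model must use one of
the two entry routes — this is what makes the planted-bounds comparison of
the two importers informative rather than dependent on whether parsimony
happened to keep them. Defaults (12 subsystems, 4-reaction chains, 20%
AND and 20% OR rules) give a task set large enough for calibration studies
while keeping each LP at toy scale.

`simulate_expression` draws a per-gene baseline from Normal(6, 1) on the
log2 scale, shifts male samples of a planted subsystem by the configured
log2 effect on 80% of its genes (partial signal, so recovery is not
trivial), adds Normal(0, 0.25) per-cell noise, and appends a male-marker
gene whose modes are 6 log2 units apart — a clean stand-in for a
male-specific marker, with the gap configurable down to overlapping-mode
regimes. Defaults of 20 samples per sex and noise 0.25 are the study
conditions of the recovery analyses. `simulate_reports` draws, per quarter
and sex, a fixed number of reports with Bernoulli liver-event flags (2%
female vs 1% male by default over 68 quarters of 10,000 reports per sex)
and drug assignments proportional to sex-specific intensities.

The generators deliberately do not emulate: reconstruction-scale networks
(thousands of reactions, compartments, currency-metabolite cycles), real
bile-acid chemistry (the pair is a topological analog only), microarray
probe effects, normalization artifacts, batch structure, or correlated gene
noise. Passing tests therefore demonstrate that the *methods* behave as
specified under their stated statistical models — calibrated type-I error,
recovery of planted effects, feasible and non-vacuous sampling — not that
real tissue data would yield any particular biology.

## Differential expression: a deliberate substitution

Gene-level inference uses a vectorized Welch two-sample t-test with
Benjamini–Hochberg correction rather than an empirical-Bayes moderated test.
The pipeline contract only needs a weight vector with controlled FDR; at the
sample sizes of interest (tens per sex) the Welch test is adequately
powered, and the implementation is checked gene-by-gene against
`stats::t.test` and a hand-computed BH step-up. Degenerate rows where both
groups have zero variance get p = 1 when the means agree (no evidence) and
p = 0 otherwise (certain difference at face value).

Sex imputation calls a sample male above the (1 − 0.16) marker quantile and
female below the 0.16 quantile — roughly one standard deviation either side
of the mean for a unimodal marker — leaving the middle unassigned; it is
invariant under strictly monotone marker transforms, errors on constant
markers, and fails soft (all unassigned, with a warning) when there are
fewer samples than `1/quantile`.

## Problem sizes and determinism

The test suite and the acceptance script run, on one CPU in a few minutes:
200 null pipelines and 50 recovery replicates on the default 12-subsystem
toy model with 1000 permutations; 50 random prune-and-sample checks and 50
bile-pair recovery replicates at 110 flux samples with thinning 100; and 100
calibration plus 100 power replicates of the report-rate test (the
calibration replicates use 2,000 reports per quarter per sex — uniformity of
the null p does not depend on the report count — while the power study keeps
the full 10,000). Every stochastic stage takes an explicit seed; pipeline
stages and per-task/per-sample streams derive theirs from a master seed and
a label, so reruns are reproducible and results do not depend on task,
reaction, or sample ordering.

## Known limitations

- The simplex backend is dense; it is not intended for reconstruction-scale
  models (Human1-class inputs would need a sparse LP backend behind the same
  contract).
- Hit-and-run with thinning 100 is asymptotically uniform but not certified
  mixed for badly conditioned polytopes; the acceptance checks constrain its
  behavior only on toy geometries.
- The FDR-filtered TIDEs test is conservative-to-anticonservative depending
  on weight sparsity (see the calibration note above); the reported doubled
  p and per-tail alpha make the convention explicit.
- No thermodynamic or loopless constraints, no gap-filling, no normalization
  or batch correction: inputs are assumed gene-level, normalized, and
  loop-free enough for flux sampling to be meaningful.
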
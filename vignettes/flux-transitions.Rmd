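---
title: "Modelling metabolic flux shifts across phenotypic transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metabolic flux shifts across phenotypic transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmod)
```

## The problem

Cancer cells that progress through distinct phenotypic stages — for ovarian
cancer lines, adherent monolayers, compact ("moruloid") spheroids, and
cavitated ("blastuloid") spheroids — rewire their metabolism along the way.
`fluxmod` implements a constraint-based pipeline that asks three questions of
stage-wise protein (or gene) expression mapped onto a genome-scale metabolic
model:

1. **Which reactions change flux when the phenotype changes?**
2. **What is the smallest set of reactions whose modulation reverts the
   later-stage flux profile towards the initial stage?**
3. **Which gene knockouts or drug inhibitions achieve such a reversal?**

The machinery is generic constraint-based modelling: steady state
`S v = 0` with bounds `lb <= v <= ub`, flux balance analysis (FBA), flux
variability analysis (FVA), context-specific model extraction and uniform
flux sampling. The package ships its own bounded-variable simplex and
branch-and-bound solver, so no external LP library is required.

## Pipeline model, stage by stage

### Expression preprocessing

The input is an abundance matrix over replicates of ordered stages
(three stages x three replicates in the motivating design). The fixed order
is: drop entities absent everywhere; keep entities observed in at least 50%
of the replicates of at least one stage; impute stage-wise (mean of the
stage's observed replicates where the stage passes the 50% rule, otherwise
the global matrix minimum); merge replicates by their mean; `log10`.
Fold-changes are reported in `log2` with Welch's t-test, the only t-test
flavour used anywhere in the package.

Two rules are deliberate choices where the procedure is ambiguous:

* a stage observed in fewer than half of its replicates is *wholly* replaced
  by the global minimum, including an observed singleton
  (`replace_observed = FALSE` keeps the singleton instead);
* p values are reported raw by default, with Benjamini-Hochberg available
  through `adjust = "BH"`.

### From genes to reactions

Gene-protein-reaction rules are parsed into boolean trees
(`and` = enzyme complex, `or` = isozymes) and evaluated numerically with the
standard min/max mapping. Genes without data are ignored inside an operator
as long as one child is scored; a reaction with no scored leaf has no
expression, a class that the extraction methods below treat specially. The
mapping is monotone: raising a gene's value never lowers a reaction's value.

### Model conditioning

Before extraction the parent model is conditioned: every exchange of a
carbon-bearing metabolite (except CO2 and bicarbonate, recognised by id and
by formula) has its maximum uptake capped at 10 mmol gDW^-1 h^-1; the biomass
reaction is removed; one irreversible sink per growth-essential metabolite is
added (`SK_<metabolite>`); and the flux-consistent subnetwork is taken, i.e.
reactions able to carry at least 1e-6 flux in some steady state. The value
1e-6 is the single global *activity tolerance* used for consistency,
functionality scoring, and the perturbation noise floor.

### Context-specific extraction

Three objective-free extraction methods are implemented, each under two
threshold schemes computed from the reaction expression array (never
hard-coded; the array minimum plays the role of the "lower threshold"
constant reported for a particular data set):

* **iMAT** — a mixed-integer program maximising the number of
  high-expression reactions (>= upper threshold) carrying at least `eps`
  flux plus the number of scored low-expression reactions (< lower
  threshold) carrying none. The returned model contains the reactions active
  in the optimum plus those still activatable under the optimal activity
  pattern (probed by FVA with the binary pattern fixed), pruned to
  consistency. Alternative MILP optima are tie-broken towards fewer active
  reactions, then lexicographically.
* **FASTCORE** — the sparse LP sequence supporting a core set (reactions
  above threshold; reactions without expression are never core).
* **INIT** — weights `5 * log2(expression / threshold)`, -2 for reactions
  without data; a MILP selects the weight-maximal reaction set in which
  every included reaction carries at least `eps` flux simultaneously.

`eps` defaults to 1e-3: comfortably above the activity tolerance, far below
physiological fluxes.

### Flux states

The steady-state polytope is sampled by artificial-centering hit-and-run:
warmup points are the per-reaction FVA optima; directions alternate between
centering moves and per-reaction-range-scaled random directions projected on
the null space of S (the scaling keeps the chain ergodic on strongly
anisotropic polytopes); the default chain keeps every 60th point and returns
`2 x reactions` samples after a 10% burn-in. The *optimal flux state* of a
stage is the sample whose flux magnitudes correlate best (Pearson) with the
stage's reaction expression; ties go to the lowest sample index. Signed-flux
and Spearman variants exist but absolute-flux Pearson is the default.

The *metabolic functionality score* of a model is the number of sink
reactions whose FBA maximum exceeds the activity tolerance. Its significance
is the fraction of same-size random flux-consistent subnetworks of the
parent scoring strictly higher — the strict inequality is kept as defined,
so a maximal model attains p = 0. Random models are drawn by removing
uniformly random reactions and greedily re-adding removed ones until the
size is within 2% of the target (a warning reports draws that cannot reach
it).

### Transitions, modules, interventions

Reactions present in both stage models are *perturbed* when
`max(|v_B|, eps) / max(|v_A|, eps)` crosses 2 in either direction
(inclusive), or the fluxes flip sign with both magnitudes above the noise
floor. The baseline correlation of a transition is the Pearson correlation
of the two states over the perturbed set; subsystem enrichment of the
perturbed set is an upper-tail hypergeometric test in the universe of common
reactions.

The greedy module search clamps perturbed reactions to their initial-stage
flux (negative reference: `(ref, 0)`; positive: `(0, ref)`; zero: `(0, 0)`),
in the order fixed by the single-modulation ranking, keeping a clamp only if
the re-estimated correlation rises by at least 0.001 (internal cut-off) and
iterating levels until a level gains less than 0.01 (external cut-off).
Those two cut-offs are the calibrated defaults of the approach; looser
internal cut-offs demonstrably give larger modules without proportional
correlation gains (a property test reproduces that pattern). One strategy is
launched from each of the top 20 single modulations by default. Each
re-estimation is a fresh sampling run whose seed derives deterministically
from (master seed, strategy, step), so searches are exactly reproducible; a
cheap deterministic LP surrogate (`mode = "project"`, the feasible flux
vector L1-closest to the reference) is available where sampling fidelity is
not needed. Infeasible clamps are skipped and logged, never counted as zero
gain.

Interventions re-use the same evaluation: knockouts re-evaluate GPRs
boolean-wise and zero the bounds of disabled reactions; drugs scale the
bounds of every reaction whose rule *mentions* a target gene by
`1 - inhibition` (membership, not boolean evaluation — partial inhibition
must dampen isozyme-protected reactions too, whereas a knockout must not
silence them). The default 50% inhibition is the plateau of the
inhibition-response curves. Screens report the correlation with the
initial-stage state and its log2 fold-change against the baseline;
correlations are floored at 0.001 before the ratio so the fold-change stays
defined when a baseline is near zero or negative — with such baselines the
`log2FC > 2` filter effectively demands a clearly positive restored
correlation. Gene essentiality on normal-tissue expression uses E-flux
(bounds linearly scaled to the per-sample maximum reaction expression,
`b_max = 1000`; the linear map is this package's choice for the unspecified
scaling), quantile normalisation via `limma`, and classifies a gene
non-essential when its growth-rate ratio is 1 in at least a third of the
usable samples. The IC50 z-score helper uses the population standard
deviation; a strict variance-denominator mode exists for auditing the
occasionally printed sigma^2 form.

## The synthetic scenario and what it does (not) show

`make_scenario()` generates the complete toy study: network, three-stage
replicate expression, drug table, normal-tissue matrix and IC50 table, with
planted ground truth. The network couples a glucose backbone to independent
hub branches:

* glucose consumption runs near saturation (mandatory uptake of at least
  8 of the 10-unit cap), so the backbone is stable across flux states and
  phenotypic contrast concentrates in the branches;
* the *planted module* is four wide-capacity branches sharing a driver gene
  (`g_drv`, in complex with a branch-specific partner); module capacity is
  set so that full activation binds the bounds within the uptake budget;
* decoy branches run at narrow mandatory levels, so they can never cross
  the two-fold rule; reversible members carry their level on a mandatory
  narrow secretion, where reversal is blocked by mass balance;
* two overflow drains with a small expression gradient absorb whatever the
  module does not take — they are the mass-balance mirror of the module and
  the only non-module reactions expected in a recovered strategy;
* byproduct handling (CO2, bicarbonate, water) runs at pinned small rates,
  exercising the carbon-bound exemptions without adding free fluxes.

Expression is log-normal (meanlog = log 100, sdlog = 1 across genes) with
multiplicative noise at the stated CV and about 5% missingness
(missing-at-random plus a low-abundance bias) injected into background genes
only. The module genes start low (100 e^-2.1) so that the planted fold
change sweeps their reactions from the bottom towards the top of the
expression range across the three stages; the overflow genes sit near the
background centre. Three extra non-model rows exercise the presence-filter
edge cases. Planted essential genes are the single-copy backbone enzymes;
isozyme-protected and orphan genes are non-essential by construction.

Because module activation rides on the expression-correlated state
selection, the clean transition of this scenario is the spheroid-maturation
step (stage 2 to stage 3), and the recovery checks run there. The state
estimates for perturbation detection use 2,000 sampled points, and module /
intervention evaluations 500 points — budgets chosen so that selection noise
sits well below the planted effect on a ~40-reaction network; the pipeline
default of `2 x reactions` points follows the sampling protocol's convention
and is appropriate for the genome-scale setting it emulates.

Passing the synthetic battery shows that the machinery — preprocessing,
extraction, sampling, perturbation detection, greedy search, screens — is
internally consistent and recovers a strong planted signal. It does not show
that real proteomics at genome scale carries such a signal, that the
correlation-selected state identifies the biological flux distribution, or
that 2-fold flux changes in sampled states are biologically meaningful; on
real data those depend on network curation and measurement depth.

## Numerical choices

* Simplex: two-phase bounded-variable, Bland's rule after degeneracy runs,
  reduced-cost tolerance 1e-9; all problems are boxed (infinite bounds are
  replaced by 1e7).
* Branch-and-bound: depth-first, most-fractional branching, node cap 2e5;
  objective ties prefer fewer active binaries, then the lexicographically
  smallest pattern.
* Sampler: chains live exactly in the null space of S; points are
  re-projected every 25 steps against numerical drift and escaping proposals
  are rejected and logged.
* Degenerate inputs: constant expression arrays give degenerate thresholds
  (warning); zero-variance flux samples are skipped during state selection;
  correlation over fewer than three reactions is an error.

## Worked example

```{r example, eval = FALSE}
sc <- make_scenario(seed = 1)
res <- run_pipeline(sc$network, sc$expression, sc$essential_mets,
                    cfg = pipeline_config(seed = 1, n_seeds = 5),
                    drug_table = sc$drug_table,
                    normal_expression = sc$normal_expression)
res$transitions[[2]]$report            # perturbed set + baseline correlation
res$transitions[[2]]$strategies[[1]]   # best reaction-modulation strategy
head(res$transitions[[2]]$knockouts)   # ranked single-gene knockouts
res$transitions[[2]]$drugs             # drug screen with log2FC filter
```

## Known limitations

* The greedy search inherits the method's mechanical bias: clamping *any*
  flagged reaction to its exact reference value raises the correlation, so
  strategies may contain a few mass-balance mirrors of the causal module
  (the overflow drains in the synthetic scenario).
* Flux sampling quality governs everything downstream; on larger networks
  the default chain length should be raised (`thin`, `n_points`).
* The MILP solver is exact but dense and single-threaded; it is sized for
  networks of hundreds of reactions, not for whole genome-scale
  reconstructions with thousands of binary variables.
* No loopless-flux correction and no thermodynamic constraints are applied
  anywhere.
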
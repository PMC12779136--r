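---
title: "Methods: GAN-augmented metabolic modeling and flux classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GAN-augmented metabolic modeling and flux classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `fluxgan`, the parameters
that matter, the design decisions taken where the method left genuine
freedom, and the limits of what the test suite can establish.

## Pipeline overview

The pipeline contrasts two metabolic states — called `healthy` and
`cancer` throughout — from a bulk expression matrix and a genome-scale
metabolic network:

1. genes with zero counts in every sample are removed;
2. if the classes are imbalanced, a WGAN-GP learns the minority class
   and synthesizes candidate profiles, which are screened by three
   biological filters;
3. every sample (real and surviving synthetic) is reduced to a
   context-specific metabolic model by iMAT and scored by flux balance
   analysis;
4. a random forest over the padded flux features separates the states,
   and its importances are aggregated to pathways and gene families.

## Constraint-based core

### FBA and the parsimonious second stage

Flux balance analysis maximizes the biomass reaction subject to steady
state (`S v = 0`) and flux bounds (units follow the model file;
conventionally mmol/gDW/h). The optimum is usually degenerate; to make
downstream flux *features* well defined, `run_fba()` fixes the optimal
biomass and then minimizes total absolute flux (a linear program over
the split `v = p − q`). The raw single-stage behaviour is available
with `minimize_total_flux = FALSE`.

Exchange fluxes follow the universal convention: negative = uptake,
positive = secretion. Infinite bounds are canonicalized to ±1000 at
read time so that the big-M constraints of the MILP below are
well-posed.

### GPR mapping and discretization

Reaction expression is the GPR evaluation of the sample's gene values:
`and` (complex subunits) takes the minimum of its operands, `or`
(isozymes) the maximum. Genes absent from the matrix are treated as
missing, not zero: an `and` over present operands only, and a rule with
no present genes leaves the reaction unmapped.

Each sample's mapped reaction levels are discretized at
`mean ± sd_multiplier * SD` (default 0.3) computed *within the sample
across reactions*. The statistics are per sample because each sample is
contextualized independently; the axis is configurable. The 0.3
multiplier yields a high/low split comparable to quartile-style cutoffs
on expression-like (right-skewed) data, though not identical: for
exactly normal values the upper tail P(Z > 0.3) ≈ 0.38 rather than
0.25. We implement the stated SD rule, not percentiles.

### iMAT

With `R_H` the highly and `R_L` the lowly expressed reactions, the
MILP maximizes the number of `R_H` reactions carrying flux of magnitude
at least ε (default 1, in model units) in either direction plus the
number of `R_L` reactions carrying none, subject to steady state and
bounds. Binary indicators enter through the standard big-M constraints;
ε must exceed `activity_tol` (default 1e-6), the magnitude below which
a reaction counts as inactive in the solution.

The retained context model closes inactive reactions to (0, 0) and —
by default — tightens the bound of each rewarded `R_H` reaction toward
its active direction to ε (`enforce_activity = TRUE`). Without this,
the parsimonious FBA stage re-zeroes every expression-supported flux
that does not feed biomass, silently discarding exactly the signal iMAT
was asked to find; with it, the flux profile reflects the activity
pattern of the iMAT optimum. A single optimal solution is used;
alternate-optima enumeration is out of scope.

The MILP is solved by a best-bound branch-and-bound over a dense
two-phase simplex implemented in the package (Dantzig pricing with a
Bland's-rule fallback against cycling). The simplex was validated
against an independent interior-point/simplex implementation on random
instances during development, and the MILP is validated in the test
suite against brute-force enumeration of all activity assignments on
networks of up to 8 reactions. Dense tableaus are entirely adequate at
the tens-of-reactions scale this package targets; genome-scale models
load correctly but large MILPs will be slow.

## WGAN-GP

Generator `z(100) → 250 → 500 → 1000 → n_genes` with LeakyReLU(0.2)
hidden layers and a Tanh output; critic mirrored
(`n_genes → 1000 → 500 → 250 → 1`, linear output). Training minimizes
`E[D(fake)] − E[D(real)] + λ·E[(||∇ D(x̂)|| − 1)²]` for the critic
(λ = 10, one uniform mixing coefficient per row) and `−E[D(fake)]` for
the generator, with Adam (β₁ = 0, β₂ = 0.9, lr 1e-4), batch size 2,
2000 epochs, and 5 critic updates (each on a fresh real minibatch) per
generator update. An epoch is one pass over the minority samples in
shuffled batches. Data are min-max scaled per gene to [-1, 1] to match
the Tanh range; constant genes map to −1 and invert to their constant;
the inverse transform clamps to the training range and at zero.

Both networks, backpropagation, and the second-order gradient of the
penalty with respect to the critic weights are implemented directly in
R matrix algebra. For piecewise-linear activations the activation
pattern is locally constant, so the double-backward pass reuses the
forward masks; the parameter gradients were verified against central
finite differences (the check is part of the test suite).

Two deliberate deviations from the textbook recipe:

* **Two-timescale learning rates.** The generator's default learning
  rate is `lr / 5`. With minority sets of a few samples, equal rates
  make the generator chase the critic and the generated mean oscillates
  between the Tanh saturation points; a slower generator against a
  critic kept near optimality converges stably. Both rates are
  configurable.
* **Convergence diagnostics.** The critic loss of a freshly initialized
  critic on low-dimensional data starts near zero (He-initialized
  critics are nearly 1-Lipschitz there), so "loss decreases from start
  to end" is not a usable training diagnostic. The tested property is
  instead that the converged generator's mean is closer to the data
  mean than a briefly trained one, and that the late-training critic
  loss stays bounded near the equilibrium.

## Biological filtration

Synthetic candidates are scored on their FBA profiles:

1. **Energy envelope** — gross production of ATP, NADH and NADPH
   (sum over reactions and compartments of the positive part of
   coefficient × flux; consumption not subtracted) must lie inside the
   min–max envelope of the real healthy profiles, bounds inclusive.
2. **Glycolysis Disorder Index** — `max(0, lactate secretion) /
   |glucose uptake|` must be zero up to `zero_tol` (1e-6; exact zero is
   meaningless in floating-point LP output). Candidates without
   measurable glucose uptake have no defined GDI and are removed.
3. **Gluconeogenesis** — no flux beyond 1e-6 in the gluconeogenic
   direction of the configured marker reactions (the toy network's
   `GNG`; for a human genome-scale model, supply the
   glucose-6-phosphatase / fructose-1,6-bisphosphatase / PEPCK
   reaction ids).

The three screens are independent predicates, so the final survivor set
does not depend on their order; each removed candidate records its
first failing stage. Gross (not net) production is used for the
envelope; a net option is a one-line change in `production_rate()` but
is not exposed, as the gross rate is the stabler quantity under
alternate optima.

## Classification and importance

Features are the union of active reaction ids over all context models,
lexicographically ordered; a sample's absent reactions are marked
missing and imputed as zero by default (an absent reaction truly
carries no flux in that model). A `sentinel` mode
(`min − 1.5 · range`) is provided in case absence should be separable
from "present at zero flux".

The forest uses 1000 Gini trees with balanced class weights, a seeded
stratified 80/20 split, 8-fold stratified cross-validation *within the
training part* (CV over all data would leak the test set), and the
out-of-bag score of the final forest. Features are sorted
lexicographically before fitting, so results are invariant to the
order in which context models were assembled.

Importance aggregation: reaction importances are normalized
mean-decrease-in-Gini; pathway importance is the mean over member
reactions, reported both normalized over all pathways and over the top
15; a gene's raw score is the summed importance of the reactions whose
GPR mentions it, weighted by `0.5 + 0.5·plogis(k (n − n0))` (k = 1,
n0 = median reaction count per gene) so that multi-reaction genes gain
weight while single-reaction genes keep at least half; families roll up
by summation (mean available) and the top 15 are tiered at the type-7
quartiles of their scores, ties promoted upward. The weighting function
form is our own: the method it implements is specified only as a
sigmoid that boosts many-reaction genes while preserving few-reaction
ones, and this is the simplest form with those two properties and an
exact midpoint value (0.75) to test against.

## The synthetic benchmark

### Toy network

24 reactions across cytosol, lysosome and extracellular space: glucose
uptake, lumped hexokinase/glycolysis, lactate fermentation and export,
lumped TCA/oxidative phosphorylation (with a CO₂ drain), a
pentose-phosphate-like NADPH producer, demand reactions for the
ATP/NADH/NADPH pools, an ATP-consuming gluconeogenesis marker, a
biomass objective, and two signal branches: a three-step lysosomal
heparan-sulfate degradation chain (single-gene GPRs) and a fatty-acid
transport/activation pair with isozyme GPRs
(`FABP1 or FABP4 or SLC27A1`; `ACSL1 or ACSBG1`).

Both signal branches terminate in boundary-style sinks (degradation
products stored in the lysosome; activated fatty acid committed toward
membrane synthesis). This carbon-decoupling is essential to the
benchmark's validity: if branch activity fed central carbon, a planted
branch signal would perturb every core flux and the feature space would
be flooded with correlated class signal. Each metabolite carries an
integer carbon tag and every internal reaction balances the tags
exactly, which the suite asserts. The biomass optimum under default
bounds (7.323944) was computed once with an independent LP solver and
is frozen as a regression constant.

### Expression simulator

Expression is log-normal per gene:
`value = 2^(baseline + class_shift + N(0, noise_sd))`, with per-gene
baselines drawn once from `N(5, 0.5)` in log2 units (FPKM ≈ 32 with
about one decade of spread, as in a matrix already reduced to expressed
metabolic genes), plus 40 decoy genes outside all GPRs so that
preprocessing and the GAN see uninformative features. Planted
differential genes shift by ±`effect_size` (default 2) in the cancer
class only. The default cohort is 40/40; the imbalanced preset (4/40)
mirrors a two-orders-of-magnitude-smaller version of a typical tumor
cohort.

Three groups of genes get deterministic baselines rather than random
draws — this is the key calibration of the benchmark:

* **planted-up** (fatty-acid transport/activation) at median − e/2,
  rising to median + e/2 in cancer: a gained program crossing the
  discretization band symmetrically;
* **planted-down** (heparan-sulfate degradation) at the median,
  falling a full effect below in cancer: a lost program;
* **housekeeping**: core catabolism (GAPDH, PKM, CS, SDHA) at
  median + 0.5 and fermentation/gluconeogenesis genes (LDHA, LDHB,
  SLC16A1, PCK1, FBP1) at median − 1.

The housekeeping pins encode a well-nourished aerobic tissue. They are
not cosmetic: isozyme `or` rules take a maximum over their genes, which
biases multi-gene reactions upward, and without the pins the simulated
*healthy* reference samples themselves sporadically activate lactate
fermentation and gluconeogenesis — at which point the biological
filters have no healthy reference physiology to defend. With random
baselines for the planted genes, recovery of the planted signal is a
seed lottery (the per-sample discretization threshold in linear FPKM
space is dominated by whichever gene happens to draw the largest
baseline); pinning the planted programs to fixed positions relative to
the population median makes the benchmark measure the pipeline, not
the baseline draw.

### What passing tests do and do not show

The simulator plants clean, independent, single-direction shifts with
homogeneous log-normal noise and no correlation structure, batch
effects, or compositional constraints. Passing the recovery tests shows
the pipeline's machinery — mapping, discretization, MILP, FBA,
filtration, classification, aggregation — transmits a planted
differential program faithfully at desk scale. It does not show that
real tumor cohorts yield stable signatures, that the GAN captures real
expression covariance (at toy scale it is closer to a smoothed
memorization of a handful of profiles, which is also all the original
design asks of it), or that an ε = 1 activation threshold is
appropriate for any particular genome-scale model.

## Numerical choices

* LP: dense two-phase tableau simplex, pivot tolerance 1e-9,
  feasibility tolerance 1e-7; Dantzig pricing with Bland fallback.
* MILP: best-bound branch and bound, most-fractional branching,
  integral-objective flooring for pruning, absolute gap 1e-6.
* FBA second stage allows the biomass to relax by a relative 1e-9 so
  the flux-minimization stage is never infeasible from roundoff.
* Mass balance and bound satisfaction of any returned profile are
  asserted at 1e-6.
* Ties in quartile tiering promote upward; Spearman uses average ranks;
  constant feature columns get ρ = 0 with a flag.
* All stochastic stages (GAN init/shuffling/latents, splits, CV folds,
  forests, subsampling) derive their seeds deterministically from one
  master seed, so a configuration reproduces byte-identical outputs.

## Problem sizes

The test suite and the acceptance script run, per invocation: the
24-reaction toy network; iMAT-versus-enumeration checks on 50 (suite)
or 20 (script) random networks of ≤ 8 reactions; balanced cohorts of
80 samples across 5 seeds; one imbalanced 4-vs-30/40 cohort with a
reduced GAN configuration (widths 32–64, 250–400 epochs) and 40–60
synthetic candidates; and a 2-gene, 32-sample GAN recovery study at
800 epochs. These sizes exercise every code path on one CPU in a few
minutes while keeping the MILP enumeration oracle exact.

## Known limitations

* The LP/MILP layer is dense and unsuited to genome-scale iMAT; it is
  exact and fully auditable at benchmark scale, which is what the
  package's claims rest on.
* The GAN at full published widths (250–1000 neurons) trains in
  minutes, not seconds; tests use reduced widths, so the full-width
  configuration is exercised only for architecture introspection and
  single-epoch runs.
* Identifier handling is by opaque symbol; no translation between gene
  identifier systems is attempted.
* SBML support covers the Level-3 FBC subset needed to load
  Human1-style models (species, reactions, bounds via parameters,
  gene-product associations, flux objectives); curation features
  (groups, annotations, units) are ignored.
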
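# fluxgan

GAN-augmented context-specific metabolic modeling and flux-based
classification of two metabolic states, in R.

## The problem

Bulk transcriptomic cohorts that contrast a disease state against
matched healthy tissue are usually heavily imbalanced — a tumor cohort
may carry over a hundred cancer samples and only a handful of adjacent
normal controls. `fluxgan` implements an integrated pipeline for that
setting:

1. **Augment** the minority class with a Wasserstein GAN with gradient
   penalty (WGAN-GP) trained on the real minority expression profiles.
2. **Screen** every synthetic profile biologically: each candidate is
   turned into a constraint-based metabolic model, and only candidates
   whose predicted physiology looks genuinely healthy are kept.
3. **Contextualize** each sample (real and synthetic) into a
   context-specific metabolic model with the iMAT mixed-integer
   program, and predict a flux distribution by flux balance analysis.
4. **Classify** the two states with a random forest over the flux
   features, and aggregate the forest's importances from reactions to
   pathways to gene families.

The pipeline's output is a multi-level ranking of the metabolic
differences between the two states: which reactions, which pathways,
and which gene families discriminate them.

## The models at the core

**Flux balance analysis (FBA).** For a stoichiometric matrix *S*, flux
vector *v* and bounds *lb ≤ v ≤ ub*, FBA solves
`max v_biomass s.t. S v = 0, lb ≤ v ≤ ub`. Among alternate optima,
`run_fba()` returns the vector minimizing total absolute flux at the
fixed optimum (a parsimonious second stage), so flux features are
reproducible.

**iMAT.** Per sample, gene expression is mapped onto reactions through
gene–protein–reaction rules (`and` → min, `or` → max), discretized into
ternary states at mean ± 0.3·SD of the sample's mapped reaction levels,
and the iMAT MILP finds a steady-state flux pattern maximizing the
number of highly expressed reactions carrying flux ≥ ε plus the number
of lowly expressed reactions carrying none. Inactive reactions are
closed in the retained context model.

**WGAN-GP.** Generator 100 → 250 → 500 → 1000 → *n*-genes with
LeakyReLU(0.2) and a Tanh output; critic *n* → 1000 → 500 → 250 → 1.
The critic is softly constrained to be 1-Lipschitz by penalizing
`(||∇_x D(x̂)||₂ − 1)²` at interpolates between real and generated
batches (λ = 10); training uses Adam (β₁ = 0, β₂ = 0.9) with five
critic steps per generator step. Both networks and the double-backward
pass for the penalty are implemented directly in R matrix algebra.

**Biological filtration.** Three screens in sequence: (i) gross
ATP/NADH/NADPH production inside the envelope of the real healthy
models; (ii) Glycolysis Disorder Index — lactate secretion over glucose
uptake — equal to zero (no Warburg phenotype in "healthy" samples);
(iii) no flux through gluconeogenesis marker reactions.

**Importance aggregation.** Forest Gini importances per reaction;
pathway importance by within-pathway averaging; gene scores as the
summed importance of a gene's reactions, weighted by
`0.5 + 0.5·σ(k(n − n₀))` so that genes with many reactions gain weight
while genes with few keep at least half; family scores tiered by
quartiles over the top 15 (Very High / High / Medium / Low).

## Worked example

```r
library(fluxgan)

net <- build_toy_network()
m   <- simulate_expression(net, phenotype_spec(seed = 42))
res <- run_pipeline(pipeline_config(m, net, seed = 42))

glance(res$rf_fit)
#>   accuracy oob_score cv_mean  cv_sd cv_min cv_max n_features n_train n_test
#> 1        1     0.984   0.984 0.0442  0.875      1         21      64     16

head(res$ledger$reactions, 5)
#>   reaction_id importance    rho constant subsystem
#> 1 FAt             0.239   0.975 FALSE    Transport reactions
#> 2 FAact           0.223   0.975 FALSE    Fatty acid activation
#> 3 EX_fa           0.213  -0.975 FALSE    Exchange/demand reactions
#> 4 EX_hs           0.0592  0.734 FALSE    Exchange/demand reactions
#> 5 HSD1            0.0534 -0.734 FALSE    Heparan sulfate degradation

head(res$ledger$families, 6)
#>   family   score n_genes tier
#> 1 FABP1   0.179        1 Very High
#> 2 FABP4   0.179        1 Very High
#> 3 SLC27A1 0.179        1 Very High
#> 4 ACSBG1  0.167        1 Very High
#> 5 ACSL1   0.167        1 Very High
#> 6 SGSH    0.0401       1 High
```

The cohort planted an up-regulated fatty-acid transport program
(FABP/SLC27A/ACSL gene families) and a down-regulated lysosomal
heparan-sulfate degradation program in the cancer class. The forest
classifies the two states perfectly, ranks the fatty-acid transport
reaction (`FAt`, Spearman ρ = +0.98 with the cancer state) at the top,
and places the transporter families in the Very High tier — the pipeline
recovers exactly what was planted.

For an imbalanced cohort (e.g. 4 healthy vs 40 cancer), the same call
trains the WGAN-GP on the 4 healthy samples, generates candidates,
filters them (`res$filtration$report` gives per-stage counts), and
balances the classes before classification.

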
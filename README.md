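# mica — Microbiome Co-occurrence Analysis of effect modification

`mica` asks a question single-taxon microbiome epidemiology cannot:
does a small group of co-occurring gut microbes — a *microbial clique* —
associate with a health outcome, and does that association differ across
levels of a contextual exposure such as food insecurity? The motivating
application is risk of cognitive impairment (RCI) in adults, measured by
an adapted mini-cog word-recall score `s ∈ {0..3}` and analysed on the
inverted log scale `y = log(4 − s)` (higher = higher risk), with
household food insecurity as the binary effect modifier.

The analysis has two stages:

1. **Discovery (rh-SiRF).** A repeated-holdout signed iterative random
   forest: iterated forests reweight split-candidate sampling by
   importance, every root-to-leaf decision path is parsed into signed
   (high/low) taxon sets, presence-based itemsets are mined from
   high-risk paths, and itemset *stability* is the fraction of random
   60/40 holdouts (default 1000, with 250 bootstrap trees each) in which
   the itemset recurs. Top combinations are accepted while they form a
   closed-loop co-occurrence network; each closed component is a clique.
2. **Inference.** Each clique of k taxa becomes an integer indicator
   0..k counting present members. Within each modifier stratum, OLS of
   `y` on the indicator plus covariates (age, race/ethnicity, BMI,
   gender, pet ownership, smoking, fiber, antibiotic use) gives the
   effect estimate; its p-value comes from permuting the outcome
   (default 10^5 times): `p = (1 + #{|t_perm| ≥ |t_obs|}) / (1 + N)`.
   Cliques discovered in one stratum are validated in the other, a
   single overall model tests the clique-by-modifier interaction, and
   propensity-subclassification balance diagnostics (love-plot tables)
   probe confounding.

Because the motivating cohort's phenotype data are access-restricted,
the package includes a first-class synthetic cohort generator
(`simulate_cohort()`) that emulates the study's structure — 360 adults,
18.9% modifier prevalence, zero-inflated compositional abundances over
150 taxa, planted cliques with stratum-specific slopes, <2% MCAR
covariate missingness — so every stage is testable end to end.

## Worked example

Analyse the shipped synthetic study fixture (a 2-taxon clique planted on
ASV0070/ASV0075 with transformed-scale slopes 0.29 in the food-insecure
and 0.05 in the food-secure stratum):

```r
library(mica)

cfg <- read_sim_config_yaml(system.file("extdata", "study_fixture.yaml", package = "mica"))
sim <- simulate_cohort(cfg)

cohort <- prepare_cohort(sim$cohort, seed = 2)   # complete-case + PMM + transform
tab <- sim$abundance
tab$abund <- tab$abund[match(cohort$sample_id, sample_ids(tab)), ]
filtered <- prevalence_filter(to_relative_abundance(tab))
#> taxa retained: 145 of 150

# stage 1: discovery in the food-insecure stratum (scaled: 100 repeats x 25 bootstraps)
insecure <- cohort[cohort$modifier == 1, ]
X <- apply(filtered$abund[match(insecure$sample_id, sample_ids(filtered)), ],
           2, quartile_codes)
stability <- repeated_holdout_stability(X, insecure$y,
                                        rhsirf_config(n_repeats = 100, n_bootstraps = 25, seed = 11))
head(stability, 3)
#>                itemset size stability mean_frequency
#> 1224 ASV0070+;ASV0075+    2      0.45     0.07830346
#> 930  ASV0043+;ASV0070+    2      0.29     0.04165732
#> 937  ASV0043+;ASV0075+    2      0.19     0.03332669

cliques <- select_cliques_closed_loop(stability)
cliques[[1]]
#> clique 'clique_1': ASV0036, ASV0043, ASV0070, ASV0075

# stage 2: stratified association with permutation p, plus the interaction test
ind <- clique_indicator(filtered, cliques[[1]])
rbind(clique_association(cohort, ind, "insecure", n_perm = 1e4, seed = 3),
      clique_association(cohort, ind, "secure",   n_perm = 1e4, seed = 3))
#>    stratum       beta      ci_low   ci_high     p_perm   n
#> 1 insecure 0.16723815  0.09336839 0.2411079 0.00009999  60
#> 2   secure 0.01085467 -0.03336506 0.0550744 0.62763724 300

interaction_test(cohort, ind, n_perm = 1e4, seed = 3)
#>              term    beta     p_perm
#> 1 clique:modifier 0.16715 0.00029997
```

Reading the output: the planted pair `ASV0070+;ASV0075+` is the most
stable co-occurrence (recovered in 45% of holdouts, far above any
competitor); closed-loop selection returns one clique containing it
(plus two draw-correlated neighbours). Per present member, carrying the
clique raises transformed cognitive risk by 0.167 (95% CI 0.09–0.24) in
the food-insecure stratum — the permutation p of 1.0e-4 is the smallest
value 10^4 permutations can resolve — while the food-secure estimate is
near zero, and the clique-by-modifier interaction confirms the effect
modification in a single overall model.

`run_pipeline(pipeline_config(sim = cfg), "outdir")` runs all of the
above plus descriptives, per-taxon screening with FDR, cross-stratum
validation and balance diagnostics, writing every report as TSV with a
JSON manifest. A thin command-line wrapper lives at
`inst/cli/mica.R` (`Rscript mica.R run --config sim.yaml --outdir out`).

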
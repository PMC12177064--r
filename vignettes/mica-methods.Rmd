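---
title: "Microbial clique discovery and effect-modification inference with mica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial clique discovery and effect-modification inference with mica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mica)
```

## The scientific problem

Gut microbes act on host health not only one taxon at a time but through
small co-occurring groups — *microbial cliques*. This package implements a
two-stage Microbiome Co-occurrence Analysis (MiCA) for asking whether the
association between such cliques and a health outcome is *modified* by a
binary exposure context — the motivating application being risk of
cognitive impairment (RCI) in adults, with household food insecurity as
the modifier.

The outcome is an adapted mini-cog word-recall score $s \in \{0,1,2,3\}$
(higher = better recall). For regression it is inverted and
log-transformed,

$$y = \log(4 - s),$$

so that $y \in [0, \log 4]$ and higher values mean higher risk. The
inversion constant 4 is the smallest shift that keeps the inverted score
positive; it anchors the best score at exactly $y = 0$. The constant and
log base are package choices (`transform_outcome()`), exposed rather than
hidden, because only "inverted and then log-transformed" is conventional
for this instrument.

Analyses are stratified by the modifier ("secure" vs "insecure") and
adjusted for age, race/ethnicity (non-Hispanic White vs other), BMI,
gender, pet ownership, ever-smoking, dietary fiber (g), and antibiotic
use in the past year.

## Stage 1 — rh-SiRF clique discovery

`repeated_holdout_stability()` mines signed itemsets from a repeated
holdout signed iterative random forest:

1. **Iterative forest (`fit_irf()`).** Round 1 grows a regression forest
   with uniformly sampled split candidates; each later round samples
   candidate features proportionally to the previous round's impurity
   importance, softened by a 10% uniform floor (so no feature's sampling
   probability hits zero and the weight vector is always valid). The last
   round grows one tree per bootstrap resample of the training split.
   `mtry` defaults to $p/3$, the usual regression-forest fraction.
2. **Signed path parsing (`extract_signed_paths()`).** Each root-to-leaf
   path yields a set of (taxon, sign) pairs — `high` if the path takes
   the `>` branch at that taxon's split, `low` otherwise; a taxon split
   twice on one path keeps its deepest, most specific sign. Paths are
   weighted by training samples in the leaf.
3. **Presence-based itemset mining (`mine_cooccurrences()`).** Only
   decision paths whose leaves predict above-average risk are mined
   (`high_risk_only`), because the estimand is combinations predictive of
   *higher* risk; and by default only `high`-signed features enter the
   itemset alphabet (`signs = "high"`), because a clique is a
   joint-*presence* pattern ("and/or" of member taxa) — the low branch of
   a split describes absence and cannot contribute to a presence
   indicator. Support (the leaf-weighted fraction of mined paths
   containing the itemset) is anti-monotone by construction. Setting
   `signs = "both"` restores the full signed alphabet for exploration.
4. **Repeated holdouts.** Each of `n_repeats` rounds draws a fresh
   60/40 train/test partition, fits the iterative forest on the training
   part, and records which itemsets clear the support floor. *Stability*
   is the fraction of holdouts recovering an itemset. Full-scale defaults
   are 1000 repeats and 250 bootstraps; tests and examples use the scaled
   100 × 25, which changes stability estimates only within binomial
   Monte-Carlo error.
5. **Closed-loop selection (`select_cliques_closed_loop()`).** Candidates
   are ranked by total occurrence frequency across repeats and bootstraps
   (stability × mean within-forest frequency). They are accepted
   greedily while the accepted taxon network stays a union of closed
   loops: every accepted taxon must lie on a cycle, with a lone accepted
   edge counting as a 2-node loop. Two refinements make the greedy rule
   well defined: an itemset that cannot yet close (for example the second
   edge of a chain) stays *pending* and is admitted later only if a
   newly arrived itemset completes a cycle with it; and committed
   itemsets are protected — no later arrival may break a committed taxon
   off its loop. Each connected component of the surviving network is one
   clique.

Stage 1 is deliberately a hypothesis-generating miner. The
`stability_threshold` (default 0.5) is not a selection gate but the
"stable" flag reported with stage-1 output: under a pure-noise outcome at
the method's operating scale (a stratum of roughly 70 samples against a
150-taxon panel) no itemset should reach it, and the test suite checks
exactly that. Error control for selected cliques comes downstream.

Discovery runs on quartile-coded abundances — the same rank-based coding
used by the univariate screen — so split points are comparable across
taxa and a presence split is always available to the trees.

### What stability can and cannot distinguish

At a stratum size of ~70 samples and ~150 retained taxa, the best of the
~10^4 spurious taxon pairs has an in-draw association comparable to a
genuine clique with a slope of ~0.3 on the transformed scale; stability
over repeated holdouts of the *same* draw cannot fully separate the two,
because both patterns are properties of the draw. This is an information
limit of the design, not of the implementation: it is why stage 2
validates every selected clique in the opposite stratum and calibrates
p-values by permutation, and why stage-1 output should be read as a
candidate list.

## Stage 2 — stratified inference

`clique_indicator()` turns a clique of $k$ taxa into an integer count of
present members (abundance strictly greater than 0), ranging 0..k.
`clique_association()` fits OLS of $y$ on the indicator plus the full
covariate set within one stratum. The "robust" p-value is a permutation
p: the outcome vector is permuted `N` times (default $10^5$),
the model refitted, and

$$p = \frac{1 + \#\{|t_{\text{perm}}| \ge |t_{\text{obs}}|\}}{1 + N},$$

which is never exactly zero. The permutation statistic is the
coefficient's t-statistic (pivotal, better exchangeability under
covariates than the raw slope); permutation is unconditional on
covariates, as a literal reading of the procedure suggests — a
residual-based scheme would be a natural extension but is not the
default. Refits are vectorised through one QR decomposition of the fixed
design, so $10^5$ permutations take seconds.

`cross_stratum_validate()` re-estimates a clique discovered in one
stratum within the other stratum's samples — held out from discovery by
construction — and `interaction_test()` fits the single overall model
`y ~ indicator * modifier + covariates`, whose product term equals the
difference of stratum slopes when covariate effects are shared.

`balance_diagnostics()` is the confounding sensitivity check: a logistic
propensity model for "any member present", quantile subclassification
(default 5 subclasses; subclasses missing an exposure group merge with a
neighbour under a warning), and standardized mean differences per
covariate before and after subclass weighting. The SMD denominator is the
pre-balancing pooled SD in both columns, so before/after are comparable
in love-plot form.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of the motivating
cohort so the whole pipeline is testable without restricted data:

- **Covariates** from Table-1-style marginals: age $\mathcal N(61.5,
  13.4^2)$, BMI $\mathcal N(31.0, 7.4^2)$ (both truncated at plausible
  floors), fiber log-normal matched to mean 19.1 g and SD 10.0 g, and
  Bernoulli binaries (female 59%, non-Hispanic White 86%, pet 52%,
  smoker 47%, antibiotics 34%); modifier prevalence 18.9%. Covariates are
  drawn independently — the joint covariate distribution of the source
  survey is not public, so correlations are left as a knob deliberately
  not turned.
- **Abundances**: per-taxon Bernoulli presence × Gamma(0.5) positive
  draw, row-closed to 1. Zero inflation ramps evenly from 0.05 to 0.97
  across taxa, so the panel spans near-ubiquitous to
  below-the-prevalence-filter, and the 5% filter has real work to do.
- **Planted cliques**: a random carrier set of the target size gets all
  members filled in (draws from each taxon's observed positive values);
  non-carriers that happen to carry all members lose one at random; rows
  are re-closed. The shipped fixture plants its 2-taxon clique on
  mid-prevalence taxa (natural presence ≈ 0.5): joint presence of taxa
  that are nearly always present carries almost no information, and
  real cliques of interest live in the mid-prevalence regime.
- **Outcome**: a latent risk on the transformed scale — intercept 0.40
  (mid-scale), centered covariate effects, per-clique stratum-specific
  slope times the indicator (defaults 0.29 insecure / 0.05 secure), and
  Gaussian noise (SD 0.15) — is clamped to $[0, \log 4]$ and discretized
  by *mean-preserving stochastic rounding* onto the four transform
  levels. A deterministic nearest-level cut would bias slope estimates
  through the quantizer staircase; stochastic rounding makes
  $E[y \mid \text{latent}] = \text{latent}$ inside the range, so planted
  slopes are recoverable by OLS, while a latent value exactly at a level
  still maps to that score with probability 1 (the transform
  round-trips). One consequence, verified in the tests: a null generator
  is only exactly constant when its intercept sits on a transform level.
  The discretization itself contributes outcome noise (SD ≈ 0.19 at
  mid-scale), so the stratified effect estimates of the shipped fixture
  have standard errors close to those reported for the real cohort —
  the fixture is calibrated to the study's signal-to-noise, not to an
  easier regime.
- **Missingness**: MCAR masking of covariate cells only (default 1.5%,
  under the study's "<2%"); outcome and modifier are never masked, and
  the pipeline's complete-case rule on those two variables is applied
  before imputation.

All draws descend from one master seed through a documented sub-seeding
scheme (`label → 32-bit hash`), so every operation is individually
reproducible and the pipeline has no hidden RNG state.

What the generator does *not* emulate: phylogenetic structure, taxon-taxon
abundance correlations beyond planted cliques, compositional bias from
library-size variation (rows are exact compositions), covariate
correlation, and MNAR missingness. Passing tests therefore demonstrate
correctness of the machinery and calibration under these stated
conditions — not performance guarantees on real 16S data.

## Preprocessing choices

- **Prevalence filter**: presence is abundance strictly greater than 0
  (no pseudo-count floor); retained are taxa present in strictly more
  than 5% of samples; retained columns are *not* rescaled — so rows no
  longer sum to 1 after filtering, by design.
- **Quartile coding**: type-7 empirical quartile cut-points with values
  equal to a cut assigned the lower code; a constant vector collapses to
  code 0. Codes enter screening models as a single ordinal slope (one
  beta per taxon, comparable across taxa).
- **Shannon diversity** in nats via vegan, on the unfiltered relative
  abundances.
- **PMM imputation**: single imputation, k = 5 donors, linear models for
  continuous and logistic for binary covariates; every imputed value is
  an observed donor value. Multiple imputation with pooling is out of
  scope; with <2% MCAR the single-imputation approximation is benign and
  keeps the pipeline deterministic given its seed.
- **FDR families** are per stratum: the screen's q-values are computed
  within each stratum's family of retained taxa, never pooled.

## Numerical and degenerate-input behaviour

- OLS designs are checked for rank; collinear columns are named in the
  error. Classical SEs are the screening default; HC3 is available
  (`robust = TRUE`) but the permutation p is the inferential basis for
  clique associations.
- A clique indicator constant within a stratum is an error at discovery
  time but a reported non-validatable row (not an exception) during
  cross-stratum validation, and degenerate cliques in a pipeline run are
  skipped with a warning rather than aborting the run.
- Empty propensity subclasses merge with their neighbour, with a warning.
- Ties in stage-1 ranking break by mean frequency, then lexicographic
  itemset key, making every report reproducible byte for byte.

## Problem sizes used by tests and the acceptance script

The test suite and `scripts/acceptance.R` run the method at the scaled
problem sizes the design documents prescribe: the shipped fixture
(n = 360, 150 taxa, 18.9% modifier prevalence, one 2-taxon clique at 25%
joint prevalence with slopes 0.29/0.05) analysed with 100 repeats × 25
bootstraps and 20 algorithm seeds; null calibration with 100–200
replicate draws and 2,000-permutation p-values; and parameter recovery at
n = 10,000 with a 40-taxon panel. Full-scale defaults (1000 × 250,
10^5 permutations) remain the package defaults for real analyses.

## Known limitations

- Stage-1 stability cannot separate a true clique from the strongest
  spurious pair at stratum sizes below ~100 (see above); treat stage-1
  output as candidates and rely on stage-2 validation.
- The closed-loop rule is one reading of "combinations forming a
  closed-loop network"; the package treats it as a structural filter on
  the co-occurrence graph, with the pending/protected-greedy semantics
  described above.
- The permutation scheme assumes exchangeability of outcomes under the
  null; with strong covariate effects a residual-permutation scheme
  would be preferable, and the permutation statistic being pivotal
  mitigates but does not remove this.
- The generator's independence assumptions (covariates, non-clique taxa)
  make the null calibration results specific to those conditions.
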
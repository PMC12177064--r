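# Shared fixture builders; everything is generated in code at test time.

# Small analysis-ready synthetic study: cohort (with transformed outcome y)
# and prevalence-filtered abundance table, rows aligned.
small_study <- function(seed = 1, n = 120, n_taxa = 40, cliques = NULL,
                        modifier_prevalence = 0.25, ...) {
  if (is.null(cliques)) {
    cliques <- if (n_taxa >= 22) list(planted_clique(c(19, 21))) else list()
  }
  cfg <- sim_config(n_samples = n, n_taxa = n_taxa, cliques = cliques,
                    modifier_prevalence = modifier_prevalence, seed = seed, ...)
  sim <- simulate_cohort(cfg)
  cohort <- prepare_cohort(sim$cohort, seed = seed + 1)
  tab <- sim$abundance
  tab$abund <- tab$abund[match(cohort$sample_id, sample_ids(tab)), , drop = FALSE]
  filt <- prevalence_filter(tab)
  list(cohort = cohort, filtered = filt, table = tab, cfg = cfg)
}

# Quartile-coded predictor matrix for stage-1 discovery.
quartiled <- function(filtered, cohort) {
  X <- apply(filtered$abund[match(cohort$sample_id, sample_ids(filtered)), ,
                            drop = FALSE], 2, quartile_codes)
  rownames(X) <- cohort$sample_id
  X
}

# Tiny rh-SiRF configuration for unit tests.
fast_sirf <- function(n_repeats = 15, n_bootstraps = 15, n_trees = 30, seed = 7,
                      ...) {
  rhsirf_config(n_repeats = n_repeats, n_bootstraps = n_bootstraps,
                n_trees = n_trees, seed = seed, ...)
}

# Stability-table row builder for selection-rule tests.
itemset_table <- function(keys, stability, mean_frequency = stability) {
  data.frame(itemset = keys, size = lengths(strsplit(keys, ";", fixed = TRUE)),
             stability = stability, mean_frequency = mean_frequency,
             n_recovered = round(stability * 100), stringsAsFactors = FALSE)
}

clique_members <- function(cliques) {
  lapply(cliques, function(cl) cl$members)
}
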
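#' Pipeline configuration
#'
#' Either a [sim_config] (synthetic run) or paths to abundance/metadata/
#' taxonomy TSVs (real-data run) must be supplied.
#'
#' @param sim a [sim_config], or `NULL` when reading tables from disk.
#' @param abundance_path,metadata_path,taxonomy_path input TSVs for a
#'   real-data run.
#' @param prevalence_threshold prevalence filter fraction.
#' @param sirf an [rhsirf_config] for stage-1 discovery.
#' @param n_perm stage-2 permutation count.
#' @param n_subclasses propensity subclasses for balance diagnostics.
#' @param seed master pipeline seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, abundance_path = NULL,
                            metadata_path = NULL, taxonomy_path = NULL,
                            prevalence_threshold = 0.05,
                            sirf = rhsirf_config(),
                            n_perm = 100000, n_subclasses = 5, seed = 1L) {
  if (is.null(sim) && is.null(abundance_path)) {
    stopf("either a sim_config or input paths must be provided")
  }
  structure(list(sim = sim, abundance_path = abundance_path,
                 metadata_path = metadata_path, taxonomy_path = taxonomy_path,
                 prevalence_threshold = prevalence_threshold, sirf = sirf,
                 n_perm = as.integer(n_perm), n_subclasses = as.integer(n_subclasses),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  subseed(0, jsonlite::toJSON(unclass(rapply(cfg, unclass, how = "replace")),
                              auto_unbox = TRUE, digits = NA, force = TRUE))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full two-stage analysis
#'
#' Sequences generation (or loading), preprocessing, descriptives, per-taxon
#' screening, stage-1 clique discovery per stratum, and stage-2 inference
#' (stratified association, cross-stratum validation, interaction test,
#' balance diagnostics), writing every report as TSV plus a JSON manifest
#' with the seed, config hash and row/taxon counts at each filter step.
#'
#' @param cfg a [pipeline_config].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of the in-memory results (`cohort`, `filtered`,
#'   `descriptives`, `screen`, `stage1`, `cliques`, `stage2`, `interaction`,
#'   `balance`, `manifest`).
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   r_version = as.character(getRversion()))
  # ingest ------------------------------------------------------------
  if (!is.null(cfg$sim)) {
    sim <- simulate_cohort(cfg$sim)
    table <- sim$abundance
    cohort <- sim$cohort
  } else {
    table <- read_abundance_tsv(cfg$abundance_path, cfg$taxonomy_path)
    cohort <- read_cohort_tsv(cfg$metadata_path)
  }
  manifest$n_samples_raw <- nrow(cohort)
  manifest$n_taxa_raw <- ncol(table$abund)
  # preprocess ---------------------------------------------------------
  if (!table$is_relative) table <- to_relative_abundance(table)
  cohort <- prepare_cohort(cohort, seed = subseed(cfg$seed, "impute"))
  keep <- match(cohort$sample_id, sample_ids(table))
  table$abund <- table$abund[keep, , drop = FALSE]
  manifest$n_samples_analytical <- nrow(cohort)
  filtered <- prevalence_filter(table, cfg$prevalence_threshold)
  manifest$n_taxa_filtered <- ncol(filtered$abund)
  write_cohort_tsv(cohort, file.path(outdir, "cohort.tsv"))
  write_abundance_tsv(filtered, file.path(outdir, "abundance_filtered.tsv"))
  # descriptives -------------------------------------------------------
  desc <- cohort_descriptives(cohort, table)
  write_tsv(desc, file.path(outdir, "descriptives.tsv"))
  # univariate screen --------------------------------------------------
  screen <- list()
  for (st in names(strata_labels())) {
    res <- asv_screen(filtered, cohort, st)
    screen[[st]] <- res
    write_tsv(res, file.path(outdir, sprintf("screen_%s.tsv", st)))
    write_tsv(volcano_table(res), file.path(outdir, sprintf("volcano_%s.tsv", st)))
  }
  # stage 1: discovery per stratum -------------------------------------
  stage1 <- list(); cliques <- list()
  for (st in names(strata_labels())) {
    idx <- stratum_rows(cohort, st)
    sub <- cohort[idx, , drop = FALSE]
    # quartile-coded abundances keep split points comparable across taxa
    X <- apply(filtered$abund[match(sub$sample_id, sample_ids(filtered)), ,
                              drop = FALSE], 2, quartile_codes)
    rownames(X) <- sub$sample_id
    scfg <- cfg$sirf
    scfg$seed <- subseed(cfg$seed, "stage1", st)
    itemsets <- repeated_holdout_stability(X, sub$y, scfg)
    itemsets$stable <- itemsets$stability >= scfg$stability_threshold
    stage1[[st]] <- itemsets
    sel <- select_cliques_closed_loop(itemsets)
    for (i in seq_along(sel)) {
      sel[[i]]$name <- sprintf("%s_clique_%d", st, i)
      sel[[i]]$discovered_in <- st
    }
    cliques <- c(cliques, sel)
    itemsets$selected <- vapply(itemsets$itemset, function(k) {
      mem <- parse_itemset(k)$members
      any(vapply(sel, function(cl) all(mem %in% cl$all_members), logical(1)))
    }, logical(1))
    write_tsv(itemsets, file.path(outdir, sprintf("stage1_%s.tsv", st)))
  }
  write_tsv(clique_network_edges(cliques), file.path(outdir, "clique_network.tsv"))
  # stage 2: inference --------------------------------------------------
  stage2 <- list(); balance <- list()
  na_row <- function(name, st, n) {
    data.frame(term = name, stratum = st, beta = NA_real_, se = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p_raw = NA_real_,
               n = n, p_perm = NA_real_, n_perm = 0L, stringsAsFactors = FALSE)
  }
  for (cl in cliques) {
    ind <- clique_indicator(filtered, cl)
    st <- cl$discovered_in
    assoc <- tryCatch(
      clique_association(cohort, ind, st, n_perm = cfg$n_perm,
                         seed = subseed(cfg$seed, "stage2", cl$name),
                         clique_name = cl$name),
      error = function(e) {
        warning(sprintf("stage 2 [%s, %s]: %s", cl$name, st, conditionMessage(e)))
        na_row(cl$name, st, length(stratum_rows(cohort, st)))
      })
    assoc$validation <- FALSE
    assoc$discovered_in <- st
    valid <- cross_stratum_validate(cohort, ind, st, n_perm = cfg$n_perm,
                                    seed = subseed(cfg$seed, "validate", cl$name),
                                    clique_name = cl$name)
    stage2[[length(stage2) + 1L]] <- rbind(assoc, valid)
    bal <- tryCatch({
      b <- balance_diagnostics(cohort, ind, cfg$n_subclasses)
      b$clique <- cl$name
      b
    }, error = function(e) {
      warning(sprintf("balance [%s]: %s", cl$name, conditionMessage(e)))
      NULL
    })
    if (!is.null(bal)) balance[[length(balance) + 1L]] <- bal
  }
  stage2_df <- if (length(stage2)) do.call(rbind, stage2) else
    data.frame(term = character(0))
  write_tsv(stage2_df, file.path(outdir, "stage2_associations.tsv"))
  interaction <- list()
  for (cl in cliques) {
    ind <- clique_indicator(filtered, cl)
    row <- tryCatch(
      interaction_test(cohort, ind, n_perm = cfg$n_perm,
                       seed = subseed(cfg$seed, "interaction", cl$name),
                       clique_name = cl$name),
      error = function(e) {
        warning(sprintf("interaction [%s]: %s", cl$name, conditionMessage(e)))
        na_row(paste0(cl$name, ":modifier"), "overall", nrow(cohort))
      })
    interaction[[length(interaction) + 1L]] <- row
  }
  interaction_df <- if (length(interaction)) do.call(rbind, interaction) else
    data.frame(term = character(0))
  write_tsv(interaction_df, file.path(outdir, "interaction_model.tsv"))
  balance_df <- if (length(balance)) do.call(rbind, balance) else
    data.frame(covariate = character(0))
  write_tsv(balance_df, file.path(outdir, "balance.tsv"))
  manifest$n_cliques <- length(cliques)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, filtered = filtered, descriptives = desc,
                 screen = screen, stage1 = stage1, cliques = cliques,
                 stage2 = stage2_df, interaction = interaction_df,
                 balance = balance_df, manifest = manifest))
}
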
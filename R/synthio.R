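#' Planted clique specification
#'
#' Describes a small set of taxa whose joint presence is forced to a target
#' prevalence and which carries a modifier-stratum-specific slope on the
#' transformed-outcome (risk) scale.
#'
#' @param members integer taxon indices (or taxon ids) of the clique members.
#' @param joint_prevalence target fraction of samples carrying ALL members.
#' @param effect named numeric of length 2, slopes per present member on the
#'   transformed-outcome scale: `c(secure = ..., insecure = ...)`.
#' @return An object of class `planted_clique`.
#' @export
planted_clique <- function(members, joint_prevalence = 0.25,
                           effect = c(secure = 0.05, insecure = 0.29)) {
  if (length(members) < 1) members <- integer(0)
  if (length(members) > 0 && (length(members) < 2 || length(members) > 8)) {
    stopf("planted clique must have 2-8 members (got %d)", length(members))
  }
  if (!is.numeric(joint_prevalence) || joint_prevalence <= 0 || joint_prevalence > 1) {
    stopf("joint_prevalence must lie in (0, 1]")
  }
  if (!all(c("secure", "insecure") %in% names(effect))) {
    stopf("effect must be named with 'secure' and 'insecure'")
  }
  structure(list(members = members, joint_prevalence = joint_prevalence,
                 effect = effect[c("secure", "insecure")]),
            class = "planted_clique")
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the statistical structure of the study sample the
#' pipeline was designed for: 360 adults, 18.9% modifier (food-insecurity)
#' prevalence, zero-inflated compositional abundances over 150 taxa, one
#' planted 2-taxon clique at 25% joint prevalence with per-member slopes of
#' 0.29 (insecure) and 0.05 (secure) on the transformed cognitive-risk
#' scale, and <2% MCAR covariate missingness.
#'
#' @param n_samples number of samples.
#' @param n_taxa number of taxa (ASVs).
#' @param modifier_prevalence Bernoulli prevalence of the binary modifier.
#' @param zero_inflation per-taxon probability that a sample lacks the taxon;
#'   scalar or length-`n_taxa` vector. The default spreads taxa evenly from
#'   nearly ubiquitous to nearly absent so the 5% prevalence filter bites.
#' @param concentration gamma shape of the positive abundance component;
#'   scalar or per-taxon.
#' @param cliques list of [planted_clique] objects. The default plants a
#'   2-taxon clique on mid-prevalence taxa (natural presence around 50%),
#'   the regime in which joint presence is informative.
#' @param covariate_effects named numeric of slopes on the transformed-outcome
#'   scale (centered covariates); may include `modifier`.
#' @param intercept latent transformed-risk baseline (scale 0 .. ln 4).
#' @param noise_sd latent Gaussian noise standard deviation.
#' @param missing_rate MCAR covariate missingness rate.
#' @param seed master seed; all operations derive sub-seeds from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 360,
                       n_taxa = 150,
                       modifier_prevalence = 0.189,
                       zero_inflation = NULL,
                       concentration = 0.5,
                       cliques = list(planted_clique(c(70, 75))),
                       covariate_effects = c(age = 0.003, fiber = -0.002,
                                             smoker = 0.04, modifier = 0.06),
                       intercept = 0.40,
                       noise_sd = 0.15,
                       missing_rate = 0.015,
                       seed = 1L) {
  if (n_samples < 2) stopf("n_samples must be >= 2")
  if (n_taxa < 1) stopf("n_taxa must be >= 1")
  if (!is_fraction(modifier_prevalence)) stopf("modifier_prevalence must lie in [0, 1]")
  if (!is_fraction(missing_rate) || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")
  if (is.null(zero_inflation)) {
    zero_inflation <- if (n_taxa == 1) 0.2 else seq(0.05, 0.97, length.out = n_taxa)
  }
  zero_inflation <- rep_len(zero_inflation, n_taxa)
  if (!is_fraction(zero_inflation)) stopf("zero_inflation must lie in [0, 1]")
  concentration <- rep_len(concentration, n_taxa)
  if (any(concentration <= 0)) stopf("concentration must be positive")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  for (cl in cliques) {
    if (!inherits(cl, "planted_clique")) stopf("cliques must be planted_clique objects")
    if (is.numeric(cl$members) && length(cl$members) && max(cl$members) > n_taxa) {
      stopf("planted clique references taxon index %d > n_taxa = %d",
            max(cl$members), n_taxa)
    }
  }
  structure(list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
                 modifier_prevalence = modifier_prevalence,
                 zero_inflation = zero_inflation, concentration = concentration,
                 cliques = cliques, covariate_effects = covariate_effects,
                 intercept = intercept, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Genus-level labels recycled over synthetic taxa; chosen to look like a
# 16S genus table (purely cosmetic).
synthetic_genus_pool <- function() {
  c("Eisenbergiella", "Eubacterium", "Ruminococcus_torques_group", "Bacteroides",
    "CAG-352F", "Christensenellaceae_R-7_group", "Faecalibacterium", "Blautia",
    "Roseburia", "Prevotella", "Akkermansia", "Alistipes", "Bifidobacterium",
    "Coprococcus", "Dorea", "Lachnospira", "Oscillibacter", "Parabacteroides",
    "Streptococcus", "Subdoligranulum")
}

#' Simulate per-sample covariates and modifier
#'
#' Continuous covariates (age, BMI, fiber) are drawn from normal/log-normal
#' marginals matching the emulated cohort; binary covariates and the
#' modifier are Bernoulli at the configured prevalences.
#'
#' @param cfg a [sim_config].
#' @return data.frame with `sample_id`, covariates and `modifier`.
#' @export
simulate_covariates <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  # fiber: log-normal matched to mean 19.06 g, sd 10.03 g
  cv <- 10.03 / 19.06
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(19.06) - sdlog^2 / 2
  with_seed(subseed(cfg$seed, "covariates"), {
    data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      age = pmax(18, rnorm(n, 61.47, 13.44)),
      bmi = pmax(15, rnorm(n, 30.99, 7.37)),
      fiber = rlnorm(n, meanlog, sdlog),
      female = rbinom(n, 1, 0.5917),
      nhw = rbinom(n, 1, 0.8556),
      pet = rbinom(n, 1, 0.5222),
      smoker = rbinom(n, 1, 0.4722),
      abx = rbinom(n, 1, 0.3444),
      modifier = rbinom(n, 1, cfg$modifier_prevalence),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a zero-inflated compositional abundance table
#'
#' Per-taxon Bernoulli presence (1 - zero_inflation) times a gamma positive
#' draw, row-closed to sum 1. Samples that would be entirely empty get their
#' least-sparse taxon forced present so every row is a valid composition.
#'
#' @param cfg a [sim_config].
#' @return an [abundance_table] with `is_relative = TRUE`.
#' @export
simulate_abundances <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples; p <- cfg$n_taxa
  with_seed(subseed(cfg$seed, "abundances"), {
    present <- matrix(rbinom(n * p, 1, rep(1 - cfg$zero_inflation, each = n)), n, p)
    pos <- matrix(rgamma(n * p, shape = rep(cfg$concentration, each = n), rate = 1), n, p)
    mat <- present * pos
    empty <- rowSums(mat) == 0
    if (any(empty)) {
      j <- which.min(cfg$zero_inflation)
      mat[empty, j] <- rgamma(sum(empty), shape = cfg$concentration[j], rate = 1)
      still <- rowSums(mat) == 0  # gamma draw is almost surely positive
      mat[still, j] <- 1
    }
    mat <- mat / rowSums(mat)
  })
  labels <- paste0(rep_len(synthetic_genus_pool(), p), "_ASV", seq_len(p))
  colnames(mat) <- sprintf("ASV%04d", seq_len(p))
  rownames(mat) <- sprintf("S%04d", seq_len(n))
  abundance_table(mat, taxonomy = setNames(labels, colnames(mat)), is_relative = TRUE)
}

resolve_members <- function(table, members) {
  ids <- taxon_ids(table)
  if (is.numeric(members)) {
    if (length(members) && max(members) > length(ids)) {
      stopf("clique member index %d exceeds %d taxa", max(members), length(ids))
    }
    return(ids[members])
  }
  missing <- setdiff(members, ids)
  if (length(missing)) stopf("clique members not in table: %s", paste(missing, collapse = ", "))
  members
}

#' Plant a joint-presence clique into an abundance table
#'
#' Adjusts presence/absence of the member taxa so that the fraction of
#' samples carrying ALL members hits the target: a random carrier set of
#' size `round(n * target)` has absent members filled in with draws from the
#' taxon's positive-abundance distribution, and every non-carrier sample has
#' one member zeroed if it happened to carry all of them. Non-member columns
#' are untouched before the final row re-closure to sum 1.
#'
#' @param table an [abundance_table] (relative).
#' @param clique a [planted_clique].
#' @param seed seed for carrier selection and fill-in draws.
#' @return the modified [abundance_table].
#' @export
plant_clique <- function(table, clique, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"), inherits(clique, "planted_clique"))
  if (length(clique$members) == 0) return(table)
  members <- resolve_members(table, clique$members)
  n <- nrow(table$abund)
  m <- round(n * clique$joint_prevalence)
  if (m < 1) stopf("joint prevalence target %.3f unreachable with n = %d samples",
                   clique$joint_prevalence, n)
  mat <- table$abund
  with_seed(subseed(seed, "plant", paste(members, collapse = ",")), {
    carriers <- sample.int(n, m)
    for (tx in members) {
      col <- mat[, tx]
      need <- carriers[col[carriers] == 0]
      if (length(need)) {
        donors <- col[col > 0]
        fill <- if (length(donors)) {
          sample(donors, length(need), replace = TRUE)
        } else {
          rgamma(length(need), shape = 0.5, rate = 1) / ncol(mat)
        }
        mat[need, tx] <- fill
      }
    }
    non <- setdiff(seq_len(n), carriers)
    all_present <- non[rowSums(mat[non, members, drop = FALSE] > 0) == length(members)]
    if (length(all_present)) {
      drop_idx <- sample(members, length(all_present), replace = TRUE)
      mat[cbind(all_present, match(drop_idx, colnames(mat)))] <- 0
    }
  })
  zero_rows <- rowSums(mat) == 0
  if (any(zero_rows)) stopf("planting emptied sample(s): %s",
                            paste(rownames(mat)[zero_rows], collapse = ", "))
  mat <- mat / rowSums(mat)
  abundance_table(mat, taxonomy = table$taxonomy, is_relative = TRUE)
}

#' Simulate the cognitive score from planted effects
#'
#' Builds a latent transformed-risk value (intercept + centered covariate
#' effects + per-clique stratum-specific slope times the clique indicator +
#' Gaussian noise), clamps it to the transform range, and maps it back to an
#' integer word-recall score in 0..3 by mean-preserving stochastic rounding
#' onto the four transform levels, so that regressing the re-transformed
#' score on the indicator recovers the planted slope.
#'
#' @param table an [abundance_table] carrying the planted cliques.
#' @param cohort covariate data.frame from [simulate_covariates()].
#' @param cfg a [sim_config].
#' @return `cohort` with an integer `outcome` column (0..3) appended.
#' @export
simulate_outcome <- function(table, cohort, cfg) {
  stopifnot(inherits(table, "abundance_table"), inherits(cfg, "sim_config"))
  if (!identical(sample_ids(table), cohort$sample_id)) {
    stopf("abundance table and cohort sample ids are not aligned")
  }
  n <- nrow(cohort)
  latent <- rep(cfg$intercept, n)
  eff <- cfg$covariate_effects
  for (cv in names(eff)) {
    if (!cv %in% names(cohort)) stopf("covariate_effects names unknown column '%s'", cv)
    x <- cohort[[cv]]
    latent <- latent + eff[[cv]] * (x - mean(x))
  }
  for (cl in cfg$cliques) {
    if (length(cl$members) == 0) next
    members <- resolve_members(table, cl$members)
    ind <- rowSums(table$abund[, members, drop = FALSE] > 0)
    slope <- ifelse(cohort$modifier == 1, cl$effect[["insecure"]], cl$effect[["secure"]])
    latent <- latent + slope * ind
  }
  with_seed(subseed(cfg$seed, "outcome"), {
    latent <- latent + rnorm(n, 0, cfg$noise_sd)
    cohort$outcome <- discretize_outcome(latent)
  })
  cohort
}

#' Map latent transformed risk to an integer score 0..3
#'
#' The transform levels are `log(4 - s)` for s = 3,2,1,0, i.e.
#' 0, ln 2, ln 3, ln 4. A latent value is clamped to \[0, ln 4\] and rounded
#' stochastically to one of its two bracketing levels with probabilities
#' that preserve its expectation; a latent value exactly at a level maps to
#' that level's score with probability 1, so the transform round-trips.
#' Consumes the current RNG stream.
#'
#' @param latent numeric vector on the transformed-outcome scale.
#' @return integer scores in `{0, 1, 2, 3}`.
#' @export
discretize_outcome <- function(latent) {
  lv <- log(1:4)                     # 0, ln2, ln3, ln4 <-> scores 3,2,1,0
  t <- pmin(pmax(latent, 0), log(4))
  i <- findInterval(t, lv, rightmost.closed = TRUE)
  lo <- lv[i]; hi <- lv[pmin(i + 1, 4L)]
  w <- ifelse(hi > lo, (t - lo) / (hi - lo), 0)
  take_hi <- runif(length(t)) < w
  level <- ifelse(take_hi, hi, lo)
  as.integer(round(4 - exp(level)))
}

#' Mask covariate cells completely at random
#'
#' Outcome, modifier and sample id are never masked.
#'
#' @param cohort cohort data.frame.
#' @param cfg a [sim_config] (uses `missing_rate` and `seed`).
#' @return cohort with `NA`s injected into covariate columns.
#' @export
inject_missingness <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$missing_rate == 0) return(cohort)
  cols <- intersect(covariate_names(), names(cohort))
  with_seed(subseed(cfg$seed, "missing"), {
    for (cl in cols) {
      mask <- runif(nrow(cohort)) < cfg$missing_rate
      cohort[[cl]][mask] <- NA
    }
  })
  cohort
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generator: covariates, abundances, clique planting, outcome
#' and missingness, in a fixed sub-seeded order.
#'
#' @param cfg a [sim_config].
#' @return list with elements `abundance` ([abundance_table]) and `cohort`
#'   (data.frame with outcome, modifier, covariates).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  cohort <- simulate_covariates(cfg)
  table <- simulate_abundances(cfg)
  for (k in seq_along(cfg$cliques)) {
    table <- plant_clique(table, cfg$cliques[[k]], seed = subseed(cfg$seed, "clique", k))
  }
  cohort <- simulate_outcome(table, cohort, cfg)
  cohort <- inject_missingness(cohort, cfg)
  list(abundance = table, cohort = cohort)
}

#' @rdname sim_config
#' @param path YAML file path.
#' @export
write_sim_config_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$cliques <- lapply(cfg$cliques, function(cl) {
    list(members = cl$members, joint_prevalence = cl$joint_prevalence,
         effect = as.list(cl$effect))
  })
  x$covariate_effects <- as.list(cfg$covariate_effects)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname sim_config
#' @export
read_sim_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cliques <- lapply(x$cliques, function(cl) {
    planted_clique(unlist(cl$members), cl$joint_prevalence, unlist(cl$effect))
  })
  sim_config(n_samples = x$n_samples, n_taxa = x$n_taxa,
             modifier_prevalence = x$modifier_prevalence,
             zero_inflation = unlist(x$zero_inflation),
             concentration = unlist(x$concentration),
             cliques = cliques,
             covariate_effects = unlist(x$covariate_effects),
             intercept = x$intercept, noise_sd = x$noise_sd,
             missing_rate = x$missing_rate, seed = x$seed)
}
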
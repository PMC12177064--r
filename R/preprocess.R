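#' Convert counts to relative abundance
#'
#' Divides each sample row by its total. Idempotent on already-relative
#' input.
#'
#' @param table an [abundance_table].
#' @return the [abundance_table] with `is_relative = TRUE`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  rs <- rowSums(table$abund)
  if (any(rs == 0)) {
    stopf("sample(s) with all-zero abundance: %s",
          paste(sample_ids(table)[rs == 0], collapse = ", "))
  }
  abundance_table(table$abund / rs, taxonomy = table$taxonomy, is_relative = TRUE)
}

#' Prevalence-filter rare taxa
#'
#' Keeps exactly the taxa present (abundance strictly greater than zero) in
#' strictly more than `threshold` of samples. Retained columns are passed
#' through bit-identically: relative abundances are NOT rescaled after rare
#' taxa are dropped.
#'
#' @param table a relative [abundance_table].
#' @param threshold prevalence fraction; taxa with prevalence `> threshold`
#'   are kept (default 0.05, i.e. the "more than 5% of samples" rule).
#' @return filtered [abundance_table] (rows no longer sum to 1).
#' @export
prevalence_filter <- function(table, threshold = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  if (!table$is_relative) stopf("prevalence_filter expects relative abundances")
  prev <- colMeans(table$abund > 0)
  keep <- prev > threshold
  if (!any(keep)) stopf("prevalence filter at %.3f removed all %d taxa",
                        threshold, ncol(table$abund))
  out <- table
  out$abund <- table$abund[, keep, drop = FALSE]
  out$taxonomy <- table$taxonomy[colnames(out$abund)]
  out
}

#' Quartile-code one taxon's abundances
#'
#' Codes in `{0,1,2,3}` from the empirical quartile cut-points (type-7
#' quantiles), with values equal to a cut-point assigned the lower code.
#' Fully rank-based: tied values share a code and a constant vector
#' collapses to all zeros.
#'
#' @param values numeric vector of per-sample abundances (length >= 4).
#' @return integer vector of codes.
#' @export
quartile_codes <- function(values) {
  if (length(values) < 4) stopf("quartile coding needs at least 4 values (got %d)",
                                length(values))
  cuts <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  as.integer(rowSums(outer(values, cuts, `>`)))
}

#' Shannon alpha diversity of one sample (nats)
#'
#' `H = -sum(p * ln p)` over positive components, computed with
#' \pkg{vegan}'s `diversity()`.
#'
#' @param row relative-abundance vector summing to 1.
#' @param tol tolerance on the row sum.
#' @return Shannon index in natural-log units.
#' @export
shannon_diversity <- function(row, tol = 1e-6) {
  if (any(row < 0)) stopf("negative abundance in Shannon input")
  if (abs(sum(row) - 1) > tol) stopf("Shannon input must sum to 1 (got %.6f)", sum(row))
  as.numeric(vegan::diversity(row, index = "shannon"))
}

#' Transform the word-recall score to the risk scale
#'
#' The 0-3 recall score is inverted (4 - score, so higher = worse recall)
#' and natural-log transformed: `log(4 - score)`. Higher transformed values
#' indicate higher risk of cognitive impairment; the best score (3) maps to
#' exactly 0. The inversion constant 4 is the smallest shift keeping the
#' inverted score positive; see the methods vignette for the rationale.
#'
#' @param score integer score(s) in `{0,1,2,3}`.
#' @return transformed outcome(s) in `[0, log 4]`.
#' @export
transform_outcome <- function(score) {
  if (any(is.na(score)) || any(!score %in% 0:3)) {
    stopf("scores must lie in {0,1,2,3}")
  }
  log(4 - score)
}

#' @rdname transform_outcome
#' @param y transformed outcome value(s).
#' @return `inverse_transform_outcome()` returns the (real-valued) score.
#' @export
inverse_transform_outcome <- function(y) 4 - exp(y)

#' Predictive-mean-matching imputation of missing covariates
#'
#' Single imputation. Each covariate column with missing cells is modelled
#' on the other covariates (linear regression for continuous columns,
#' logistic for binaries) using its observed rows; every missing cell is
#' filled with the observed value of one of the `k` donors whose predicted
#' means are nearest to the recipient's prediction, drawn uniformly among
#' them. Predictor gaps are bridged with column means/modes for the
#' prediction step only, so imputed values are always observed donor
#' values.
#'
#' @param cohort cohort data.frame (missingness only in covariate columns).
#' @param k number of donors (default 5).
#' @param seed seed for donor draws.
#' @return completed cohort data.frame.
#' @export
pmm_impute <- function(cohort, k = 5, seed = 1L) {
  cols <- intersect(covariate_names(), names(cohort))
  other <- setdiff(names(cohort), c("sample_id", cols))
  if (any(vapply(cohort[other], anyNA, logical(1)))) {
    stopf("missingness outside covariate columns")
  }
  miss_cols <- cols[vapply(cohort[cols], anyNA, logical(1))]
  if (!length(miss_cols)) return(cohort)
  fully_missing <- miss_cols[vapply(cohort[miss_cols], function(x) all(is.na(x)), logical(1))]
  if (length(fully_missing)) {
    stopf("column(s) entirely missing: %s", paste(fully_missing, collapse = ", "))
  }
  # mean/mode-filled predictor copy used only to form predictions
  filled <- cohort
  for (cl in cols) {
    x <- filled[[cl]]
    if (anyNA(x)) filled[[cl]][is.na(x)] <- mean(x, na.rm = TRUE)
  }
  with_seed(seed, {
    for (cl in miss_cols) {
      obs <- !is.na(cohort[[cl]])
      preds <- setdiff(cols, cl)
      dat <- filled[, preds, drop = FALSE]
      dat$.y <- cohort[[cl]]
      binary <- all(cohort[[cl]][obs] %in% c(0, 1))
      fit <- if (binary) {
        glm(.y ~ ., data = dat[obs, , drop = FALSE], family = binomial())
      } else {
        lm(.y ~ ., data = dat[obs, , drop = FALSE])
      }
      yhat <- predict(fit, newdata = dat, type = if (binary) "response" else "response")
      donors_hat <- yhat[obs]
      donors_val <- cohort[[cl]][obs]
      for (i in which(!obs)) {
        d <- abs(donors_hat - yhat[i])
        pool <- order(d)[seq_len(min(k, length(d)))]
        cohort[[cl]][i] <- donors_val[pool[sample.int(length(pool), 1)]]
      }
    }
  })
  cohort
}

#' Prepare an analysis-ready cohort
#'
#' Applies the complete-case filter on outcome and modifier, attaches the
#' transformed outcome column `y`, and imputes residual covariate
#' missingness with [pmm_impute()].
#'
#' @param cohort raw cohort data.frame.
#' @param seed imputation seed.
#' @return analysis-ready cohort with column `y`.
#' @export
prepare_cohort <- function(cohort, seed = 1L) {
  keep <- !is.na(cohort$outcome) & !is.na(cohort$modifier)
  cohort <- cohort[keep, , drop = FALSE]
  cohort <- pmm_impute(cohort, seed = seed)
  cohort$y <- transform_outcome(cohort$outcome)
  cohort
}
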
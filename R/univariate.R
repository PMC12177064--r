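#' Covariate-adjusted OLS association for one term
#'
#' Ordinary least squares of the transformed outcome on a focal predictor
#' plus adjustment covariates, returning the focal term's estimate with a
#' t-based 95% confidence interval. Classical standard errors by default;
#' HC3 heteroskedasticity-robust errors on request.
#'
#' @param y numeric outcome vector (transformed scale).
#' @param design data.frame of predictors; the focal column named by `term`.
#' @param term name of the focal column in `design`.
#' @param stratum label recorded in the result row.
#' @param robust use sandwich HC3 standard errors.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data.frame: `term, stratum, beta, se, ci_low, ci_high,
#'   p_raw, n` (an association-result row).
#' @export
ols_fit <- function(y, design, term, stratum = "overall", robust = FALSE,
                    conf_level = 0.95) {
  design <- as.data.frame(design)
  if (!term %in% names(design)) stopf("term '%s' not in design", term)
  if (anyNA(y) || anyNA(design)) stopf("missing values in model input; impute first")
  n <- length(y)
  if (n <= ncol(design) + 1) stopf("n = %d too small for %d parameters", n, ncol(design) + 1)
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design; collinear column(s): %s", paste(bad, collapse = ", "))
  }
  fit <- lm(y ~ ., data = design)
  est <- coef(fit)[[term]]
  vc <- if (robust) sandwich::vcovHC(fit, type = "HC3") else stats::vcov(fit)
  se <- sqrt(vc[term, term])
  df <- fit$df.residual
  tval <- est / se
  crit <- qt(1 - (1 - conf_level) / 2, df)
  data.frame(term = term, stratum = stratum, beta = est, se = se,
             ci_low = est - crit * se, ci_high = est + crit * se,
             p_raw = 2 * pt(-abs(tval), df), n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values via `p.adjust(method = "BH")`, with input validation.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return q-values in the input order (empty in, empty out).
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-taxon quartile-coded screening within a stratum
#'
#' For every retained taxon, quartile-codes its relative abundances within
#' the stratum and fits a covariate-adjusted OLS with the code entering as
#' a single ordinal slope. Raw p-values are BH-adjusted within the
#' stratum's family.
#'
#' @param table prevalence-filtered relative [abundance_table].
#' @param cohort analysis-ready cohort (column `y` present).
#' @param stratum `"secure"`, `"insecure"`, or `"overall"`.
#' @param min_n smallest admissible stratum size.
#' @return data.frame with one association-result row per taxon, plus
#'   `q_fdr` and a `label` (genus-level taxonomy) column.
#' @export
asv_screen <- function(table, cohort, stratum, min_n = 30) {
  stopifnot(inherits(table, "abundance_table"))
  idx <- stratum_rows(cohort, stratum)
  if (length(idx) < min_n) {
    stopf("stratum '%s' has n = %d < minimum %d", stratum, length(idx), min_n)
  }
  sub <- cohort[idx, , drop = FALSE]
  mat <- table$abund[match(sub$sample_id, sample_ids(table)), , drop = FALSE]
  covs <- sub[, intersect(covariate_names(), names(sub)), drop = FALSE]
  rows <- lapply(colnames(mat), function(tx) {
    design <- cbind(data.frame(asv_q = quartile_codes(mat[, tx])), covs)
    out <- ols_fit(sub$y, design, term = "asv_q", stratum = stratum)
    out$term <- tx
    out
  })
  res <- do.call(rbind, rows)
  res$q_fdr <- bh_adjust(res$p_raw)
  res$label <- unname(table$taxonomy[res$term])
  res
}

stratum_rows <- function(cohort, stratum) {
  if (identical(stratum, "overall")) return(seq_len(nrow(cohort)))
  which(cohort$modifier == stratum_value(stratum))
}

#' Volcano-plot table
#'
#' Adds `-log10(p)` and a significance band to screening results; reference
#' bands correspond to raw p at 0.05 and 0.01.
#'
#' @param results screening results from [asv_screen()].
#' @return data.frame with `term, label, stratum, beta, neg_log10_p, band`.
#' @export
volcano_table <- function(results) {
  if (!nrow(results)) stopf("no results to tabulate")
  band <- ifelse(results$p_raw < 0.01, "p<0.01",
                 ifelse(results$p_raw < 0.05, "p<0.05", "ns"))
  data.frame(term = results$term,
             label = if ("label" %in% names(results)) results$label else results$term,
             stratum = results$stratum, beta = results$beta,
             neg_log10_p = -log10(results$p_raw), band = band,
             stringsAsFactors = FALSE)
}
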
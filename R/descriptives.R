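#' Stratified descriptive statistics
#'
#' Table-1-style summary by modifier stratum: mean (SD) with a Wilcoxon
#' rank-sum p-value for continuous variables; counts (%) with Fisher's
#' exact p for binary variables (chi-square fallback above 2 levels).
#' Includes the cognitive score and, when an abundance table is supplied,
#' Shannon alpha diversity.
#'
#' @param cohort analysis-ready cohort.
#' @param table optional relative [abundance_table] (pre-filter) for the
#'   Shannon diversity row.
#' @return data.frame: `variable, level, overall, secure, insecure, p_value,
#'   test`.
#' @export
cohort_descriptives <- function(cohort, table = NULL) {
  if (!"modifier" %in% names(cohort)) stopf("cohort lacks a modifier column")
  g <- cohort$modifier
  cont <- list(age = cohort$age, bmi = cohort$bmi, fiber = cohort$fiber,
               cognitive_score = cohort$outcome)
  if (!is.null(table)) {
    mat <- table$abund[match(cohort$sample_id, sample_ids(table)), , drop = FALSE]
    cont$shannon_diversity <- apply(mat, 1, shannon_diversity)
  }
  bin <- list(female = cohort$female, nhw = cohort$nhw, pet = cohort$pet,
              smoker = cohort$smoker, abx = cohort$abx)
  fmt_mean <- function(x) sprintf("%.2f (%.2f)", mean(x), sd(x))
  rows <- list()
  for (nm in names(cont)) {
    x <- cont[[nm]]
    p <- if (length(unique(x)) < 2) 1 else
      suppressWarnings(wilcox.test(x ~ g)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, level = "mean (sd)",
      overall = fmt_mean(x), secure = fmt_mean(x[g == 0]),
      insecure = fmt_mean(x[g == 1]), p_value = p, test = "wilcoxon",
      stringsAsFactors = FALSE)
  }
  for (nm in names(bin)) {
    x <- bin[[nm]]
    tab <- table(factor(x), factor(g, levels = 0:1))
    p <- if (nrow(tab) < 2) 1 else if (nrow(tab) == 2) {
      fisher.test(tab)$p.value
    } else {
      suppressWarnings(chisq.test(tab)$p.value)
    }
    test <- if (nrow(tab) == 2) "fisher" else "chi-square"
    for (lev in rownames(tab)) {
      cnt <- function(sel) {
        k <- sum(x[sel] == as.numeric(lev))
        sprintf("%d (%.2f%%)", k, 100 * k / sum(sel))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = lev, overall = cnt(rep(TRUE, length(x))),
        secure = cnt(g == 0), insecure = cnt(g == 1), p_value = p, test = test,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Fisher's exact p-value for a 2x2 table by hypergeometric enumeration
#'
#' Two-sided p as the total probability of tables (at fixed margins) no
#' more probable than the observed one. Exposed mainly as a readable
#' reference for the descriptives table's Fisher column.
#'
#' @param tab 2x2 integer matrix.
#' @return two-sided exact p-value.
#' @export
fisher_exact_p <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
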
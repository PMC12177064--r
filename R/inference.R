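#' Clique presence indicator
#'
#' Integer per-sample count of clique members present (abundance strictly
#' greater than 0), so a clique of k taxa yields values in 0..k.
#'
#' @param table relative [abundance_table] (post prevalence filter).
#' @param clique a [clique_definition] or character vector of taxon ids.
#' @return named integer vector over samples.
#' @export
clique_indicator <- function(table, clique) {
  stopifnot(inherits(table, "abundance_table"))
  members <- if (inherits(clique, "clique_definition")) clique$members else clique
  unknown <- setdiff(members, taxon_ids(table))
  if (length(unknown)) stopf("unknown clique member(s): %s", paste(unknown, collapse = ", "))
  ind <- rowSums(table$abund[, members, drop = FALSE] > 0)
  setNames(as.integer(ind), sample_ids(table))
}

build_design <- function(cohort, indicator, extra = NULL) {
  covs <- cohort[, intersect(covariate_names(), names(cohort)), drop = FALSE]
  design <- cbind(data.frame(clique = as.numeric(indicator)), covs)
  if (!is.null(extra)) design <- cbind(design, extra)
  design
}

#' Permutation p-value for one regression coefficient
#'
#' Permutes the outcome vector `N` times, refits the full linear model, and
#' compares the focal coefficient's t-statistic against the permutation
#' distribution: two-tailed `p = (1 + #{|t_perm| >= |t_obs|}) / (1 + N)`,
#' which can never be exactly zero. Refits are vectorised through the QR
#' decomposition of the fixed design, so `N = 1e5` is practical.
#'
#' @param y outcome vector.
#' @param design data.frame of predictors (focal column `term`).
#' @param term focal column name.
#' @param N number of permutations (default 1e5).
#' @param seed permutation seed.
#' @return list: `observed` t, `N`, `exceed` count, `p`.
#' @export
permutation_p <- function(y, design, term, N = 100000, seed = 1L) {
  if (N < 1) stopf("N must be >= 1")
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(design)))
  n <- nrow(X); p <- ncol(X)
  j <- match(term, colnames(X))
  if (is.na(j)) stopf("term '%s' not in design", term)
  qrX <- qr(X)
  if (qrX$rank < p) stopf("rank-deficient design in permutation test")
  Q <- qr.Q(qrX)
  R <- qr.R(qrX)
  Rinv <- backsolve(R, diag(p))
  # var(beta_j) = sigma2 * (R^-1 R^-T)[j,j]
  ucov <- sum(Rinv[j, ]^2)
  tstat <- function(Y) {
    # Y: n x m matrix of outcomes; returns t for coefficient j per column
    QtY <- crossprod(Q, Y)                    # p x m
    beta_j <- drop(Rinv[j, ] %*% QtY)
    rss <- colSums(Y^2) - colSums(QtY^2)
    sigma2 <- rss / (n - p)
    beta_j / sqrt(sigma2 * ucov)
  }
  t_obs <- tstat(matrix(y, ncol = 1))
  block <- 2000L
  exceed <- 0L
  with_seed(seed, {
    done <- 0L
    while (done < N) {
      m <- min(block, N - done)
      Yp <- vapply(seq_len(m), function(i) y[sample.int(n)], numeric(n))
      exceed <- exceed + sum(abs(tstat(Yp)) >= abs(t_obs))
      done <- done + m
    }
  })
  p_val <- (1 + exceed) / (1 + N)
  list(observed = as.numeric(t_obs), N = as.integer(N),
       exceed = as.integer(exceed), p = p_val)
}

#' Stratified covariate-adjusted clique association
#'
#' OLS of the transformed outcome on the clique indicator plus the full
#' covariate set within one modifier stratum. The "robust" p-value is the
#' permutation p (outcome permuted within the stratum); the asymptotic
#' t-test p is reported alongside.
#'
#' @param cohort analysis-ready cohort (column `y`).
#' @param indicator named integer vector from [clique_indicator()].
#' @param stratum `"secure"`, `"insecure"`, or `"overall"`.
#' @param n_perm permutations for the robust p (0 = asymptotic only).
#' @param seed permutation seed.
#' @param clique_name label recorded in the result row.
#' @return one-row data.frame: association-result columns plus
#'   `p_perm` and `n_perm`.
#' @export
clique_association <- function(cohort, indicator, stratum, n_perm = 100000,
                               seed = 1L, clique_name = "clique") {
  idx <- stratum_rows(cohort, stratum)
  sub <- cohort[idx, , drop = FALSE]
  ind <- indicator[sub$sample_id]
  if (anyNA(ind)) stopf("indicator is missing for some stratum samples")
  if (length(unique(ind)) < 2) {
    stopf("clique indicator is constant within stratum '%s'", stratum)
  }
  design <- build_design(sub, ind)
  res <- ols_fit(sub$y, design, term = "clique", stratum = stratum)
  res$term <- clique_name
  if (n_perm > 0) {
    pr <- permutation_p(sub$y, design, term = "clique", N = n_perm,
                        seed = subseed(seed, "perm", stratum, clique_name))
    res$p_perm <- pr$p
    res$n_perm <- pr$N
  } else {
    res$p_perm <- NA_real_
    res$n_perm <- 0L
  }
  res
}

#' Validate a clique in the opposite stratum
#'
#' Re-estimates the association of a clique discovered in stratum A within
#' the held-out samples of stratum B. A constant indicator in B is reported
#' as non-validatable (NA row), not an error.
#'
#' @param cohort analysis-ready cohort.
#' @param indicator clique indicator over all samples.
#' @param discovered_in stratum the clique was discovered in.
#' @inheritParams clique_association
#' @return one-row data.frame labelled with the validation stratum and a
#'   `validation` flag.
#' @export
cross_stratum_validate <- function(cohort, indicator, discovered_in,
                                   n_perm = 100000, seed = 1L,
                                   clique_name = "clique") {
  other <- setdiff(names(strata_labels()), discovered_in)
  res <- tryCatch(
    clique_association(cohort, indicator, other, n_perm = n_perm, seed = seed,
                       clique_name = clique_name),
    error = function(e) {
      data.frame(term = clique_name, stratum = other, beta = NA_real_,
                 se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_raw = NA_real_, n = length(stratum_rows(cohort, other)),
                 p_perm = NA_real_, n_perm = 0L, stringsAsFactors = FALSE)
    })
  res$validation <- TRUE
  res$discovered_in <- discovered_in
  res
}

#' Clique-by-modifier interaction test
#'
#' Single overall model on all samples: `y ~ indicator + modifier +
#' indicator:modifier + covariates`. Returns the product-term estimate; its
#' permutation p permutes the outcome unconditionally.
#'
#' @inheritParams clique_association
#' @return one-row data.frame for the interaction term.
#' @export
interaction_test <- function(cohort, indicator, n_perm = 100000, seed = 1L,
                             clique_name = "clique") {
  ind <- indicator[cohort$sample_id]
  if (anyNA(ind)) stopf("indicator is missing for some samples")
  if (length(unique(cohort$modifier)) < 2) stopf("both strata must be represented")
  extra <- data.frame(modifier = cohort$modifier,
                      clique_x_modifier = as.numeric(ind) * cohort$modifier)
  design <- build_design(cohort, ind, extra = extra)
  res <- ols_fit(cohort$y, design, term = "clique_x_modifier", stratum = "overall")
  res$term <- paste0(clique_name, ":modifier")
  if (n_perm > 0) {
    pr <- permutation_p(cohort$y, design, term = "clique_x_modifier", N = n_perm,
                        seed = subseed(seed, "perm-int", clique_name))
    res$p_perm <- pr$p
    res$n_perm <- pr$N
  } else {
    res$p_perm <- NA_real_
    res$n_perm <- 0L
  }
  res
}

#' Covariate balance under propensity subclassification
#'
#' Dichotomises exposure as "any clique member present", fits a logistic
#' propensity model on the covariates, cuts samples into propensity
#' quantile subclasses (empty subclasses merge with a neighbour, with a
#' warning), and reports the standardized mean difference of every
#' covariate before and after subclass weighting. The SMD denominator is
#' the pre-balancing pooled SD in both columns so the two are comparable
#' (love-plot data).
#'
#' @param cohort analysis-ready cohort.
#' @param indicator clique indicator.
#' @param n_subclasses propensity quantile subclasses (default 5).
#' @return data.frame: `covariate, smd_before, smd_after`.
#' @export
balance_diagnostics <- function(cohort, indicator, n_subclasses = 5) {
  ind <- indicator[cohort$sample_id]
  expo <- as.integer(ind > 0)
  if (length(unique(expo)) < 2) stopf("exposure is constant; no balance to assess")
  covs <- intersect(covariate_names(), names(cohort))
  dat <- cohort[, covs, drop = FALSE]
  ps <- predict(glm(expo ~ ., data = dat, family = binomial()), type = "response")
  br <- unique(quantile(ps, seq(0, 1, length.out = n_subclasses + 1)))
  if (length(br) - 1 < n_subclasses) {
    warning("empty propensity subclass(es) merged with neighbours")
  }
  sub <- cut(ps, breaks = br, include.lowest = TRUE, labels = FALSE)
  # merge subclasses lacking either exposure group into the nearest neighbour
  repeat {
    tab <- table(factor(sub), factor(expo, levels = 0:1))
    bad <- which(tab[, 1] == 0 | tab[, 2] == 0)
    if (!length(bad) || length(unique(sub)) <= 1) break
    b <- as.integer(rownames(tab)[bad[1]])
    lv <- sort(unique(sub))
    pos <- match(b, lv)
    nb <- if (pos > 1) lv[pos - 1] else lv[pos + 1]
    sub[sub == b] <- nb
    warning("propensity subclass without both exposure groups merged")
  }
  smd <- function(x, e) {
    s <- sqrt((var(x[e == 1]) + var(x[e == 0])) / 2)
    if (s == 0) return(c(0, s))
    c((mean(x[e == 1]) - mean(x[e == 0])) / s, s)
  }
  out <- lapply(covs, function(cv) {
    x <- dat[[cv]]
    pre <- smd(x, expo)
    pooled_sd <- pre[2]
    if (pooled_sd == 0) {
      after <- 0
    } else {
      lv <- sort(unique(sub))
      w <- vapply(lv, function(s) mean(sub == s), numeric(1))
      diffs <- vapply(lv, function(s) {
        xs <- x[sub == s]; es <- expo[sub == s]
        mean(xs[es == 1]) - mean(xs[es == 0])
      }, numeric(1))
      after <- sum(w * diffs) / pooled_sd
    }
    data.frame(covariate = cv, smd_before = pre[1], smd_after = after,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
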
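test_that("clique indicators count present members and respect 0..k bounds", {
  mat <- rbind(s1 = c(0.2, 0.3, 0.0, 0.5), s2 = c(0.0, 0.0, 0.4, 0.6),
               s3 = c(0.1, 0.1, 0.4, 0.4), s4 = c(0.0, 0.0, 0.0, 1.0))
  colnames(mat) <- c("a", "b", "c", "d")
  tab <- abundance_table(mat, is_relative = TRUE)
  ind2 <- clique_indicator(tab, c("a", "b"))
  expect_identical(unname(ind2), c(2L, 0L, 2L, 0L))
  expect_true(all(ind2 >= 0 & ind2 <= 2))
  ind4 <- clique_indicator(tab, c("a", "b", "c", "d"))
  expect_true(all(ind4 >= 0 & ind4 <= 4))
  expect_identical(unname(ind4["s4"]), 1L)
  expect_error(clique_indicator(tab, c("a", "zz")), "unknown")
})

test_that("clique association delegates exactly to the OLS engine", {
  st <- small_study(seed = 81, n = 200)
  ind <- clique_indicator(st$filtered, taxon_ids(st$filtered)[1:2])
  res <- clique_association(st$cohort, ind, "overall", n_perm = 0)
  sub <- st$cohort
  design <- cbind(data.frame(clique = as.numeric(ind[sub$sample_id])),
                  sub[, c("age", "bmi", "fiber", "female", "nhw", "pet",
                          "smoker", "abx")])
  oracle <- ols_fit(sub$y, design, term = "clique", stratum = "overall")
  expect_equal(res$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(res$se, oracle$se, tolerance = 1e-10)
  # constant indicator within a stratum is an error
  const <- setNames(rep(1L, nrow(st$cohort)), st$cohort$sample_id)
  expect_error(clique_association(st$cohort, const, "overall", n_perm = 0),
               "constant")
})

test_that("permutation p has the add-one floor and matches the t-test under a Gaussian null", {
  n <- 120
  dat <- withr::with_seed(3, data.frame(x = rnorm(n), z = rnorm(n)))
  # overwhelming effect: no permutation can beat it
  y_strong <- 3 * dat$x + withr::with_seed(4, rnorm(n, 0, 0.1))
  pr <- permutation_p(y_strong, dat, term = "x", N = 200, seed = 1)
  expect_equal(pr$p, 1 / 201)
  expect_gt(pr$p, 0)
  # null: permutation p agrees with the classical t-test p
  y_null <- withr::with_seed(5, rnorm(n))
  pr <- permutation_p(y_null, dat, term = "x", N = 2000, seed = 2)
  fit <- summary(lm(y_null ~ x + z, dat))
  p_t <- fit$coefficients["x", 4]
  expect_lt(abs(pr$p - p_t), 2 * sqrt(p_t * (1 - p_t) / 2000) + 1e-3)
  # invariant to relabeling / reordering covariate columns
  pr2 <- permutation_p(y_null, dat[, c("z", "x")], term = "x", N = 500, seed = 9)
  pr3 <- permutation_p(y_null, dat[, c("x", "z")], term = "x", N = 500, seed = 9)
  expect_equal(pr2$p, pr3$p)
})

test_that("cross-stratum validation reports the opposite stratum faithfully", {
  both <- small_study(seed = 91, n = 400, modifier_prevalence = 0.5,
                      cliques = list(planted_clique(c(19, 21),
                                                    effect = c(secure = 0.35, insecure = 0.35))))
  ind <- clique_indicator(both$filtered, c("ASV0019", "ASV0021"))
  disc <- clique_association(both$cohort, ind, "insecure", n_perm = 0)
  val <- cross_stratum_validate(both$cohort, ind, "insecure", n_perm = 0)
  expect_identical(val$stratum, "secure")
  expect_true(val$validation)
  expect_true(disc$ci_low > 0)         # effect present where discovered
  expect_true(val$ci_low > 0)          # and replicates in the other stratum
  # effect in one stratum only: validation estimate is near zero
  only_a <- small_study(seed = 92, n = 500, modifier_prevalence = 0.5,
                        cliques = list(planted_clique(c(19, 21),
                                                      effect = c(secure = 0, insecure = 0.4))))
  ind_a <- clique_indicator(only_a$filtered, c("ASV0019", "ASV0021"))
  val_a <- cross_stratum_validate(only_a$cohort, ind_a, "insecure", n_perm = 0)
  expect_lt(abs(val_a$beta), 2 * val_a$se)
  # constant indicator in the validation stratum: NA row, not an error
  coh <- only_a$cohort
  ind_c <- ind_a
  ind_c[coh$sample_id[coh$modifier == 0]] <- 1L
  val_c <- cross_stratum_validate(coh, ind_c, "insecure", n_perm = 0)
  expect_true(is.na(val_c$beta))
})

test_that("the interaction term recovers the difference of stratum slopes", {
  st <- small_study(seed = 93, n = 2500, n_taxa = 30, modifier_prevalence = 0.5,
                    cliques = list(planted_clique(c(14, 16),
                                                  effect = c(secure = 0.05, insecure = 0.29))))
  ind <- clique_indicator(st$filtered, c("ASV0014", "ASV0016"))
  res <- interaction_test(st$cohort, ind, n_perm = 0)
  expect_lt(abs(res$beta - 0.24), 3 * res$se)
  # equal slopes: interaction near zero
  eq <- small_study(seed = 94, n = 1500, n_taxa = 30, modifier_prevalence = 0.5,
                    cliques = list(planted_clique(c(14, 16),
                                                  effect = c(secure = 0.2, insecure = 0.2))))
  ind_eq <- clique_indicator(eq$filtered, c("ASV0014", "ASV0016"))
  res_eq <- interaction_test(eq$cohort, ind_eq, n_perm = 0)
  expect_lt(abs(res_eq$beta), 2 * res_eq$se)
  # stratified betas agree with main + interaction within 2 SE
  a_sec <- clique_association(eq$cohort, ind_eq, "secure", n_perm = 0)
  a_ins <- clique_association(eq$cohort, ind_eq, "insecure", n_perm = 0)
  expect_lt(abs((a_ins$beta - a_sec$beta) - res_eq$beta),
            2 * sqrt(a_ins$se^2 + a_sec$se^2))
})

test_that("balance diagnostics compute SMDs by definition and improve under subclassing", {
  # pure shift of exactly one pooled SD
  x0 <- as.numeric(scale(withr::with_seed(1, rnorm(30))))  # sample sd exactly 1
  cohort <- data.frame(sample_id = sprintf("S%02d", 1:60),
                       age = c(x0, x0 + 1),
                       bmi = rep(25, 60), fiber = rep(19, 60),
                       female = rep(0:1, 30), nhw = 1, pet = 0, smoker = 0,
                       abx = 0, modifier = 0, outcome = 2, y = log(2))
  ind <- setNames(rep(c(0L, 1L), each = 30), cohort$sample_id)
  suppressWarnings(bal <- balance_diagnostics(cohort, ind, n_subclasses = 2))
  expect_equal(bal$smd_before[bal$covariate == "age"], 1, tolerance = 1e-9)
  expect_equal(bal$smd_before[bal$covariate == "bmi"], 0)
  # confounded exposure: subclassification shrinks mean |SMD|
  n <- 600
  coh <- withr::with_seed(7, {
    age <- rnorm(n, 60, 10)
    expo <- rbinom(n, 1, plogis((age - 60) / 6))
    data.frame(sample_id = sprintf("S%04d", 1:n), age = age,
               bmi = rnorm(n, 30, 5), fiber = rnorm(n, 19, 6),
               female = rbinom(n, 1, 0.5), nhw = rbinom(n, 1, 0.85),
               pet = rbinom(n, 1, 0.5), smoker = rbinom(n, 1, 0.5),
               abx = rbinom(n, 1, 0.3), modifier = rbinom(n, 1, 0.2),
               outcome = 2, y = log(2), expo = expo)
  })
  ind2 <- setNames(coh$expo, coh$sample_id)
  bal2 <- balance_diagnostics(coh[, setdiff(names(coh), "expo")], ind2)
  expect_lt(mean(abs(bal2$smd_after)), mean(abs(bal2$smd_before)))
})
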